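# Sentiment feature space: per-post non-negative counts over
#   sent:<token>  one per sentiment-lexicon word
#   ent:<token>   one per entity-lexicon word
#   emo_pos / emo_neg   signed emoticon counts
#   punct_exclam / punct_question   expressive punctuation counts
# The class pairing f_{j,c}(c', d) = g_j(d) * 1[c' = c] is handled inside the
# model, so lambda is a (feature x class) matrix.

#' Sentiment feature counts for one tokenized post
#'
#' @param tokens Character vector of post tokens.
#' @param lexicons List with `entity_words` and `sentiment_words`
#'   (see [bootstrap_lexicon()]).
#' @return Named numeric vector of non-negative counts; only the non-zero
#'   support is returned.
#' @export
extract_features <- function(tokens, lexicons) {
  counts <- table(tokens)
  out <- numeric(0)
  s <- intersect(names(counts), lexicons$sentiment_words)
  if (length(s)) out <- c(out, setNames(as.numeric(counts[s]), paste0("sent:", s)))
  e <- intersect(names(counts), lexicons$entity_words)
  if (length(e)) out <- c(out, setNames(as.numeric(counts[e]), paste0("ent:", e)))
  emo <- emoticon_sets()
  np <- sum(counts[intersect(names(counts), emo$positive)])
  nn <- sum(counts[intersect(names(counts), emo$negative)])
  ex <- sum(counts[intersect(names(counts), "!")])
  qu <- sum(counts[intersect(names(counts), "?")])
  extra <- c(emo_pos = np, emo_neg = nn, punct_exclam = ex, punct_question = qu)
  c(out, extra[extra > 0])
}

#' Sentiment feature matrix for a tokenized corpus
#'
#' Vectorized companion of [extract_features()]: one row per post, one
#' column per feature, identical counts.
#'
#' @param posts Tokenized post tibble.
#' @inheritParams extract_features
#' @return Sparse matrix (posts x features) with post ids as row names.
#' @export
features_matrix <- function(posts, lexicons) {
  special <- c(emoticon_sets()$positive, emoticon_sets()$negative, "!", "?")
  vocab <- c(lexicons$sentiment_words, lexicons$entity_words, special)
  dtm <- corpus_dtm_counts(posts, vocab)
  emo <- emoticon_sets()
  cols <- list()
  if (length(lexicons$sentiment_words)) {
    m <- dtm[, lexicons$sentiment_words, drop = FALSE]
    colnames(m) <- paste0("sent:", lexicons$sentiment_words)
    cols$sent <- m
  }
  if (length(lexicons$entity_words)) {
    m <- dtm[, lexicons$entity_words, drop = FALSE]
    colnames(m) <- paste0("ent:", lexicons$entity_words)
    cols$ent <- m
  }
  extra <- cbind(emo_pos = Matrix::rowSums(dtm[, emo$positive, drop = FALSE]),
                 emo_neg = Matrix::rowSums(dtm[, emo$negative, drop = FALSE]),
                 punct_exclam = dtm[, "!"],
                 punct_question = dtm[, "?"])
  out <- do.call(cbind, c(unname(cols), list(extra)))
  rownames(out) <- posts$id
  methods::as(out, "CsparseMatrix")
}

# like corpus_dtm() but with token multiplicities
corpus_dtm_counts <- function(posts, vocab) {
  toks <- unlist(posts$tokens, use.names = FALSE)
  doc <- rep.int(seq_len(nrow(posts)), lengths(posts$tokens))
  term <- match(toks, vocab)
  keep <- !is.na(term)
  Matrix::sparseMatrix(i = doc[keep], j = term[keep], x = 1,
                       dims = c(nrow(posts), length(vocab)),
                       dimnames = list(posts$id, vocab))
}

.slack_name <- "..slack.."

# Align a feature vector/matrix to the model's feature space and append the
# slack feature padding every row's total to M (an IIS requirement).
maxent_design <- function(model, fv) {
  feats <- setdiff(model$features, .slack_name)
  if (is.null(dim(fv))) {
    fv <- matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))
  }
  g <- matrix(0, nrow(fv), length(feats), dimnames = list(rownames(fv), feats))
  shared <- intersect(colnames(fv), feats)
  g[, shared] <- as.matrix(fv[, shared, drop = FALSE])
  slack <- pmax(model$M - rowSums(g), 0)
  g <- cbind(g, slack)
  colnames(g)[ncol(g)] <- .slack_name
  g
}

#' Maximum-entropy class probabilities
#'
#' Evaluates the multinomial log-linear model
#' \eqn{p(c \mid d, \lambda) = \exp(\sum_i \lambda_{i,c} f_i(d)) /
#' \sum_{c'} \exp(\sum_i \lambda_{i,c'} f_i(d))}
#' with log-sum-exp stabilization. Features unknown to the model are
#' ignored; missing ones count as zero.
#'
#' @param fv Named numeric feature vector, or a matrix with one row per
#'   instance.
#' @param model A `maxent_model` from [train_maxent_iis()].
#' @return A named probability vector (single instance) or a matrix with
#'   one row per instance; rows are strictly positive and sum to 1.
#' @export
maxent_prob <- function(fv, model) {
  stopifnot(inherits(model, "maxent_model"))
  single <- is.null(dim(fv))
  g <- maxent_design(model, fv)
  scores <- g %*% model$lambda
  p <- softmax_rows(scores)
  colnames(p) <- model$classes
  if (single) p[1, ] else p
}

#' Train a maximum-entropy classifier by improved iterative scaling
#'
#' Fits the feature weights by IIS: every instance is padded with a slack
#' feature so the feature total is the constant \eqn{M}, and each iteration
#' applies the closed-form update
#' \eqn{\delta_{j,c} = \log(\tilde E[f_{j,c}] / E_\lambda[f_{j,c}]) / M},
#' which provably does not decrease the training log-likelihood. Features
#' never observed with a class get a capped negative update (which keeps
#' the monotonicity guarantee). Training stops when the mean log-likelihood
#' improves by less than `tol` or after `max_iter` iterations.
#'
#' @param g Feature matrix (instances x features), non-negative and finite;
#'   e.g. from [features_matrix()].
#' @param y Class labels (>= 2 distinct classes required).
#' @param tol Convergence tolerance on the mean log-likelihood change.
#' @param max_iter Iteration cap.
#' @return A list of class `maxent_model`: `classes`, `features` (including
#'   the slack), `lambda` (feature x class matrix), `M`, `ll_trace` (mean
#'   log-likelihood per iteration, non-decreasing), `converged`,
#'   `iterations`.
#' @export
train_maxent_iis <- function(g, y, tol = 1e-6, max_iter = 500) {
  g <- as.matrix(g)
  if (!all(is.finite(g))) {
    abort("feature matrix contains non-finite values.",
          class = "opinionpulse_training_error")
  }
  if (any(g < 0)) {
    abort("IIS requires non-negative feature values.",
          class = "opinionpulse_training_error")
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    abort("training data contains a single class.",
          class = "opinionpulse_training_error")
  }
  n <- nrow(g)
  M <- max(rowSums(g), 1)
  g <- cbind(g, pmax(M - rowSums(g), 0))
  colnames(g)[ncol(g)] <- .slack_name
  J <- ncol(g)
  C <- length(classes)
  lambda <- matrix(0, J, C, dimnames = list(colnames(g), classes))
  ymat <- outer(y, classes, `==`) + 0
  emp <- crossprod(g, ymat)  # empirical feature-class counts
  cap <- 30 / M
  ll <- function(p) mean(log(pmax(rowSums(p * ymat), 1e-300)))
  p <- softmax_rows(g %*% lambda)
  trace <- ll(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    expec <- crossprod(g, p)  # model expected counts
    delta <- matrix(0, J, C)
    pos <- emp > 0
    delta[pos] <- log(emp[pos] / expec[pos]) / M
    delta[!pos & expec > 0] <- -cap
    lambda <- lambda + delta
    p <- softmax_rows(g %*% lambda)
    trace <- c(trace, ll(p))
    if (trace[it + 1] - trace[it] < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(classes = classes, features = colnames(g), lambda = lambda,
                 M = M, ll_trace = trace, converged = converged,
                 iterations = length(trace) - 1L),
            class = "maxent_model")
}

#' @export
predict.maxent_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- maxent_prob(newdata, object)
  if (type == "prob") return(p)
  if (is.null(dim(p))) object$classes[which.max(p)]
  else object$classes[max.col(p, ties.method = "first")]
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d classes, %d features, %d IIS iterations (%s)\n",
              length(x$classes), length(x$features), x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}
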