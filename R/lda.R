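#' Online latent Dirichlet allocation with a dynamic vocabulary
#'
#' A stochastic variational Bayes LDA fitted on minibatches of documents.
#' Each minibatch runs a per-document variational E-step (digamma
#' geometric-mean parameterization) and a stochastic M-step on the
#' topic-word variational parameters with step size
#' \eqn{\rho_t = (\tau_0 + t)^{-\kappa}}. Words never seen before are
#' appended to the vocabulary before the update, so the model can follow a
#' growing post stream.
#'
#' @param K Number of topics.
#' @param alpha Document-topic Dirichlet prior (default 1/K).
#' @param eta Topic-word Dirichlet prior.
#' @param kappa Learning-rate decay exponent in \[0.5, 1\] (0 reduces a
#'   single full-corpus batch to one batch variational EM step).
#' @param tau0 Learning-rate delay.
#' @param vocab Optional initial vocabulary.
#' @param seed Seed for the topic-word initialization (and for the
#'   initialization of newly appended words).
#' @return A list of class `lda_model`.
#' @export
lda_model <- function(K, alpha = 1 / K, eta = 0.01, kappa = 0.7, tau0 = 64,
                      vocab = character(0), seed = 1) {
  K <- check_count(K, "K", min = 1L)
  lambda <- matrix(numeric(0), K, 0)
  model <- structure(list(K = K, alpha = alpha, eta = eta, kappa = kappa,
                          tau0 = tau0, t = 0L, docs_seen = 0L,
                          vocab = character(0), lambda = lambda,
                          seed = as.integer(seed), draw = 0L),
                     class = "lda_model")
  if (length(vocab)) model <- lda_grow_vocab(model, vocab)
  model
}

# Append new words; their topic-word parameters are initialized from the
# same seeded Gamma(100, 100) draw as the Hoffman-style initialization.
lda_grow_vocab <- function(model, words) {
  new <- setdiff(unique(words), model$vocab)
  if (!length(new)) return(model)
  cols <- with_seed(model$seed + model$draw, {
    matrix(stats::rgamma(model$K * length(new), shape = 100, rate = 100),
           model$K, length(new))
  })
  model$draw <- model$draw + 1L
  model$lambda <- cbind(model$lambda, cols)
  model$vocab <- c(model$vocab, new)
  colnames(model$lambda) <- model$vocab
  model
}

lda_exp_elog_beta <- function(lambda) {
  exp(digamma(lambda) - digamma(rowSums(lambda)))
}

# Variational E-step for one document over word ids/counts.
# Returns list(gamma, phi_contrib) where phi_contrib[k, w] is the
# sufficient-statistics contribution before multiplying by expElogbeta.
lda_e_step_doc <- function(ids, cts, expElogbeta, alpha, K,
                           max_inner = 100, conv = 1e-3) {
  gamma_d <- rep(1, K)
  expElogtheta <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
  beta_d <- expElogbeta[, ids, drop = FALSE]
  phinorm <- as.numeric(crossprod(beta_d, expElogtheta)) + 1e-100
  for (i in seq_len(max_inner)) {
    last <- gamma_d
    gamma_d <- alpha + expElogtheta * as.numeric(beta_d %*% (cts / phinorm))
    expElogtheta <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
    phinorm <- as.numeric(crossprod(beta_d, expElogtheta)) + 1e-100
    if (mean(abs(gamma_d - last)) < conv) break
  }
  list(gamma = gamma_d, resp = outer(expElogtheta, cts / phinorm))
}

#' One online update from a minibatch of documents
#'
#' @param model An [lda_model()].
#' @param docs List of token character vectors (a minibatch; must be
#'   non-empty).
#' @param total_docs Corpus size \eqn{D} used to rescale the minibatch
#'   sufficient statistics; defaults to the number of documents seen after
#'   this update.
#' @return The updated model (vocabulary grown, `t` advanced).
#' @export
online_lda_update <- function(model, docs, total_docs = NULL) {
  stopifnot(inherits(model, "lda_model"))
  if (length(docs) == 0L) {
    abort("minibatch must be non-empty.", class = "opinionpulse_config_error")
  }
  model <- lda_grow_vocab(model, unlist(docs, use.names = FALSE))
  S <- length(docs)
  D <- total_docs %||% (model$docs_seen + S)
  expElogbeta <- lda_exp_elog_beta(model$lambda)
  sstats <- matrix(0, model$K, length(model$vocab))
  for (d in docs) {
    tab <- table(d)
    ids <- match(names(tab), model$vocab)
    cts <- as.numeric(tab)
    es <- lda_e_step_doc(ids, cts, expElogbeta, model$alpha, model$K)
    sstats[, ids] <- sstats[, ids] + es$resp
  }
  sstats <- sstats * expElogbeta
  rho <- (model$tau0 + model$t)^(-model$kappa)
  model$lambda <- (1 - rho) * model$lambda +
    rho * (model$eta + (D / S) * sstats)
  colnames(model$lambda) <- model$vocab
  model$t <- model$t + 1L
  model$docs_seen <- model$docs_seen + S
  model
}

#' Fit online LDA over a corpus in minibatches
#'
#' @param docs List of token vectors (or a tokenized post tibble, in which
#'   case its `tokens` column is used).
#' @param K Topic count.
#' @param passes Sweeps over the corpus.
#' @param batch_size Minibatch size.
#' @param ... Passed to [lda_model()].
#' @return A fitted `lda_model`.
#' @export
lda_online <- function(docs, K = 10, passes = 3, batch_size = 256, ...) {
  if (is.data.frame(docs)) docs <- docs$tokens
  model <- lda_model(K, ...)
  n <- length(docs)
  if (n == 0L) return(model)
  starts <- seq(1, n, by = batch_size)
  for (p in seq_len(passes)) {
    for (s in starts) {
      batch <- docs[s:min(s + batch_size - 1, n)]
      model <- online_lda_update(model, batch, total_docs = n)
    }
  }
  model
}

#' Topic-word probability matrix
#' @param model A fitted `lda_model`.
#' @return A K x V matrix; every row sums to 1.
#' @export
topic_word <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  model$lambda / rowSums(model$lambda)
}

#' Infer document-topic proportions
#' @param model A fitted `lda_model`.
#' @param docs List of token vectors or a tokenized post tibble.
#' @return Matrix (documents x topics) of normalized variational topic
#'   proportions.
#' @export
lda_doc_topics <- function(model, docs) {
  if (is.data.frame(docs)) docs <- docs$tokens
  expElogbeta <- lda_exp_elog_beta(model$lambda)
  out <- matrix(NA_real_, length(docs), model$K)
  for (i in seq_along(docs)) {
    tab <- table(docs[[i]])
    ids <- match(names(tab), model$vocab)
    keep <- !is.na(ids)
    if (!any(keep)) {
      out[i, ] <- 1 / model$K
      next
    }
    es <- lda_e_step_doc(ids[keep], as.numeric(tab)[keep], expElogbeta,
                         model$alpha, model$K)
    out[i, ] <- es$gamma / sum(es$gamma)
  }
  out
}

#' Rank topics over a document subset
#'
#' Topics are ranked by their total expected assignment mass (sum of
#' per-document variational topic proportions) over the subset; each is
#' reported with its top words.
#'
#' @param model A fitted `lda_model`.
#' @param docs Non-empty list of token vectors or tokenized post tibble.
#' @param k Number of topics to report (must not exceed the model's K).
#' @param n_words Top words listed per topic.
#' @return A tibble with columns `rank`, `topic`, `mass`, `top_words`
#'   (list-column).
#' @export
top_topics <- function(model, docs, k = 5, n_words = 10) {
  if (is.data.frame(docs)) docs <- docs$tokens
  if (k > model$K) {
    abort("`k` exceeds the model's topic count.",
          class = "opinionpulse_config_error")
  }
  if (length(docs) == 0L) {
    abort("document subset must be non-empty.",
          class = "opinionpulse_config_error")
  }
  theta <- lda_doc_topics(model, docs)
  mass <- colSums(theta)
  ord <- order(-mass)[seq_len(k)]
  tw <- topic_word(model)
  tibble(rank = seq_len(k), topic = ord, mass = mass[ord],
         top_words = purrr::map(ord, function(t) {
           model$vocab[order(-tw[t, ])[seq_len(min(n_words, ncol(tw)))]]
         }))
}

#' Topic co-occurrence graph over a document subset
#'
#' Edge weight between topics i and j is the number of subset documents
#' whose inferred topic proportions exceed the presence threshold for both
#' topics; the matrix is symmetric with a zero diagonal.
#'
#' @param model A fitted `lda_model`.
#' @param docs List of token vectors or tokenized post tibble.
#' @param theta Presence threshold in (0, 1).
#' @return A symmetric K x K integer matrix of co-occurrence counts.
#' @export
topic_cooccurrence <- function(model, docs, theta = 0.2) {
  if (theta <= 0 || theta >= 1) {
    abort("`theta` must lie strictly between 0 and 1.",
          class = "opinionpulse_config_error")
  }
  if (is.data.frame(docs)) docs <- docs$tokens
  props <- lda_doc_topics(model, docs)
  pres <- props > theta
  w <- crossprod(pres * 1L)
  diag(w) <- 0L
  w
}

#' Persist a fitted LDA model as a plain-text directory
#'
#' Writes `vocab.csv` (word, index) and `topic_word.txt` (dense
#' whitespace-delimited K x V matrix of the variational parameters).
#'
#' @param model A fitted `lda_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble(index = seq_along(model$vocab), word = model$vocab),
                   file.path(dir, "vocab.csv"))
  utils::write.table(model$lambda, file.path(dir, "topic_word.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d, vocabulary %d words, %d minibatch updates\n",
              x$K, length(x$vocab), x$t))
  invisible(x)
}
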