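#' Sparse document-term matrix for a tokenized corpus
#'
#' @param posts Tokenized post tibble (list-column `tokens`).
#' @param vocab Optional fixed term vector; defaults to all observed tokens.
#' @return A sparse `dgCMatrix` (documents x terms) with post ids as row
#'   names.
#' @export
corpus_dtm <- function(posts, vocab = NULL) {
  stopifnot("tokens" %in% names(posts))
  toks <- unlist(posts$tokens, use.names = FALSE)
  lens <- lengths(posts$tokens)
  doc <- rep.int(seq_len(nrow(posts)), lens)
  if (is.null(vocab)) vocab <- sort(unique(toks))
  term <- match(toks, vocab)
  keep <- !is.na(term)
  m <- Matrix::sparseMatrix(i = doc[keep], j = term[keep], x = 1,
                            dims = c(nrow(posts), length(vocab)),
                            dimnames = list(posts$id, vocab))
  methods::as(m, "CsparseMatrix")
}

#' Pluggable binary classifiers for topic tracking
#'
#' The active-learning loop takes any classifier honoring a two-function
#' contract: `fit(x, y)` trains on a sparse/dense feature matrix and binary
#' labels, and returns an object accepted by `prob(model, x)`, which returns
#' calibrated positive-class probabilities. `classifier_glmnet()` (the
#' default) is a class-balanced, ridge-penalized logistic regression — a
#' deterministic, calibrated linear model whose dense weights suit the
#' boundary-focused labeled sets an uncertainty-sampling loop produces.
#' `classifier_svm()` wraps a linear-kernel SVM
#' with probability calibration (requires the e1071 package).
#'
#' @param lambda Penalty at which predictions are made.
#' @param alpha Elastic-net mixing. The default 0 (ridge) keeps dense token
#'   weights: under uncertainty sampling the labeled set concentrates on
#'   boundary examples, and sparse (L1) fits can lock onto the token subset
#'   those examples happen to contain, zeroing equally informative tokens
#'   they do not.
#' @param balanced Reweight observations so both classes carry equal total
#'   weight — active-learning labeled sets are typically very imbalanced.
#' @param cost SVM cost parameter.
#' @return A list with functions `fit` and `prob`.
#' @export
classifier_glmnet <- function(lambda = 0.001, alpha = 0, balanced = TRUE) {
  # glmnet is fitted along a decreasing path down to the target penalty;
  # cold single-lambda fits are unreliable on the tiny labeled sets an
  # active-learning loop starts from.
  path <- exp(seq(log(lambda * 100), log(lambda), length.out = 25))
  list(
    fit = function(x, y) {
      w <- if (balanced) {
        length(y) / (2 * table(factor(y, levels = c(FALSE, TRUE)))[as.character(y)])
      } else {
        rep(1, length(y))
      }
      suppressWarnings(
        glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = alpha, weights = as.numeric(w),
                       lambda = path, standardize = FALSE))
    },
    prob = function(model, x) {
      as.numeric(predict(model, x, s = lambda, type = "response"))
    })
}

#' @rdname classifier_glmnet
#' @export
classifier_svm <- function(cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    abort("classifier_svm() requires the e1071 package.")
  }
  list(
    fit = function(x, y) {
      e1071::svm(as.matrix(x), factor(y, levels = c(FALSE, TRUE)),
                 kernel = "linear", cost = cost, probability = TRUE,
                 scale = FALSE)
    },
    prob = function(model, x) {
      p <- attr(predict(model, as.matrix(x), probability = TRUE),
                "probabilities")
      as.numeric(p[, "TRUE"])
    })
}

#' Initialize an active-learning state
#'
#' @param dtm Document-term matrix over the full pool ([corpus_dtm()]).
#' @param seed_labels Tibble with columns `post_id`, `label` (logical);
#'   must contain at least one example of each class.
#' @param budget Maximum number of query iterations.
#' @param classifier A classifier contract (see [classifier_glmnet()]).
#' @param strategy `"uncertainty"` (default) queries the pool posts closest
#'   to the decision boundary; `"exploitation"` selects those with the
#'   largest positive-class probability (the literal "largest score" rule,
#'   kept as an option; it queries almost no negatives and cannot sharpen
#'   the boundary in a binary pool); `"random"` queries a uniform sample
#'   (the no-active-learning baseline; uses the session RNG).
#' @return A list of class `al_state` with labeled set `d_l`, pool `d_u`,
#'   trained classifier, iteration counter and budget.
#' @export
al_state <- function(dtm, seed_labels, budget = 20,
                     classifier = classifier_glmnet(),
                     strategy = c("uncertainty", "exploitation", "random")) {
  strategy <- match.arg(strategy)
  stopifnot(all(c("post_id", "label") %in% names(seed_labels)))
  if (!all(seed_labels$post_id %in% rownames(dtm))) {
    abort("seed post ids not found in the corpus.",
          class = "opinionpulse_config_error")
  }
  d_l <- setNames(as.logical(seed_labels$label), seed_labels$post_id)
  state <- structure(list(
    dtm = dtm, d_l = d_l,
    d_u = setdiff(rownames(dtm), names(d_l)),
    classifier = classifier, strategy = strategy,
    model = NULL, iteration = 0L, budget = as.integer(budget),
    terminated = FALSE, history = list()), class = "al_state")
  al_retrain(state)
}

al_retrain <- function(state) {
  y <- state$d_l
  if (length(unique(y)) < 2L) {
    abort("labeled set contains a single class; seed both classes before training.",
          class = "opinionpulse_training_error")
  }
  state$model <- state$classifier$fit(state$dtm[names(y), , drop = FALSE], y)
  state
}

#' One active-learning iteration
#'
#' Scores the unlabeled pool with the current classifier, selects the
#' `batch_size` posts with the largest selection score (ties broken by post
#' id order), labels them via the oracle, moves them from the pool to the
#' labeled set, retrains, and increments the iteration counter. An empty
#' pool returns the state unchanged with `terminated = TRUE`.
#'
#' @param state An [al_state()].
#' @param batch_size Number of posts queried per iteration.
#' @param oracle Function mapping a character vector of post ids to logical
#'   true labels (ground truth in the synthetic setting; see
#'   [oracle_from_truth()]).
#' @return The updated `al_state`.
#' @export
al_iteration <- function(state, batch_size, oracle) {
  stopifnot(inherits(state, "al_state"))
  if (length(state$d_u) == 0L) {
    state$terminated <- TRUE
    return(state)
  }
  p <- state$classifier$prob(state$model,
                             state$dtm[state$d_u, , drop = FALSE])
  score <- switch(state$strategy,
                  exploitation = p,
                  uncertainty = -abs(p - 0.5),
                  random = runif(length(p)))
  take <- head(order(-score, state$d_u), min(batch_size, length(state$d_u)))
  ids <- state$d_u[take]
  labs <- as.logical(oracle(ids))
  state$d_l <- c(state$d_l, setNames(labs, ids))
  state$d_u <- state$d_u[-take]
  state$iteration <- state$iteration + 1L
  state$history[[state$iteration]] <-
    tibble(iteration = state$iteration, n_labeled = length(state$d_l),
           n_pool = length(state$d_u), n_positive = sum(state$d_l))
  al_retrain(state)
}

#' Oracle backed by ground-truth corpus labels
#' @param posts A corpus tibble with `id` and `truth_on_topic`.
#' @return A function mapping post ids to logical labels.
#' @export
oracle_from_truth <- function(posts) {
  truth <- setNames(posts$truth_on_topic, posts$id)
  function(ids) unname(truth[ids])
}

#' Track a topic through a post stream by active learning
#'
#' Runs [al_iteration()] until the query budget or the pool is exhausted,
#' then applies the final classifier to the whole corpus and returns the
#' posts whose predicted on-topic probability reaches the decision
#' threshold.
#'
#' @param posts Tokenized corpus ([tokenize_corpus()]).
#' @param seed_labels Tibble `post_id`, `label` with both classes present.
#' @param oracle Labeling oracle; defaults to the corpus ground truth.
#' @param batch_size,budget Active-learning loop controls.
#' @param threshold Decision threshold on the final probability.
#' @param classifier,strategy Passed to [al_state()].
#' @return A list of class `topic_tracking` with elements `on_topic`
#'   (predicted on-topic post tibble), `prob` (named vector over all
#'   posts), `state` (final `al_state`) and `history`.
#' @export
track_topic <- function(posts, seed_labels, oracle = oracle_from_truth(posts),
                        batch_size = 10, budget = 20, threshold = 0.5,
                        classifier = classifier_glmnet(),
                        strategy = c("uncertainty", "exploitation", "random")) {
  strategy <- match.arg(strategy)
  dtm <- corpus_dtm(posts)
  state <- al_state(dtm, seed_labels, budget = budget,
                    classifier = classifier, strategy = strategy)
  while (state$iteration < state$budget && !state$terminated) {
    state <- al_iteration(state, batch_size, oracle)
  }
  p <- state$classifier$prob(state$model, dtm)
  names(p) <- rownames(dtm)
  keep <- p >= threshold
  out <- posts[keep, , drop = FALSE]
  for (a in c("vocab", "config")) attr(out, a) <- attr(posts, a)
  structure(list(on_topic = out, prob = p, state = state,
                 history = dplyr::bind_rows(state$history),
                 threshold = threshold),
            class = "topic_tracking")
}

#' @rdname track_topic
#' @param seeds_by_topic Named list of seed-label tibbles, one per tracked
#'   topic; the loop is run independently per topic.
#' @param ... Passed on to [track_topic()].
#' @export
track_topics <- function(posts, seeds_by_topic, ...) {
  purrr::map(seeds_by_topic, function(s) track_topic(posts, s, ...))
}

#' Binary and macro-averaged F1
#'
#' @param truth,pred Logical vectors (binary F1) or equal-length label
#'   vectors (macro F1).
#' @return A single numeric value. F1 of an empty positive set is 0.
#' @export
f1_score <- function(truth, pred) {
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @rdname f1_score
#' @export
macro_f1 <- function(truth, pred) {
  classes <- sort(unique(as.character(truth)))
  mean(vapply(classes, function(cl) {
    f1_score(as.character(truth) == cl, as.character(pred) == cl)
  }, numeric(1)))
}
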