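#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a maximum-entropy model
#' @param x A `maxent_model`.
#' @param ... Ignored.
#' @return A tibble with one row per (feature, class) weight.
#' @export
tidy.maxent_model <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x$lambda), feature = x$features),
    -"feature", names_to = "class", values_to = "estimate")
}

#' @rdname tidy.maxent_model
#' @return `glance()`: a one-row model summary.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble(n_features = length(x$features), n_classes = length(x$classes),
         log_likelihood = tail(x$ll_trace, 1), iterations = x$iterations,
         converged = x$converged)
}

#' Tidy a cross-validated Lasso fit
#' @param x A `lasso_fit`.
#' @param ... Ignored.
#' @return A tibble `term`, `estimate` at the selected penalty.
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @rdname tidy.lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble(lambda = x$lambda, n_nonzero = sum(x$beta != 0),
         cv_error = min(x$cv_curve$mean_error))
}

#' Tidy a Bayesian-network structure
#' @param x A `bn_structure`.
#' @param ... Ignored.
#' @return The edge list as a tibble.
#' @export
tidy.bn_structure <- function(x, ...) x$edges

#' @rdname tidy.bn_structure
#' @export
glance.bn_structure <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         score = x$score, moves = length(x$trajectory) - 1L)
}

#' Tidy a fitted LDA model
#' @param x An `lda_model`.
#' @param n_words Words reported per topic.
#' @param ... Ignored.
#' @return A tibble `topic`, `word`, `probability` (top words per topic).
#' @export
tidy.lda_model <- function(x, n_words = 10, ...) {
  tw <- topic_word(x)
  dplyr::bind_rows(purrr::map(seq_len(x$K), function(k) {
    ord <- order(-tw[k, ])[seq_len(min(n_words, ncol(tw)))]
    tibble(topic = k, word = x$vocab[ord], probability = tw[k, ord])
  }))
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(k = x$K, vocab_size = length(x$vocab), updates = x$t,
         docs_seen = x$docs_seen)
}
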