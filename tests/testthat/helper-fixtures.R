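# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small tokenized corpus (2 years x 100 posts/year)
small_corpus <- function() {
  memo("small_corpus", function() {
    tokenize_corpus(gen_corpus(corpus_config(n_years = 2, posts_per_year = 100,
                                             seed = 42)))
  })
}

# mid-size tokenized corpus used by tracking / sentiment tests
mid_corpus <- function(seed = 7) {
  memo(paste0("mid_corpus_", seed), function() {
    tokenize_corpus(gen_corpus(corpus_config(n_years = 3, posts_per_year = 400,
                                             seed = seed)))
  })
}

# larger corpus for the end-to-end sentiment chain (held-out posts remain
# after the 200-per-class expert seed draw)
sent_corpus <- function(seed = 23) {
  memo(paste0("sent_corpus_", seed), function() {
    tokenize_corpus(gen_corpus(corpus_config(n_years = 3, posts_per_year = 1000,
                                             seed = seed)))
  })
}

# 50-post hand-checkable labeled fixture for counting oracles
fifty_post_fixture <- function() {
  memo("fifty", function() {
    posts <- gen_corpus(corpus_config(n_years = 5, posts_per_year = 10,
                                      seed = 99))
    tokenize_corpus(posts)
  })
}

# stratified both-class seed labels for tracking
tracking_seeds <- function(posts, n = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    post_id = c(sample(posts$id[posts$truth_on_topic], n),
                sample(posts$id[!posts$truth_on_topic], n)),
    label = rep(c(TRUE, FALSE), each = n))
}

# random labeled MaxEnt instances with overlapping class profiles (finite MLE)
random_maxent_instances <- function(n = 200, J = 6, seed = 1) {
  set.seed(seed)
  classes <- c("neg", "neu", "pos")
  y <- sample(classes, n, replace = TRUE)
  means <- matrix(c(2, 1, 0.5,
                    0.5, 2, 1,
                    1, 0.5, 2), 3, 3, byrow = TRUE,
                  dimnames = list(classes, NULL))
  g <- matrix(0, n, J, dimnames = list(NULL, paste0("f", seq_len(J))))
  for (i in seq_len(n)) {
    g[i, ] <- stats::rpois(J, lambda = rep(means[y[i], ], length.out = J))
  }
  list(g = g, y = y)
}

# gradient-ascent oracle maximizing the same conditional log-likelihood as
# IIS (slack-padded design), via BFGS with the analytic gradient
maxent_oracle_probs <- function(g, y, M = NULL) {
  classes <- sort(unique(y))
  M <- M %||% max(rowSums(g), 1)
  gs <- cbind(g, pmax(M - rowSums(g), 0))
  ymat <- outer(y, classes, `==`) + 0
  J <- ncol(gs)
  C <- length(classes)
  nll <- function(l) {
    lam <- matrix(l, J, C)
    sc <- gs %*% lam
    -sum((sc - apply(sc, 1, function(r) r[1] + log(sum(exp(r - r[1]))))) * ymat)
  }
  grad <- function(l) {
    lam <- matrix(l, J, C)
    sc <- gs %*% lam
    p <- exp(sc - apply(sc, 1, max))
    p <- p / rowSums(p)
    as.numeric(-crossprod(gs, ymat - p))
  }
  opt <- stats::optim(numeric(J * C), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  lam <- matrix(opt$par, J, C)
  sc <- gs %*% lam
  p <- exp(sc - apply(sc, 1, max))
  p <- p / rowSums(p)
  colnames(p) <- classes
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
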