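two_topic_docs <- function(n = 400, len = 20, seed = 11) {
  va <- sprintf("alpha%02d", 1:30)
  vb <- sprintf("beta%02d", 1:30)
  set.seed(seed)
  docs <- lapply(seq_len(n), function(i) {
    sample(if (i %% 2 == 1) va else vb, len, replace = TRUE)
  })
  list(docs = docs, va = va, vb = vb)
}

test_that("the vocabulary grows by exactly the unseen words", {
  m <- lda_model(K = 3, vocab = c("a", "b"), seed = 1)
  expect_length(m$vocab, 2L)
  m2 <- online_lda_update(m, list(c("a", "zz"), c("b")))
  expect_length(m2$vocab, 3L)
  expect_true("zz" %in% m2$vocab)
  m3 <- online_lda_update(m2, list(c("a", "b", "zz")))
  expect_length(m3$vocab, 3L)
  expect_error(online_lda_update(m, list()),
               class = "opinionpulse_config_error")
})

test_that("a single-word corpus concentrates mass on that word", {
  docs <- rep(list(rep("only", 10)), 50)
  m <- lda_online(docs, K = 2, passes = 2, batch_size = 16, seed = 2)
  tw <- topic_word(m)
  expect_gte(max(tw[, "only"]), 0.99)
})

test_that("topic-word rows renormalize to one after every update", {
  tt <- two_topic_docs(n = 64, seed = 3)
  m <- lda_model(K = 4, seed = 3)
  for (s in seq(1, 64, by = 16)) {
    m <- online_lda_update(m, tt$docs[s:(s + 15)], total_docs = 64)
    expect_true(all(abs(rowSums(topic_word(m)) - 1) < 1e-10))
  }
})

test_that("with kappa = 0 one full batch equals a batch variational EM step", {
  tt <- two_topic_docs(n = 30, seed = 5)
  m0 <- lda_model(K = 2, kappa = 0, tau0 = 64, seed = 5)
  m0 <- opinionpulse:::lda_grow_vocab(m0, unlist(tt$docs))
  m1 <- online_lda_update(m0, tt$docs, total_docs = 30)
  # independent M-step: rho = 1, so lambda = eta + (D/S) * sstats with the
  # sufficient statistics recomputed from m0's pre-update parameters
  expEl <- exp(digamma(m0$lambda) - digamma(rowSums(m0$lambda)))
  sstats <- matrix(0, m0$K, length(m0$vocab))
  for (d in tt$docs) {
    tab <- table(d)
    ids <- match(names(tab), m0$vocab)
    cts <- as.numeric(tab)
    gamma_d <- rep(1, m0$K)
    expEt <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
    beta_d <- expEl[, ids, drop = FALSE]
    phinorm <- as.numeric(crossprod(beta_d, expEt)) + 1e-100
    for (it in 1:100) {
      last <- gamma_d
      gamma_d <- m0$alpha + expEt * as.numeric(beta_d %*% (cts / phinorm))
      expEt <- exp(digamma(gamma_d) - digamma(sum(gamma_d)))
      phinorm <- as.numeric(crossprod(beta_d, expEt)) + 1e-100
      if (mean(abs(gamma_d - last)) < 1e-3) break
    }
    sstats[, ids] <- sstats[, ids] + outer(expEt, cts / phinorm)
  }
  lambda_vem <- m0$eta + sstats * expEl
  expect_equal(unname(m1$lambda), unname(lambda_vem), tolerance = 1e-10)
})

test_that("topic ranking follows summed document-topic mass", {
  tt <- two_topic_docs(n = 200, seed = 7)
  m <- lda_online(tt$docs, K = 2, passes = 3, batch_size = 64, seed = 7)
  theta <- lda_doc_topics(m, tt$docs)
  # brute-force ranking oracle
  mass <- c(sum(theta[, 1]), sum(theta[, 2]))
  ranked <- top_topics(m, tt$docs, k = 2)
  expect_equal(ranked$topic, order(-mass))
  expect_equal(ranked$mass, sort(mass, decreasing = TRUE))
  expect_length(ranked$top_words[[1]], 10L)

  # a pure single-topic subset ranks its topic first
  tw <- topic_word(m)
  alpha_topic <- which.max(tw[, tt$va[1]])
  pure <- tt$docs[seq(1, 200, by = 2)]  # the alpha-vocabulary documents
  expect_equal(top_topics(m, pure, k = 1)$topic, alpha_topic)

  expect_error(top_topics(m, tt$docs, k = 5),
               class = "opinionpulse_config_error")
  expect_error(top_topics(m, list(), k = 1),
               class = "opinionpulse_config_error")
})

test_that("topic co-occurrence counts jointly present topics", {
  tt <- two_topic_docs(n = 30, seed = 9)
  m <- lda_online(tt$docs, K = 2, passes = 3, batch_size = 30, seed = 9)
  w <- topic_cooccurrence(m, tt$docs, theta = 0.3)
  expect_true(isSymmetric(unname(as.matrix(w))))
  expect_equal(diag(w), c(0L, 0L), ignore_attr = TRUE)
  # brute-force recount
  props <- lda_doc_topics(m, tt$docs)
  manual <- sum(props[, 1] > 0.3 & props[, 2] > 0.3)
  expect_equal(w[1, 2], manual)
  # single-topic documents produce no co-occurrence at a clear threshold
  expect_equal(max(w), 0)

  mixed <- c(tt$docs[1:5], lapply(1:5, function(i) {
    c(sample(tt$va, 10, replace = TRUE), sample(tt$vb, 10, replace = TRUE))
  }))
  w2 <- topic_cooccurrence(m, mixed, theta = 0.3)
  expect_equal(w2[1, 2], 5)

  expect_error(topic_cooccurrence(m, tt$docs, theta = 0),
               class = "opinionpulse_config_error")
  expect_error(topic_cooccurrence(m, tt$docs, theta = 1),
               class = "opinionpulse_config_error")
})

test_that("held-out predictive quality does not degrade as batches accumulate", {
  tt <- two_topic_docs(n = 300, seed = 13)
  held <- two_topic_docs(n = 60, seed = 14)$docs
  loglik <- function(m) {
    tw <- topic_word(m)
    theta <- lda_doc_topics(m, held)
    sum(vapply(seq_along(held), function(i) {
      p <- as.numeric(theta[i, ] %*% tw[, match(held[[i]], m$vocab)])
      sum(log(pmax(p, 1e-12)))
    }, numeric(1)))
  }
  m <- lda_model(K = 2, seed = 13)
  m <- online_lda_update(m, tt$docs[1:100], total_docs = 300)
  ll_early <- loglik(m)
  m <- online_lda_update(m, tt$docs[101:200], total_docs = 300)
  m <- online_lda_update(m, tt$docs[201:300], total_docs = 300)
  ll_late <- loglik(m)
  expect_gte(ll_late, ll_early - abs(0.02 * ll_early))
})

test_that("models persist to a plain-text directory", {
  tt <- two_topic_docs(n = 20, seed = 15)
  m <- lda_online(tt$docs, K = 2, passes = 1, seed = 15)
  d <- withr::local_tempdir()
  write_lda_model(m, d)
  vocab <- readr::read_csv(file.path(d, "vocab.csv"), show_col_types = FALSE)
  expect_equal(vocab$word, m$vocab)
  lam <- as.matrix(utils::read.table(file.path(d, "topic_word.txt")))
  expect_equal(unname(lam), unname(m$lambda), tolerance = 1e-12)
})
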