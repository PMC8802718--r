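# a deterministic fake classifier whose probabilities are read off a table
fixed_prob_classifier <- function(probs) {
  list(fit = function(x, y) probs,
       prob = function(model, x) unname(model[rownames(x)]))
}

test_that("an empty pool terminates the iteration unchanged", {
  tk <- small_corpus()[1:10, ]
  dtm <- corpus_dtm(tk)
  seeds <- tibble::tibble(post_id = tk$id,
                          label = tk$truth_on_topic)
  st <- al_state(dtm, seeds, budget = 5)
  expect_length(st$d_u, 0L)
  st2 <- al_iteration(st, 3, oracle_from_truth(tk))
  expect_true(st2$terminated)
  expect_equal(st2$iteration, 0L)
  expect_equal(st2$d_l, st$d_l)
})

test_that("selection takes the largest scores with id-order tie-breaks", {
  tk <- small_corpus()[1:5, ]
  dtm <- corpus_dtm(tk)
  seeds <- tibble::tibble(post_id = tk$id[4:5], label = c(TRUE, FALSE))
  probs <- stats::setNames(c(0.9, 0.8, 0.1, 1, 0), tk$id)
  st <- al_state(dtm, seeds, budget = 5,
                 classifier = fixed_prob_classifier(probs),
                 strategy = "exploitation")
  st <- al_iteration(st, 2, oracle_from_truth(tk))
  queried <- setdiff(names(st$d_l), seeds$post_id)
  expect_setequal(queried, tk$id[1:2])

  # exact ties broken by post id order
  tied <- stats::setNames(c(0.5, 0.5, 0.5, 1, 0), tk$id)
  st2 <- al_state(dtm, seeds, budget = 5,
                  classifier = fixed_prob_classifier(tied),
                  strategy = "exploitation")
  st2 <- al_iteration(st2, 2, oracle_from_truth(tk))
  expect_setequal(setdiff(names(st2$d_l), seeds$post_id), sort(tk$id[1:3])[1:2])
})

test_that("labeled and pool sets are conserved across iterations", {
  tk <- mid_corpus()
  seeds <- tracking_seeds(tk, seed = 3)
  st <- al_state(corpus_dtm(tk), seeds, budget = 5)
  total <- length(st$d_l) + length(st$d_u)
  for (i in 1:3) {
    st <- al_iteration(st, 7, oracle_from_truth(tk))
    expect_equal(length(st$d_l) + length(st$d_u), total)
    expect_length(intersect(names(st$d_l), st$d_u), 0L)
  }
  expect_equal(st$iteration, 3L)
})

test_that("a single-class labeled set is a training error", {
  tk <- small_corpus()
  seeds <- tibble::tibble(post_id = tk$id[tk$truth_on_topic][1:4],
                          label = rep(TRUE, 4))
  expect_error(al_state(corpus_dtm(tk), seeds),
               class = "opinionpulse_training_error")
})

test_that("budget zero classifies with the seed-trained model only", {
  tk <- mid_corpus()
  seeds <- tracking_seeds(tk, n = 20, seed = 5)
  tr <- track_topic(tk, seeds, budget = 0)
  expect_equal(tr$state$iteration, 0L)
  expect_equal(nrow(tr$history), 0L)
  expect_setequal(tr$on_topic$id, tk$id[tr$prob[tk$id] >= 0.5])
})

test_that("a separable corpus is tracked perfectly after convergence", {
  tk <- mid_corpus(seed = 13)
  seeds <- tracking_seeds(tk, seed = 13)
  tr <- track_topic(tk, seeds, batch_size = 10, budget = 15)
  ho <- !(tk$id %in% names(tr$state$d_l))
  pred <- tk$id %in% tr$on_topic$id
  expect_gte(f1_score(tk$truth_on_topic[ho], pred[ho]), 0.98)
  expect_gte(sum(tk$truth_on_topic & pred) / sum(tk$truth_on_topic), 0.9)
})

test_that("a full labeling budget matches fully supervised training", {
  tk <- small_corpus()
  seeds <- tracking_seeds(tk, seed = 2)
  n_pool <- nrow(tk) - nrow(seeds)
  tr <- track_topic(tk, seeds, batch_size = 50,
                    budget = ceiling(n_pool / 50) + 1)
  expect_length(tr$state$d_u, 0L)
  clf <- classifier_glmnet()
  dtm <- corpus_dtm(tk)
  full <- clf$fit(dtm, tk$truth_on_topic)
  p_full <- clf$prob(full, dtm)
  expect_equal(unname(tr$prob[tk$id]), p_full, tolerance = 1e-8)
})

test_that("multiple topics map over seed sets", {
  tk <- small_corpus()
  seeds <- tracking_seeds(tk, seed = 4)
  res <- track_topics(tk, list(tcm = seeds, again = seeds), budget = 1)
  expect_named(res, c("tcm", "again"))
  expect_s3_class(res$tcm$on_topic, "tbl_df")
})

test_that("macro F1 averages per-class F1", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  f_a <- f1_score(truth == "a", pred == "a")
  f_b <- f1_score(truth == "b", pred == "b")
  f_c <- f1_score(truth == "c", pred == "c")
  expect_equal(macro_f1(truth, pred), mean(c(f_a, f_b, f_c)))
  expect_equal(f1_score(c(TRUE, FALSE), c(FALSE, FALSE)), 0)
})
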