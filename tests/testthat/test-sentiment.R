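mk_tok <- function(tokens, tags) {
  tibble::tibble(id = sprintf("d%03d", seq_along(tokens)),
                 tokens = tokens, pos_tags = tags)
}

test_that("lexicon bootstrap applies document-frequency and window rules", {
  empty <- tibble::tibble(id = character(), tokens = list(), pos_tags = list())
  lx <- bootstrap_lexicon(empty)
  expect_length(lx$entity_words, 0L)
  expect_length(lx$sentiment_words, 0L)

  # a NOUN seen once with f_min = 2 is excluded
  tk <- mk_tok(list(c("herb", "nice"), c("stone", "nice")),
               list(c("NOUN", "ADJ"), c("NOUN", "ADJ")))
  lx <- bootstrap_lexicon(tk, f_min = 2, c_min = 1)
  expect_length(lx$entity_words, 0L)

  # every ADJ adjacent to a frequent NOUN becomes a sentiment word
  tk2 <- mk_tok(list(c("herb", "nice"), c("herb", "fine"), c("herb", "nice")),
                list(c("NOUN", "ADJ"), c("NOUN", "ADJ"), c("NOUN", "ADJ")))
  lx2 <- bootstrap_lexicon(tk2, f_min = 2, c_min = 1, window = 3)
  expect_equal(lx2$entity_words, "herb")
  expect_setequal(lx2$sentiment_words, c("nice", "fine"))

  # outside the window the ADJ is not picked up
  far <- mk_tok(list(c("herb", "x", "x", "x", "x", "nice"),
                     c("herb", "y", "y", "y", "y", "nice")),
                list(c("NOUN", rep("OTHER", 4), "ADJ"),
                     c("NOUN", rep("OTHER", 4), "ADJ")))
  lx3 <- bootstrap_lexicon(far, f_min = 2, c_min = 1, window = 3)
  expect_length(lx3$sentiment_words, 0L)
})

test_that("feature extraction counts lexicon tokens, emoticons and punctuation", {
  lex <- list(entity_words = c("herb"), sentiment_words = c("nice", "awful"))
  expect_length(extract_features(c("x", "y"), lex), 0L)
  fv <- extract_features(c("nice"), lex)
  expect_equal(fv, c("sent:nice" = 1))
  fv2 <- extract_features(c("herb", "nice", "nice", ":)", "!", "!", "?"), lex)
  expect_equal(fv2[["sent:nice"]], 2)
  expect_equal(fv2[["ent:herb"]], 1)
  expect_equal(fv2[["emo_pos"]], 1)
  expect_equal(fv2[["punct_exclam"]], 2)
  expect_equal(fv2[["punct_question"]], 1)
})

test_that("the corpus feature matrix equals per-post brute-force counts", {
  tk <- mid_corpus()[1:100, ]
  lex <- bootstrap_lexicon(tk)
  g <- features_matrix(tk, lex)
  for (i in seq(1, 100, by = 9)) {
    fv <- extract_features(tk$tokens[[i]], lex)
    row <- g[i, ]
    expect_equal(unname(row[names(fv)]), unname(fv))
    expect_equal(sum(row), sum(fv))
  }
})

test_that("opinion-graph polarities match their defining counts", {
  lex <- list(entity_words = "herb", sentiment_words = c("nice", "bad"))
  tk <- mk_tok(list(c("herb", "nice"), c("nice"), c("herb", "bad"),
                    c("nice", "bad"), c("herb")),
               list(c("NOUN", "ADJ"), "ADJ", c("NOUN", "ADJ"),
                    c("ADJ", "ADJ"), "NOUN"))
  labels <- c("pos", "pos", "neg", "neg", "neu")
  gph <- build_okg(tk, labels, lex, gamma = 0)
  pol <- stats::setNames(gph$nodes$polarity, gph$nodes$token)
  expect_equal(pol[["nice"]], (2 - 1) / 3)   # 2 pos, 1 neg
  expect_equal(pol[["bad"]], (0 - 2) / 2)    # 0 pos, 2 neg
  expect_equal(pol[["herb"]], 0)             # 1 pos, 1 neg

  only_pos <- build_okg(tk[1:2, ], c("pos", "pos"), lex, gamma = 0)
  expect_equal(only_pos$nodes$polarity[only_pos$nodes$token == "nice"], 1)

  empty <- build_okg(tk[0, ], character(0), lex)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("graph polarity equals a brute-force recount on the 50-post fixture", {
  tk <- fifty_post_fixture()
  on <- tk[tk$truth_on_topic, ]
  lex <- list(entity_words = sprintf("ent%03d", 1:40),
              sentiment_words = c(sprintf("pos%03d", 1:30),
                                  sprintf("neg%03d", 1:30)))
  labels <- on$truth_sentiment
  gph <- build_okg(on, labels, lex, gamma = 1)
  for (i in seq_len(nrow(gph$nodes))) {
    tok <- gph$nodes$token[i]
    contains <- vapply(on$tokens, function(t) tok %in% t, logical(1))
    np <- sum(contains & labels == "pos")
    nn <- sum(contains & labels == "neg")
    expect_equal(gph$nodes$n_pos[i], np)
    expect_equal(gph$nodes$n_neg[i], nn)
    expect_equal(gph$nodes$polarity[i], (np - nn) / (np + nn + 1))
  }
  # edge weights: brute-force pairwise co-occurrence
  if (nrow(gph$edges) > 0) {
    for (j in seq(1, nrow(gph$edges), by = 23)) {
      a <- gph$edges$from[j]; b <- gph$edges$to[j]
      w <- sum(vapply(on$tokens, function(t) (a %in% t) && (b %in% t),
                      logical(1)))
      expect_equal(gph$edges$weight[j], w)
    }
  }
})

test_that("polarity stays bounded for arbitrary label assignments", {
  tk <- mid_corpus()[1:150, ]
  lex <- bootstrap_lexicon(tk)
  set.seed(5)
  for (rep in 1:5) {
    labels <- sample(c("pos", "neg", "neu"), nrow(tk), replace = TRUE)
    gph <- build_okg(tk, labels, lex, gamma = sample(c(0, 1, 2), 1))
    expect_true(all(gph$nodes$polarity >= -1 & gph$nodes$polarity <= 1))
    expect_true(all(gph$edges$weight >= 0))
    expect_true(all(gph$edges$from != gph$edges$to))
  }
})

test_that("stance propagation labels by the signed score with a neutral band", {
  lex <- list(entity_words = character(0), sentiment_words = c("good", "bad"))
  tk <- mk_tok(list(rep("good", 3), rep("bad", 3)),
               list(rep("ADJ", 3), rep("ADJ", 3)))
  gph <- build_okg(tk, c("pos", "neg"), lex, gamma = 0)
  # single strongly positive node
  expect_equal(propagate_stance(gph, c("good", "zzz"), z_gate = 0)$stance, "pos")
  expect_equal(propagate_stance(gph, "bad", z_gate = 0)$stance, "neg")
  # no overlap with the graph
  r <- propagate_stance(gph, c("a", "b"))
  expect_equal(r$stance, "neu")
  expect_equal(r$score, 0)
  # mirror-symmetric post: equal-magnitude opposite nodes cancel
  r2 <- propagate_stance(gph, c("good", "bad"), z_gate = 0)
  expect_equal(r2$score, 0)
  expect_equal(r2$stance, "neu")
})

test_that("the full sentiment chain recovers labels on a separable corpus", {
  tk <- sent_corpus(seed = 23)
  on <- tk[tk$truth_on_topic, ]
  lab <- classify_corpus(on, seed = 2)
  ho <- !(lab$id %in% attr(lab, "seed_ids"))
  expect_gte(macro_f1(lab$truth_sentiment[ho], lab$stance[ho]), 0.9)

  # neutral-truth-only corpus stays neutral
  neu <- on[on$truth_sentiment == "neu", ]
  lab2 <- classify_corpus(neu, seed = 2)
  expect_gte(mean(lab2$stance == "neu"), 0.95)

  # empty corpus passes through
  lab3 <- classify_corpus(on[0, ])
  expect_equal(nrow(lab3), 0L)
  expect_true(all(c("stance", "score") %in% names(lab3)))
})

test_that("maxent-only ablation also labels the separable corpus well", {
  tk <- sent_corpus(seed = 29)
  on <- tk[tk$truth_on_topic, ]
  lab <- classify_corpus(on, arbiter = "maxent", seed = 3)
  ho <- !(lab$id %in% attr(lab, "seed_ids"))
  expect_gte(macro_f1(lab$truth_sentiment[ho], lab$stance[ho]), 0.9)
})

test_that("end-to-end yearly label proportions recover the generator trend", {
  trend <- sentiment_trend_geometric(n_years = 3, start_year = 2004)
  posts <- gen_corpus(corpus_config(n_years = 3, posts_per_year = 1000,
                                    sentiment_trend = trend, seed = 37))
  tk <- tokenize_corpus(posts)
  on <- tk[tk$truth_on_topic, ]
  lab <- classify_corpus(on, seed = 37)
  yr <- as.integer(format(lab$timestamp, "%Y"))
  for (y in trend$year) {
    emp <- prop.table(table(factor(lab$stance[yr == y],
                                   levels = c("pos", "neg", "neu"))))
    row <- trend[trend$year == y, ]
    expect_lt(abs(emp[["pos"]] - row$p_pos), 0.05)
    expect_lt(abs(emp[["neg"]] - row$p_neg), 0.05)
  }
})
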