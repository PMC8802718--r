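test_that("corpus generation conserves counts and honors the on-topic fraction", {
  cfg <- corpus_config(n_years = 10, posts_per_year = 100, seed = 1)
  posts <- gen_corpus(cfg)
  expect_equal(nrow(posts), 1000L)
  expect_equal(sum(posts$truth_on_topic), 500L)

  none <- gen_corpus(corpus_config(n_years = 3, posts_per_year = 50,
                                   frac_on_topic = 0, seed = 2))
  expect_equal(sum(none$truth_on_topic), 0L)
  expect_true(all(none$truth_sentiment == "neu"))
})

test_that("the same seed reproduces byte-identical JSONL output", {
  cfg <- corpus_config(n_years = 2, posts_per_year = 40, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_posts_jsonl(gen_corpus(cfg), f1)
  write_posts_jsonl(gen_corpus(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  back <- read_posts_jsonl(f1)
  orig <- gen_corpus(cfg)
  expect_equal(back$text, orig$text)
  expect_equal(back$truth_sentiment, orig$truth_sentiment)
  # the JSONL timestamp format truncates to whole seconds
  expect_equal(as.numeric(back$timestamp), floor(as.numeric(orig$timestamp)))
})

test_that("invalid corpus configurations are rejected", {
  expect_error(corpus_config(frac_on_topic = 1.2),
               class = "opinionpulse_config_error")
  bad_trend <- tibble::tibble(year = 2004:2013, p_pos = 0.8, p_neg = 0.3,
                              p_neutral = -0.1)
  expect_error(corpus_config(sentiment_trend = bad_trend),
               class = "opinionpulse_config_error")
})

test_that("yearly sentiment proportions match the configured trend", {
  trend <- sentiment_trend_geometric(n_years = 2, start_year = 2004)
  posts <- gen_corpus(corpus_config(n_years = 2, posts_per_year = 10000,
                                    sentiment_trend = trend, seed = 3))
  on <- posts[posts$truth_on_topic, ]
  yr <- as.integer(format(on$timestamp, "%Y"))
  for (y in unique(trend$year)) {
    emp <- prop.table(table(factor(on$truth_sentiment[yr == y],
                                   levels = c("pos", "neg", "neu"))))
    cfg_row <- trend[trend$year == y, ]
    expect_lt(abs(emp[["pos"]] - cfg_row$p_pos), 0.02)
    expect_lt(abs(emp[["neg"]] - cfg_row$p_neg), 0.02)
    expect_lt(abs(emp[["neu"]] - cfg_row$p_neutral), 0.02)
  }
})

test_that("panel has the configured dimensions and exact national growth", {
  panel <- gen_panel(panel_config(seed = 7))
  expect_equal(nrow(panel), 34L * 11L)
  expect_equal(length(setdiff(names(panel), c("region", "year", "visits"))), 30L)

  cfg <- panel_config(noise_sd = 0, seed = 5)
  panel2 <- gen_panel(cfg)
  totals <- tapply(panel2$visits, panel2$year, sum)
  ratios <- totals[-1] / totals[-length(totals)]
  expect_equal(as.numeric(ratios), rep(cfg$visits_growth, 10),
               tolerance = 1e-10)
})

test_that("OLS on log-visits recovers the signs of the true effects", {
  cfg <- panel_config(seed = 11)
  panel <- gen_panel(cfg)
  x <- scale(as.matrix(panel[, cfg$factors]))
  fit <- stats::lm(log(panel$visits) ~ x)
  coefs <- stats::setNames(coef(fit)[-1], cfg$factors)
  truth <- attr(panel, "true_beta")
  for (f in names(truth[truth != 0])) {
    expect_equal(sign(coefs[[f]]), sign(truth[[f]]))
  }
  # noiseless limit: OLS recovers the effects numerically
  cfg0 <- panel_config(noise_sd = 0, seed = 12)
  p0 <- gen_panel(cfg0)
  x0 <- scale(as.matrix(p0[, cfg0$factors]))
  # remove the deterministic year trend and region effect via dummies
  fit0 <- stats::lm(log(p0$visits) ~ x0 + factor(p0$year) + factor(p0$region))
  b0 <- stats::setNames(coef(fit0)[2:(1 + length(cfg0$factors))], cfg0$factors)
  # perfect fit up to the sample standardization of the factor columns
  expect_equal(suppressWarnings(summary(fit0))$r.squared, 1, tolerance = 1e-9)
  expect_equal(unname(b0[c("gdp", "education")]),
               unname(attr(p0, "true_beta")[c("gdp", "education")]),
               tolerance = 0.15)
})

test_that("panel configuration invariants are enforced", {
  expect_error(panel_config(true_beta = c(gdp = 1)),
               class = "opinionpulse_config_error")
  expect_error(panel_config(true_beta = c(nonexistent = 1, gdp = 1)),
               class = "opinionpulse_config_error")
  expect_error(panel_config(noise_sd = -1),
               class = "opinionpulse_config_error")
})

test_that("visit records follow the configured age mixture", {
  expect_equal(nrow(gen_visit_records(visit_config(n_records = 0))), 0L)

  single <- visit_config(n_records = 500,
                         age_mixture = tibble::tibble(lo = 25, hi = 35,
                                                      weight = 1),
                         seed = 2)
  rec <- gen_visit_records(single)
  expect_true(all(rec$age >= 25 & rec$age <= 35))

  expect_error(visit_config(age_mixture = tibble::tibble(
    lo = c(0, 10), hi = c(5, 20), weight = c(1.5, -0.5))),
    class = "opinionpulse_config_error")

  # modal 5-year band of the default mixture sits inside 25-35: compare the
  # empirical histogram against the mixture density evaluated directly
  cfg <- visit_config(n_records = 50000, seed = 4)
  rec <- gen_visit_records(cfg)
  mix <- cfg$age_mixture
  dens <- function(age) {
    sum(mix$weight * (age >= mix$lo & age <= mix$hi) / (mix$hi - mix$lo + 1))
  }
  grid_starts <- seq(0, 85, by = 5)
  true_mass <- vapply(grid_starts, function(s) {
    sum(vapply(s:(s + 4), dens, numeric(1)))
  }, numeric(1))
  expect_true(grid_starts[which.max(true_mass)] >= 25 &&
                grid_starts[which.max(true_mass)] + 4 <= 35)
  emp <- vapply(grid_starts, function(s) sum(rec$age >= s & rec$age <= s + 4),
                numeric(1))
  modal <- grid_starts[which.max(emp)]
  expect_true(modal >= 25 && modal + 4 <= 35)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_corpus(corpus_config(n_years = 1, posts_per_year = 30,
                                            seed = 21))$text,
                   gen_corpus(corpus_config(n_years = 1, posts_per_year = 30,
                                            seed = 21))$text)
  expect_identical(gen_panel(panel_config(seed = 21))$visits,
                   gen_panel(panel_config(seed = 21))$visits)
  expect_identical(gen_visit_records(visit_config(n_records = 100, seed = 21)),
                   gen_visit_records(visit_config(n_records = 100, seed = 21)))
})
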