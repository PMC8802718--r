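#' Configure a synthetic labeled post corpus
#'
#' Builds the configuration object consumed by [gen_corpus()]. The generator
#' emulates a multi-year social-media stream in a synthetic language:
#' space-delimited tokens drawn from four pairwise-disjoint vocabularies
#' (topic entities, positive opinion words, negative opinion words, and
#' off-topic filler), plus signed emoticons and expressive punctuation.
#' Each post carries ground-truth fields: whether it is on the tracked topic
#' and, for on-topic posts, its sentiment label.
#'
#' Yearly sentiment labels are allocated by exact largest-remainder
#' composition against `sentiment_trend` (then shuffled across posts), so the
#' configured proportions are the exact ground truth of the generated stream
#' at any corpus size, not just in expectation.
#'
#' @param n_years Number of years in the stream.
#' @param posts_per_year Posts generated per calendar year.
#' @param start_year First calendar year.
#' @param frac_on_topic Fraction of each year's posts that are on-topic.
#' @param sentiment_trend Data frame with columns `year`, `p_pos`, `p_neg`,
#'   `p_neutral` (each row summing to 1), one row per year. Default: a flat
#'   trend with equal thirds. See [sentiment_trend_geometric()] for the
#'   calibrated rising-criticism trend.
#' @param lexicon_sizes Named list/vector with entries `entity`, `positive`,
#'   `negative`, `filler` giving vocabulary sizes.
#' @param emoticon_rate Probability that a polar on-topic post carries a
#'   signed emoticon.
#' @param punct_rate Probability that a polar post carries an exclamation
#'   mark (negative and neutral posts may also carry question marks at half
#'   this rate).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A list of class `corpus_config`.
#' @seealso [gen_corpus()], [headline_config()]
#' @export
corpus_config <- function(n_years = 10, posts_per_year = 500, start_year = 2004,
                          frac_on_topic = 0.5, sentiment_trend = NULL,
                          lexicon_sizes = c(entity = 40, positive = 30,
                                            negative = 30, filler = 400),
                          emoticon_rate = 0.3, punct_rate = 0.3, seed = 1) {
  n_years <- check_count(n_years, "n_years", min = 1L)
  posts_per_year <- check_count(posts_per_year, "posts_per_year", min = 0L)
  check_proportion(frac_on_topic, "frac_on_topic")
  check_proportion(emoticon_rate, "emoticon_rate")
  check_proportion(punct_rate, "punct_rate")
  years <- start_year + seq_len(n_years) - 1L
  if (is.null(sentiment_trend)) {
    sentiment_trend <- tibble(year = years, p_pos = 1 / 3, p_neg = 1 / 3,
                              p_neutral = 1 / 3)
  }
  sentiment_trend <- as_tibble(sentiment_trend)
  need <- c("year", "p_pos", "p_neg", "p_neutral")
  if (!all(need %in% names(sentiment_trend))) {
    abort("`sentiment_trend` needs columns year, p_pos, p_neg, p_neutral.",
          class = "opinionpulse_config_error")
  }
  if (!all(years %in% sentiment_trend$year)) {
    abort("`sentiment_trend` must cover every corpus year.",
          class = "opinionpulse_config_error")
  }
  props <- as.matrix(sentiment_trend[, c("p_pos", "p_neg", "p_neutral")])
  if (any(props < 0 | props > 1) || any(abs(rowSums(props) - 1) > 1e-6)) {
    abort("sentiment proportions must lie in [0, 1] and sum to 1 per year.",
          class = "opinionpulse_config_error")
  }
  sizes <- as.list(lexicon_sizes)
  for (nm in c("entity", "positive", "negative", "filler")) {
    sizes[[nm]] <- check_count(sizes[[nm]] %||% NA, paste0("lexicon_sizes$", nm),
                               min = 1L)
  }
  structure(list(n_years = n_years, posts_per_year = posts_per_year,
                 start_year = as.integer(start_year), years = years,
                 frac_on_topic = frac_on_topic,
                 sentiment_trend = sentiment_trend, lexicon_sizes = sizes,
                 emoticon_rate = emoticon_rate, punct_rate = punct_rate,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Geometric rising-criticism sentiment trend
#'
#' Yearly sentiment proportions in which the negative/positive ratio rises
#' geometrically from `start_ratio` to `start_ratio * fold` over `n_years`,
#' with the neutral share held constant. The end-to-start ratio of yearly
#' negative/positive ratios is then exactly `fold` — the ground-truth
#' Opinion Polarity Ratio trend of a corpus generated from it.
#'
#' @param n_years,start_year Years covered.
#' @param start_ratio Negative/positive ratio in the first year.
#' @param fold Total fold-change of that ratio over the period.
#' @param p_neutral Constant neutral share.
#' @return A tibble usable as `sentiment_trend` in [corpus_config()].
#' @export
sentiment_trend_geometric <- function(n_years = 10, start_year = 2004,
                                      start_ratio = 0.6, fold = 2.33,
                                      p_neutral = 0.35) {
  check_proportion(p_neutral, "p_neutral")
  r <- start_ratio * fold^((seq_len(n_years) - 1) / (n_years - 1))
  tibble(year = start_year + seq_len(n_years) - 1L,
         p_pos = (1 - p_neutral) / (1 + r),
         p_neg = (1 - p_neutral) * r / (1 + r),
         p_neutral = p_neutral)
}

# Disjoint synthetic vocabularies plus the exact POS-tag lexicon.
# Filler words get mixed tags (some NOUN/VERB) so lexicon bootstrapping has
# non-trivial candidates to filter.
build_vocab <- function(sizes) {
  entity <- sprintf("ent%03d", seq_len(sizes$entity))
  positive <- sprintf("pos%03d", seq_len(sizes$positive))
  negative <- sprintf("neg%03d", seq_len(sizes$negative))
  filler <- sprintf("fil%03d", seq_len(sizes$filler))
  fidx <- seq_along(filler)
  filler_tag <- ifelse(fidx %% 5L == 0L, "NOUN",
                       ifelse(fidx %% 7L == 0L, "VERB", "OTHER"))
  tag_lexicon <- tibble(
    token = c(entity, positive, negative, filler),
    tag = c(rep("NOUN", length(entity)), rep("ADJ", length(positive)),
            rep("ADJ", length(negative)), filler_tag)
  )
  list(entity = entity, positive = positive, negative = negative,
       filler = filler, emoticons_pos = c(":)", ":D"),
       emoticons_neg = c(":(", ":/"), tag_lexicon = tag_lexicon)
}

#' Generate a labeled synthetic post corpus
#'
#' Draws a multi-year post stream per the configuration: each year contains
#' exactly `round(frac_on_topic * posts_per_year)` on-topic posts whose
#' sentiment labels follow the configured yearly proportions exactly
#' (largest-remainder allocation, shuffled over posts). On-topic posts mix
#' entity tokens, label-matched opinion words (positive/negative posts carry
#' at least one) and filler; neutral posts carry entities and filler but no
#' polarity words; off-topic posts draw from filler only. Polar posts may
#' carry signed emoticons and expressive punctuation. A small fraction of
#' posts embeds user mentions, URLs or email addresses to exercise
#' protected-token extraction. Timestamps are uniform within each year.
#'
#' @param config A [corpus_config()].
#' @return A tibble with columns `id`, `user`, `timestamp`, `text`,
#'   `truth_on_topic`, `truth_sentiment` (`"pos"`, `"neg"`, `"neu"`;
#'   off-topic posts are `"neu"`). The vocabulary (including the exact
#'   tag lexicon) is attached as attribute `"vocab"`, the config as
#'   `"config"`.
#' @examples
#' posts <- gen_corpus(corpus_config(n_years = 2, posts_per_year = 50))
#' dplyr::count(posts, truth_on_topic, truth_sentiment)
#' @export
gen_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  vocab <- build_vocab(config$lexicon_sizes)
  trend <- config$sentiment_trend
  n <- config$posts_per_year

  with_seed(config$seed, {
    rows <- purrr::map(config$years, function(yr) {
      if (n == 0L) {
        return(NULL)
      }
      n_on <- as.integer(round(config$frac_on_topic * n))
      p <- trend[trend$year == yr, c("p_pos", "p_neg", "p_neutral")]
      cnt <- allocate_counts(n_on, as.numeric(p))
      labels <- sample(rep(c("pos", "neg", "neu"), times = cnt))
      on_topic <- c(rep(TRUE, n_on), rep(FALSE, n - n_on))
      sentiment <- c(labels, rep("neu", n - n_on))
      ord <- sample.int(n)
      on_topic <- on_topic[ord]
      sentiment <- sentiment[ord]
      text <- vapply(seq_len(n), function(i) {
        compose_post(on_topic[i], sentiment[i], vocab,
                     config$emoticon_rate, config$punct_rate)
      }, character(1))
      t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yr), tz = "UTC")
      t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yr + 1L), tz = "UTC")
      ts <- t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs"))
      tibble(year = yr, user = sprintf("@user%04d", sample.int(max(n %/% 5L, 1L), n,
                                                               replace = TRUE)),
             timestamp = ts, text = text,
             truth_on_topic = on_topic, truth_sentiment = sentiment)
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) > 0) {
      out <- dplyr::mutate(out, id = sprintf("p%06d", dplyr::row_number()),
                           .before = 1)
      out$year <- NULL
    } else {
      out <- tibble(id = character(), user = character(),
                    timestamp = as.POSIXct(character(), tz = "UTC"),
                    text = character(), truth_on_topic = logical(),
                    truth_sentiment = character())
    }
    attr(out, "vocab") <- vocab
    attr(out, "config") <- config
    out
  })
}

# One synthetic post as a token string.
compose_post <- function(on_topic, sentiment, vocab, emoticon_rate, punct_rate) {
  len <- sample(8:16, 1L)
  if (on_topic) {
    n_ent <- 2L + stats::rbinom(1L, 3L, 0.5)
    n_sent <- if (sentiment == "neu") 0L else sample(1:3, 1L)
    n_fill <- max(len - n_ent - n_sent, 1L)
    toks <- c(sample(vocab$entity, n_ent, replace = TRUE),
              if (n_sent > 0) {
                pool <- if (sentiment == "pos") vocab$positive else vocab$negative
                sample(pool, n_sent, replace = TRUE)
              },
              sample(vocab$filler, n_fill, replace = TRUE))
    toks <- sample(toks)
  } else {
    toks <- sample(vocab$filler, len, replace = TRUE)
  }
  u <- runif(3)
  if (u[1] < 0.05) toks <- c(toks, sprintf("@user%04d", sample.int(9999L, 1L)))
  if (u[2] < 0.03) toks <- c(toks, sprintf("http://t.example/%03d", sample.int(999L, 1L)))
  if (u[3] < 0.02) toks <- c(toks, sprintf("u%02d@mail.example", sample.int(99L, 1L)))
  tail_bits <- character(0)
  v <- runif(2)
  if (sentiment %in% c("pos", "neg") && v[1] < emoticon_rate) {
    pool <- if (sentiment == "pos") vocab$emoticons_pos else vocab$emoticons_neg
    tail_bits <- c(tail_bits, sample(pool, 1L))
  }
  if (sentiment %in% c("pos", "neg") && v[2] < punct_rate) {
    tail_bits <- c(tail_bits, "!")
  } else if (sentiment == "neu" && v[2] < punct_rate / 2) {
    tail_bits <- c(tail_bits, "?")
  }
  paste(c(toks, tail_bits), collapse = " ")
}

#' Read and write post corpora as JSON Lines
#'
#' One UTF-8 JSON record per line with fields `id`, `user`, `timestamp`
#' (ISO-8601), `text` and ground-truth fields nested under `truth`.
#' Writing the same corpus twice yields byte-identical files.
#'
#' @param posts A post tibble as returned by [gen_corpus()].
#' @param path File path.
#' @return `write_posts_jsonl()` returns `path` invisibly;
#'   `read_posts_jsonl()` returns a post tibble.
#' @export
write_posts_jsonl <- function(posts, path) {
  df <- data.frame(id = posts$id, user = posts$user,
                   timestamp = format(posts$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                   text = posts$text, stringsAsFactors = FALSE)
  df$truth <- data.frame(on_topic = posts$truth_on_topic,
                         sentiment = posts$truth_sentiment,
                         stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE, flatten = TRUE)
  tibble(id = df$id, user = df$user,
         timestamp = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC"),
         text = df$text,
         truth_on_topic = df[["truth.on_topic"]],
         truth_sentiment = df[["truth.sentiment"]])
}

#' Load the shipped headline-trend study configuration
#'
#' The package ships a calibrated default configuration
#' (`extdata/headline_trend.yaml`): a 10-year, 2,000-posts/year corpus whose
#' ground-truth yearly negative/positive ratio rises 2.33-fold, and a
#' 34-region 2004-2014 panel whose national visit total grows 2.41-fold.
#' The calibration constants live in the YAML file, not in code.
#'
#' @param path Optional path to an alternative YAML file.
#' @return A list with elements `corpus` ([corpus_config()]),
#'   `panel` ([panel_config()]) and `visits` ([visit_config()]).
#' @export
headline_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "headline_trend.yaml",
                                package = "opinionpulse", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  cc <- raw$corpus
  trend <- dplyr::bind_rows(cc$sentiment_trend)
  corpus <- corpus_config(
    n_years = cc$n_years, posts_per_year = cc$posts_per_year,
    start_year = cc$start_year, frac_on_topic = cc$frac_on_topic,
    sentiment_trend = trend, lexicon_sizes = cc$lexicon_sizes,
    emoticon_rate = cc$emoticon_rate, punct_rate = cc$punct_rate,
    seed = cc$seed)
  pc <- raw$panel
  panel <- panel_config(
    n_regions = pc$n_regions, start_year = pc$start_year,
    end_year = pc$end_year, n_factors = pc$n_factors,
    true_beta = unlist(pc$true_beta), noise_sd = pc$noise_sd,
    visits_growth = pc$visits_growth, base_total_visits = pc$base_total_visits,
    seed = pc$seed)
  vc <- raw$visits
  mix <- dplyr::bind_rows(vc$age_mixture)
  visits <- visit_config(n_records = vc$n_records, age_mixture = mix,
                         seed = vc$seed)
  list(corpus = corpus, panel = panel, visits = visits)
}
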