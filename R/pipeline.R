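#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's configuration (by default the shipped
#' headline-trend study configuration), the stage toggles, the per-stage
#' seeds and the output directory into one reproducible run description.
#'
#' @param out_dir Directory for stage artifacts (created on run).
#' @param seed Base seed; stage seeds are derived from it unless set
#'   explicitly in the stage blocks.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("generate", "preprocess", "track", "classify", "metrics",
#'   "topics", "factors")`.
#' @param corpus,panel,visits Generator configs; default from
#'   [headline_config()].
#' @param tracking,sentiment,topics,factors Named lists of stage
#'   parameters overriding the defaults of [track_topic()],
#'   [classify_corpus()], [lda_online()]/[top_topics()] and
#'   [lasso_cv()]/[learn_bn()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("pulse_run_"), seed = 1,
                       stages = c("generate", "preprocess", "track",
                                  "classify", "metrics", "topics", "factors"),
                       corpus = NULL, panel = NULL, visits = NULL,
                       tracking = list(), sentiment = list(),
                       topics = list(), factors = list()) {
  all_stages <- c("generate", "preprocess", "track", "classify", "metrics",
                  "topics", "factors")
  if (!all(stages %in% all_stages)) {
    abort("unknown stage name.", class = "opinionpulse_config_error")
  }
  base <- headline_config()
  corpus <- corpus %||% base$corpus
  panel <- panel %||% base$panel
  visits <- visits %||% base$visits
  corpus$seed <- as.integer(seed)
  panel$seed <- as.integer(seed)
  visits$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 corpus = corpus, panel = panel, visits = visits,
                 tracking = tracking, sentiment = sentiment,
                 topics = topics, factors = factors),
            class = "run_config")
}

# The hash covers the scientific configuration only, not where artifacts
# are written, so identical runs into different directories agree.
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

stage_requires <- function(bundle, stage, deps) {
  missing <- deps[!deps %in% names(bundle$artifacts)]
  if (length(missing)) {
    abort(sprintf("stage '%s' requires missing upstream stage artifact(s): %s",
                  stage, paste(missing, collapse = ", ")),
          class = "opinionpulse_dependency_error")
  }
}

#' Execute the full analysis pipeline
#'
#' Runs the enabled stages in dependency order — generate synthetic inputs,
#' tokenize, track the topic, classify sentiment, compute the OPR series
#' and trend ratios, mine polarity topics, and attribute visits to panel
#' factors — writing one plain-text artifact set per stage plus a JSON
#' report index carrying provenance (config hash, seeds). Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `pulse_report` with the stage results
#'   (`opr_series`, `trend_ratios`, `lasso`, `bn_blanket`, `top_topics`,
#'   `cooccurrence`, `age_histogram`, `provenance`, plus the intermediate
#'   `artifacts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) s %in% config$stages
  bundle <- list(artifacts = list(),
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   stages = config$stages,
                                   package_version =
                                     as.character(utils::packageVersion("opinionpulse"))))

  if (on("generate")) {
    bundle$artifacts$corpus <- gen_corpus(config$corpus)
    bundle$artifacts$panel <- gen_panel(config$panel)
    bundle$artifacts$visit_records <- gen_visit_records(config$visits)
    readr::write_csv(bundle$artifacts$panel, file.path(config$out_dir, "panel.csv"))
    readr::write_csv(bundle$artifacts$visit_records,
                     file.path(config$out_dir, "visit_records.csv"))
  }
  if (on("preprocess")) {
    stage_requires(bundle, "preprocess", "corpus")
    bundle$artifacts$tokenized <- tokenize_corpus(bundle$artifacts$corpus)
  }
  if (on("track")) {
    stage_requires(bundle, "track", "tokenized")
    tk <- bundle$artifacts$tokenized
    seeds <- with_seed(config$seed, {
      pos <- sample(tk$id[tk$truth_on_topic], 5)
      neg <- sample(tk$id[!tk$truth_on_topic], 5)
      tibble(post_id = c(pos, neg),
             label = rep(c(TRUE, FALSE), each = 5))
    })
    args <- c(list(posts = tk, seed_labels = seeds), config$tracking)
    bundle$artifacts$tracking <- do.call(track_topic, args)
  }
  if (on("classify")) {
    stage_requires(bundle, "classify", "tracking")
    args <- c(list(posts = bundle$artifacts$tracking$on_topic,
                   seed = config$seed), config$sentiment)
    bundle$artifacts$labeled <- do.call(classify_corpus, args)
  }
  if (on("metrics")) {
    stage_requires(bundle, "metrics", "labeled")
    series <- opr_series(bundle$artifacts$labeled)
    bundle$opr_series <- series
    bundle$trend_ratios <- list(opr = trend_ratio(series))
    if (!is.null(bundle$artifacts$panel)) {
      yearly <- dplyr::summarise(dplyr::group_by(bundle$artifacts$panel,
                                                 .data$year),
                                 visits = sum(.data$visits), .groups = "drop")
      bundle$visits_by_year <- yearly
      bundle$trend_ratios$visits <- trend_ratio(yearly, "visits")
    }
    write_opr_outputs(series, file.path(config$out_dir, "opr_series.csv"),
                      file.path(config$out_dir, "opr_summary.json"))
  }
  if (on("topics")) {
    stage_requires(bundle, "topics", "labeled")
    lab <- bundle$artifacts$labeled
    topt <- config$topics
    K <- topt$K %||% 10
    model <- lda_online(lab, K = K, passes = topt$passes %||% 2,
                        batch_size = topt$batch_size %||% 256,
                        seed = config$seed)
    theta <- topt$theta %||% 0.2
    pos_docs <- lab$tokens[lab$stance == "pos"]
    neg_docs <- lab$tokens[lab$stance == "neg"]
    bundle$top_topics <- list(
      positive = top_topics(model, pos_docs, k = min(5, K)),
      negative = top_topics(model, neg_docs, k = min(5, K)))
    bundle$cooccurrence <- list(
      positive = topic_cooccurrence(model, pos_docs, theta = theta),
      negative = topic_cooccurrence(model, neg_docs, theta = theta))
    bundle$artifacts$lda <- model
    write_lda_model(model, file.path(config$out_dir, "lda_model"))
    for (pol in c("positive", "negative")) {
      w <- bundle$cooccurrence[[pol]]
      idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
      readr::write_csv(tibble(topic_i = idx[, 1], topic_j = idx[, 2],
                              weight = w[idx]),
                       file.path(config$out_dir,
                                 sprintf("cooccurrence_%s.csv", pol)))
    }
    jsonlite::write_json(
      purrr::map(bundle$top_topics, function(tt) {
        purrr::pmap(tt, function(rank, topic, mass, top_words) {
          list(rank = rank, topic = topic, mass = mass, top_words = top_words)
        })
      }),
      file.path(config$out_dir, "top_topics.json"), auto_unbox = TRUE,
      digits = NA)
  }
  if (on("factors")) {
    stage_requires(bundle, "factors", "panel")
    fopt <- config$factors
    panel <- preprocess_panel(bundle$artifacts$panel)
    X <- as.matrix(panel[panel_factors(panel)])
    fit <- lasso_cv(X, panel$log_visits,
                    n_folds = fopt$n_folds %||% 10, seed = config$seed)
    ddata <- discretize_panel(panel, n_bins = fopt$n_bins %||% 3)
    bn <- learn_bn(ddata, max_parents = fopt$max_parents %||% 2,
                   init_as_naive_bayes = fopt$init_as_naive_bayes %||% FALSE,
                   ess = fopt$ess %||% 1.0)
    bundle$lasso <- fit
    bundle$bn <- bn
    bundle$bn_blanket <- influential_factors(bn, "visits")
    bundle$age_histogram <- if (!is.null(bundle$artifacts$visit_records)) {
      age_distribution(bundle$artifacts$visit_records)
    }
    readr::write_csv(tibble(factor = names(fit$beta), coefficient = fit$beta),
                     file.path(config$out_dir, "lasso_coefficients.csv"))
    readr::write_csv(fit$cv_curve, file.path(config$out_dir, "lasso_cv_curve.csv"))
    readr::write_csv(bn$edges, file.path(config$out_dir, "bn_edges.csv"))
    jsonlite::write_json(list(target = "visits",
                              markov_blanket = bundle$bn_blanket),
                         file.path(config$out_dir, "bn_blanket.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(bundle$age_histogram)) {
      readr::write_csv(as_tibble(bundle$age_histogram),
                       file.path(config$out_dir, "age_histogram.csv"))
    }
    gdp_strat <- if ("gdp" %in% panel_factors(panel)) {
      stratified_visits(panel, "gdp")
    }
    if (!is.null(gdp_strat)) {
      readr::write_csv(gdp_strat, file.path(config$out_dir,
                                            "stratified_visits_gdp.csv"))
    }
  }
  bundle <- structure(bundle, class = "pulse_report")
  write_report_index(bundle, config)
  bundle
}

write_report_index <- function(bundle, config) {
  index <- list(
    config_hash = bundle$provenance$config_hash,
    seed = bundle$provenance$seed,
    stages = bundle$provenance$stages,
    package_version = bundle$provenance$package_version,
    trend_ratios = bundle$trend_ratios,
    markov_blanket = bundle$bn_blanket,
    lasso_lambda = if (!is.null(bundle$lasso)) bundle$lasso$lambda,
    modal_age_band = if (!is.null(bundle$age_histogram)) {
      attr(bundle$age_histogram, "modal_band")
    })
  jsonlite::write_json(index[!vapply(index, is.null, logical(1))],
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Summarize a pipeline report
#'
#' Renders the figure set (OPR vs. visits trend, Lasso impact
#' coefficients, visit-age histogram) and a plain-text topic table from a
#' completed report bundle; components missing from the bundle are listed
#' rather than failing the summary.
#'
#' @param bundle A `pulse_report` from [run_pipeline()].
#' @param out_dir Output directory for figures and tables.
#' @return A list with `files` (paths written) and `missing` (components
#'   the bundle lacked), invisibly.
#' @export
summarize_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pulse_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  missing <- character(0)
  save_fig <- function(plot, name) {
    path <- file.path(out_dir, name)
    suppressMessages(ggplot2::ggsave(path, plot, width = 7, height = 4.5,
                                     dpi = 150))
    files <<- c(files, path)
  }
  if (!is.null(bundle$opr_series)) {
    if (!is.null(bundle$visits_by_year)) {
      save_fig(plot_opr_vs_visits(bundle$opr_series, bundle$visits_by_year),
               "opr_vs_visits.png")
    } else {
      save_fig(ggplot2::autoplot(bundle$opr_series), "opr_series.png")
    }
  } else {
    missing <- c(missing, "opr_series")
  }
  if (!is.null(bundle$lasso)) {
    save_fig(ggplot2::autoplot(bundle$lasso), "lasso_coefficients.png")
  } else {
    missing <- c(missing, "lasso")
  }
  if (!is.null(bundle$age_histogram)) {
    save_fig(ggplot2::autoplot(bundle$age_histogram), "age_histogram.png")
  } else {
    missing <- c(missing, "age_histogram")
  }
  if (!is.null(bundle$top_topics)) {
    tt <- dplyr::bind_rows(purrr::imap(bundle$top_topics, function(t, pol) {
      dplyr::mutate(t, polarity = pol,
                    top_words = vapply(.data$top_words, paste,
                                       character(1), collapse = " "))
    }))
    path <- file.path(out_dir, "topic_table.csv")
    readr::write_csv(tt, path)
    files <- c(files, path)
  } else {
    missing <- c(missing, "top_topics")
  }
  if (length(missing)) {
    inform(paste("summary omitted missing component(s):",
                 paste(missing, collapse = ", ")))
  }
  invisible(list(files = files, missing = missing))
}

#' @export
print.pulse_report <- function(x, ...) {
  cat("<pulse_report>\n")
  if (!is.null(x$trend_ratios)) {
    cat(sprintf("  OPR trend ratio: %.3f\n", x$trend_ratios$opr))
    if (!is.null(x$trend_ratios$visits)) {
      cat(sprintf("  visits trend ratio: %.3f\n", x$trend_ratios$visits))
    }
  }
  if (!is.null(x$bn_blanket)) {
    cat("  Markov blanket of visits:", paste(x$bn_blanket, collapse = ", "), "\n")
  }
  invisible(x)
}
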