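#' Preprocess a raw region-year utilization panel
#'
#' Filters the panel to the study window, centers and scales every factor
#' column to unit variance (dropping zero-variance columns with a logged
#' warning) and adds the log-transformed dependent variable, so Lasso
#' coefficients are comparable impact coefficients across factors.
#'
#' @param raw Data frame with columns `region`, `year`, `visits` and one
#'   column per candidate factor.
#' @param start_year,end_year Inclusive year filter (default 2004-2014).
#' @return A tibble with `region`, `year`, `visits`, `log_visits` and the
#'   standardized factor columns. Attributes: `"scaling"` (per-factor
#'   center/scale), `"dropped"` (zero-variance columns removed).
#' @export
preprocess_panel <- function(raw, start_year = 2004, end_year = 2014) {
  need <- c("region", "year", "visits")
  if (!all(need %in% names(raw))) {
    abort(paste("panel must contain columns:", paste(need, collapse = ", ")),
          class = "opinionpulse_config_error")
  }
  out <- dplyr::filter(as_tibble(raw), .data$year >= start_year,
                       .data$year <= end_year)
  if (nrow(out) < 2L) {
    abort("fewer than 2 rows remain after the year filter.",
          class = "opinionpulse_config_error")
  }
  if (any(out$visits < 0)) {
    abort("visits must be non-negative.", class = "opinionpulse_config_error")
  }
  factors <- setdiff(names(out), c(need, "log_visits"))
  dropped <- factors[vapply(out[factors], function(x) sd(x) == 0, logical(1))]
  if (length(dropped)) {
    warn(paste("dropping zero-variance factor column(s):",
               paste(dropped, collapse = ", ")),
         class = "opinionpulse_dropped_columns")
    out <- out[setdiff(names(out), dropped)]
    factors <- setdiff(factors, dropped)
  }
  centers <- vapply(out[factors], mean, numeric(1))
  scales <- vapply(out[factors], sd, numeric(1))
  out[factors] <- purrr::map2(out[factors], factors,
                              function(x, f) (x - centers[f]) / scales[f])
  out <- dplyr::mutate(out, log_visits = log(.data$visits), .after = "visits")
  attr(out, "scaling") <- tibble(factor = factors, center = unname(centers),
                                 scale = unname(scales))
  attr(out, "dropped") <- dropped
  attr(out, "factors") <- factors
  out
}

panel_factors <- function(panel) {
  attr(panel, "factors") %||%
    setdiff(names(panel), c("region", "year", "visits", "log_visits"))
}

#' Quantile-discretize a standardized panel
#'
#' Cuts every variable (the factors plus `visits`) at quantiles into
#' `n_bins` ordinal levels; a column with fewer distinct values than bins
#' is binned by its distinct values. Bin edges are recorded in the
#' `"bin_edges"` attribute.
#'
#' @param panel Standardized panel from [preprocess_panel()].
#' @param n_bins Number of ordinal levels.
#' @return A tibble of integer level codes over `visits` and the factors.
#' @export
discretize_panel <- function(panel, n_bins = 3) {
  vars <- c("visits", panel_factors(panel))
  edges <- list()
  out <- purrr::map(setNames(vars, vars), function(v) {
    x <- panel[[v]]
    if (length(unique(x)) < n_bins) {
      edges[[v]] <<- sort(unique(x))
      return(as.integer(factor(x)))
    }
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    edges[[v]] <<- br
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  })
  out <- as_tibble(out)
  attr(out, "bin_edges") <- edges
  out
}

#' Mean visits stratified by factor level
#'
#' Groups region-years into quantile levels of one factor and reports the
#' mean and spread of visits per level.
#'
#' @param panel Panel tibble (raw or preprocessed) with `visits`.
#' @param factor_name Factor column to stratify by.
#' @param n_levels Number of quantile levels.
#' @return A tibble `level`, `n`, `mean_visits`, `sd_visits`.
#' @export
stratified_visits <- function(panel, factor_name, n_levels = 4) {
  if (!factor_name %in% names(panel)) {
    abort(sprintf("factor '%s' not found in the panel.", factor_name),
          class = "opinionpulse_config_error")
  }
  x <- panel[[factor_name]]
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_levels + 1)))
  lev <- cut(x, breaks = br, include.lowest = TRUE,
             labels = seq_len(length(br) - 1L))
  dplyr::summarise(dplyr::group_by(tibble(level = as.integer(lev),
                                          visits = panel$visits),
                                   .data$level),
                   n = dplyr::n(),
                   mean_visits = mean(.data$visits),
                   sd_visits = sd(.data$visits), .groups = "drop")
}

#' Age distribution of visit records
#'
#' Bins visit ages into bands chosen to expose the clinically discussed
#' groups (early childhood 0-8, the 25-35 prime cohort, ...) and reports
#' the modal band.
#'
#' @param records Visit records with an `age` column (all ages >= 0).
#' @param bin_edges Right-closed integer band edges; the defaults produce
#'   bands 0-8, 9-15, 16-24, 25-35, 36-50, 51-65 and 66+.
#' @return A tibble of class `age_distribution` with `band`, `count`,
#'   `prop`; the modal band label is attached as attribute
#'   `"modal_band"`.
#' @export
age_distribution <- function(records, bin_edges = c(8, 15, 24, 35, 50, 65)) {
  stopifnot("age" %in% names(records))
  if (any(records$age < 0)) {
    abort("ages must be non-negative.", class = "opinionpulse_config_error")
  }
  breaks <- c(-1, bin_edges, Inf)
  lo <- c(0, bin_edges + 1)
  hi <- c(bin_edges, Inf)
  labels <- ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(lo, "+"))
  band <- cut(records$age, breaks = breaks, labels = labels)
  counts <- table(band)
  out <- tibble(band = factor(labels, levels = labels),
                count = as.integer(counts[labels]),
                prop = as.integer(counts[labels]) / max(nrow(records), 1L))
  attr(out, "modal_band") <- labels[which.max(out$count)]
  class(out) <- c("age_distribution", class(out))
  out
}
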