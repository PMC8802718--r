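#' Opinion Polarity Ratio
#'
#' The ratio of negative to positive post counts on a topic:
#' \eqn{n_-/n_+} when \eqn{n_+ \neq 0}, and the additively smoothed
#' \eqn{(n_- + \delta)/(n_+ + \delta)} when \eqn{n_+ = 0}, with smoothing
#' factor \eqn{0 < \delta \le 1}. The smoothing applies only to the
#' zero-denominator branch; `always_smooth = TRUE` switches to smoothing
#' both branches.
#'
#' @param n_pos,n_neg Non-negative post counts (vectorized).
#' @param delta Smoothing factor in (0, 1].
#' @param always_smooth Apply the smoothed form regardless of `n_pos`.
#' @return Non-negative ratio(s).
#' @examples
#' opr(10, 20)        # 2
#' opr(0, 5)          # (5 + 1) / (0 + 1) = 6
#' opr(0, 0, delta = 0.5)  # 1
#' @export
opr <- function(n_pos, n_neg, delta = 1, always_smooth = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    abort("`delta` must lie in (0, 1].", class = "opinionpulse_config_error")
  }
  if (any(n_pos < 0) || any(n_neg < 0)) {
    abort("counts must be non-negative.", class = "opinionpulse_config_error")
  }
  if (always_smooth) {
    (n_neg + delta) / (n_pos + delta)
  } else {
    ifelse(n_pos != 0, n_neg / n_pos, (n_neg + delta) / (n_pos + delta))
  }
}

#' Yearly Opinion Polarity Ratio series
#'
#' Bins stance-labeled posts by calendar year and computes one OPR per
#' year. Neutral posts enter neither count. Years inside the observed span
#' with no posts are emitted with zero counts (their OPR comes from the
#' smoothed branch).
#'
#' @param labeled Post tibble with a stance column (`"pos"`, `"neg"`,
#'   `"neu"`) and a timestamp column.
#' @param delta,always_smooth Passed to [opr()].
#' @param stance_col,time_col Column names.
#' @return A tibble of class `opr_series` with columns `year`, `n_pos`,
#'   `n_neg`, `opr`, strictly increasing in `year`.
#' @export
opr_series <- function(labeled, delta = 1, always_smooth = FALSE,
                       stance_col = "stance", time_col = "timestamp") {
  stopifnot(stance_col %in% names(labeled), time_col %in% names(labeled))
  yr <- as.integer(format(labeled[[time_col]], "%Y"))
  st <- labeled[[stance_col]]
  years <- if (length(yr)) seq(min(yr), max(yr)) else integer(0)
  out <- tibble(year = years,
                n_pos = vapply(years, function(y) sum(yr == y & st == "pos"),
                               numeric(1)),
                n_neg = vapply(years, function(y) sum(yr == y & st == "neg"),
                               numeric(1)))
  out$opr <- opr(out$n_pos, out$n_neg, delta = delta,
                 always_smooth = always_smooth)
  class(out) <- c("opr_series", class(out))
  out
}

#' End-to-start trend ratio of a series
#'
#' Ratio of the last period's value to the first period's; defined for the
#' OPR series and for any positive numeric series (e.g. yearly national
#' visit totals).
#'
#' @param x An `opr_series`, a data frame with a value column, or a
#'   numeric vector ordered by period.
#' @param value_col Value column when `x` is a data frame.
#' @return A single ratio.
#' @examples
#' trend_ratio(c(2, 3, 5))  # 2.5
#' @export
trend_ratio <- function(x, value_col = "opr") {
  v <- if (is.data.frame(x)) x[[value_col]] else as.numeric(x)
  if (length(v) < 2L) {
    abort("a trend ratio needs at least two periods.",
          class = "opinionpulse_config_error")
  }
  if (v[1] <= 0) {
    abort("first period's value must be positive.",
          class = "opinionpulse_config_error")
  }
  v[length(v)] / v[1]
}

#' Write an OPR series with its trend summary
#'
#' @param series An [opr_series()].
#' @param csv_path,json_path Output paths (CSV table, JSON summary).
#' @return Paths, invisibly.
#' @export
write_opr_outputs <- function(series, csv_path, json_path) {
  readr::write_csv(as_tibble(series), csv_path)
  jsonlite::write_json(list(trend_ratio = trend_ratio(series),
                            n_years = nrow(series),
                            total_pos = sum(series$n_pos),
                            total_neg = sum(series$n_neg)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
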