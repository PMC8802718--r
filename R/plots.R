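#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_minimal
NULL

#' Plot an OPR series
#' @param object An [opr_series()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.opr_series <- function(object, ...) {
  ggplot(object, aes(x = .data$year, y = .data$opr)) +
    geom_line(color = "firebrick") +
    geom_point(color = "firebrick") +
    labs(x = "year", y = "Opinion Polarity Ratio",
         title = "Yearly opinion polarity ratio") +
    theme_minimal()
}

#' Dual-axis OPR vs. visits trend figure
#'
#' Overlays the yearly Opinion Polarity Ratio with the national visit
#' totals (rescaled to a secondary axis).
#'
#' @param series An [opr_series()].
#' @param visits_by_year Tibble with `year` and `visits`.
#' @return A ggplot.
#' @export
plot_opr_vs_visits <- function(series, visits_by_year) {
  shared <- dplyr::inner_join(as_tibble(series), visits_by_year, by = "year")
  if (nrow(shared) == 0L) {
    shared <- dplyr::bind_rows(
      dplyr::mutate(as_tibble(series), visits = NA_real_),
      dplyr::mutate(visits_by_year, n_pos = NA, n_neg = NA, opr = NA))
  }
  k <- max(shared$visits, na.rm = TRUE) / max(shared$opr, na.rm = TRUE)
  ggplot(shared, aes(x = .data$year)) +
    geom_line(aes(y = .data$opr, color = "OPR")) +
    geom_point(aes(y = .data$opr, color = "OPR")) +
    geom_line(aes(y = .data$visits / k, color = "visits")) +
    geom_point(aes(y = .data$visits / k, color = "visits")) +
    ggplot2::scale_y_continuous(
      name = "Opinion Polarity Ratio",
      sec.axis = ggplot2::sec_axis(~ . * k, name = "visits")) +
    ggplot2::scale_color_manual(values = c(OPR = "firebrick",
                                           visits = "steelblue")) +
    labs(x = "year", color = NULL,
         title = "Criticism intensity vs. utilization") +
    theme_minimal()
}

#' Plot Lasso impact coefficients
#' @param object A [lasso_cv()] fit.
#' @param ... Ignored.
#' @return A ggplot bar chart of the coefficients at the selected penalty.
#' @export
autoplot.lasso_fit <- function(object, ...) {
  df <- tibble(factor = names(object$beta), coefficient = object$beta)
  df <- df[order(-abs(df$coefficient)), ]
  df$factor <- factor(df$factor, levels = rev(df$factor))
  ggplot(df, aes(x = .data$coefficient, y = .data$factor)) +
    geom_col(fill = "steelblue") +
    labs(x = "impact coefficient (standardized scale)", y = NULL,
         title = sprintf("Lasso factor selection (lambda = %.3g)",
                         object$lambda)) +
    theme_minimal()
}

#' Plot a visit-age histogram
#' @param object An [age_distribution()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.age_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$band, y = .data$count)) +
    geom_col(fill = "darkseagreen4") +
    labs(x = "age band", y = "visits",
         title = sprintf("Visit-age distribution (modal band %s)",
                         attr(object, "modal_band"))) +
    theme_minimal()
}

#' Plot a topic co-occurrence graph as a weighted edge tile map
#' @param w Symmetric co-occurrence matrix from [topic_cooccurrence()].
#' @return A ggplot.
#' @export
plot_topic_cooccurrence <- function(w) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(as.data.frame(w),
                            .name_repair = ~ as.character(seq_len(ncol(w)))),
                  topic_i = dplyr::row_number()),
    -"topic_i", names_to = "topic_j", values_to = "weight")
  df$topic_j <- as.integer(df$topic_j)
  ggplot(df, aes(x = .data$topic_i, y = .data$topic_j,
                 fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "topic", y = "topic", title = "Topic co-occurrence") +
    theme_minimal()
}
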