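panel_factor_names <- function(n_factors) {
  base <- c("gdp", "education", "hospital_beds", "physicians", "nurses",
            "medical_consumption", "drug_expenditure", "insurance_coverage",
            "pension_coverage", "population", "urbanization",
            "income_per_capita", "unemployment", "pm25", "so2_emissions",
            "green_coverage", "temperature", "humidity", "rainfall",
            "sunshine_hours", "road_density", "internet_penetration",
            "mobile_subscriptions", "literacy", "college_enrollment",
            "life_expectancy", "birth_rate", "aging_ratio",
            "social_security_spending", "fiscal_health_spending")
  if (n_factors <= length(base)) {
    base[seq_len(n_factors)]
  } else {
    c(base, sprintf("factor_%02d", seq_len(n_factors - length(base))))
  }
}

#' Configure a synthetic region-year utilization panel
#'
#' Configuration for [gen_panel()], which emulates a national statistics
#' panel: one row per (region, year) holding a visit count and candidate
#' explanatory factors (economic, education, medical-infrastructure,
#' environment, weather, social-security proxies). Visits depend sparsely on
#' the factors; by default only the GDP and education proxies carry signal.
#'
#' @param n_regions Number of regions (default 34 provincial-level units).
#' @param start_year,end_year Inclusive year range (default 2004-2014).
#' @param n_factors Number of candidate factor columns (default 30).
#' @param true_beta Named numeric vector of ground-truth effects on
#'   log-visits per standard deviation of the factor; names must be factor
#'   names. At least two entries must be nonzero.
#' @param noise_sd Standard deviation of the region-year log-normal noise.
#' @param visits_growth Multiplicative yearly growth of the national visit
#'   total (followed exactly; see Details).
#' @param base_total_visits National visit total in the first year.
#' @param seed Integer seed.
#'
#' @details The generator draws region-year weights
#' \eqn{w_{ry} = \exp(u_r + \beta^\top x_{ry} + \varepsilon_{ry})} (with a
#' region size effect \eqn{u_r}) and then scales each year so the national
#' total equals `base_total_visits * visits_growth^(year - start_year)`
#' exactly. Cross-sectional dependence of visits on the factors is thereby
#' preserved while the configured national growth trajectory is
#' deterministic ground truth rather than a random quantity.
#'
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_regions = 34, start_year = 2004, end_year = 2014,
                         n_factors = 30,
                         true_beta = c(gdp = 0.6, education = 0.4),
                         noise_sd = 0.1, visits_growth = 2.41^(1 / 10),
                         base_total_visits = 1e6, seed = 1) {
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  n_factors <- check_count(n_factors, "n_factors", min = 1L)
  if (end_year < start_year) {
    abort("`end_year` must be >= `start_year`.", class = "opinionpulse_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "opinionpulse_config_error")
  }
  if (visits_growth <= 0) {
    abort("`visits_growth` must be > 0.", class = "opinionpulse_config_error")
  }
  factors <- panel_factor_names(n_factors)
  beta <- setNames(numeric(n_factors), factors)
  if (length(true_beta)) {
    if (is.null(names(true_beta)) || !all(names(true_beta) %in% factors)) {
      abort("`true_beta` must be named with factor names present in the panel.",
            class = "opinionpulse_config_error")
    }
    beta[names(true_beta)] <- true_beta
  }
  support <- sum(beta != 0)
  if (support > n_factors) {
    abort("more nonzero effects than factors.", class = "opinionpulse_config_error")
  }
  if (support < 2) {
    abort("`true_beta` must have at least two nonzero entries.",
          class = "opinionpulse_config_error")
  }
  structure(list(n_regions = n_regions, start_year = as.integer(start_year),
                 end_year = as.integer(end_year), n_factors = n_factors,
                 factors = factors, true_beta = beta, noise_sd = noise_sd,
                 visits_growth = visits_growth,
                 base_total_visits = base_total_visits,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Generate a synthetic region-year utilization panel
#'
#' @param config A [panel_config()].
#' @return A tibble with columns `region`, `year`, `visits` and one column
#'   per factor (raw, non-standardized scale; each factor has its own
#'   deterministic location and spread). The ground-truth coefficient vector
#'   (on the standardized scale) is attached as attribute `"true_beta"`, the
#'   config as `"config"`.
#' @examples
#' panel <- gen_panel(panel_config(seed = 7))
#' dim(panel)   # 34 regions x 11 years = 374 rows
#' @export
gen_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  years <- seq(config$start_year, config$end_year)
  R <- config$n_regions
  P <- config$n_factors
  n <- R * length(years)
  with_seed(config$seed, {
    region <- rep(sprintf("region_%02d", seq_len(R)), times = length(years))
    year <- rep(years, each = R)
    z <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, config$factors))
    u <- rnorm(R, sd = 0.3)[rep(seq_len(R), times = length(years))]
    eps <- if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0
    w <- exp(u + drop(z %*% config$true_beta) + eps)
    total <- config$base_total_visits * config$visits_growth^(year - config$start_year)
    year_sum <- tapply(w, year, sum)[as.character(year)]
    visits <- total * w / as.numeric(year_sum)
    # raw factor scales: deterministic per-factor location and spread
    mu <- seq_len(P)
    sdv <- 1 + seq_len(P) / 10
    x_raw <- sweep(sweep(z, 2L, sdv, `*`), 2L, mu, `+`)
    out <- dplyr::bind_cols(tibble(region = region, year = year, visits = visits),
                            as_tibble(x_raw))
    attr(out, "true_beta") <- config$true_beta
    attr(out, "config") <- config
    out
  })
}

#' Configure and generate synthetic visit-age records
#'
#' Emulates per-visit hospital records whose age distribution is a mixture
#' of uniform age bands. The default mixture puts the modal mass at ages
#' 25-35 with a secondary early-childhood (0-8) mode that exceeds the 9-15
#' band.
#'
#' @param n_records Number of visit records.
#' @param age_mixture Data frame with columns `lo`, `hi`, `weight`; weights
#'   must be non-negative and sum to 1, ages non-negative.
#' @param start_year,end_year Year range stamped uniformly onto records.
#' @param seed Integer seed.
#' @return `visit_config()` returns a list of class `visit_config`;
#'   `gen_visit_records()` returns a tibble with columns `visit_id`, `year`,
#'   `age`.
#' @export
visit_config <- function(n_records = 50000,
                         age_mixture = tibble(
                           lo = c(25, 0, 36, 51, 16, 66, 9),
                           hi = c(35, 8, 50, 65, 24, 90, 15),
                           weight = c(0.32, 0.18, 0.16, 0.14, 0.10, 0.06, 0.04)),
                         start_year = 2004, end_year = 2014, seed = 1) {
  n_records <- check_count(n_records, "n_records", min = 0L)
  age_mixture <- as_tibble(age_mixture)
  if (!all(c("lo", "hi", "weight") %in% names(age_mixture))) {
    abort("`age_mixture` needs columns lo, hi, weight.",
          class = "opinionpulse_config_error")
  }
  if (any(age_mixture$weight < 0)) {
    abort("mixture weights must be non-negative.",
          class = "opinionpulse_config_error")
  }
  if (abs(sum(age_mixture$weight) - 1) > 1e-6) {
    abort("mixture weights must sum to 1.", class = "opinionpulse_config_error")
  }
  if (any(age_mixture$lo < 0) || any(age_mixture$hi < age_mixture$lo)) {
    abort("age bands must satisfy 0 <= lo <= hi.",
          class = "opinionpulse_config_error")
  }
  structure(list(n_records = n_records, age_mixture = age_mixture,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year), seed = as.integer(seed)),
            class = "visit_config")
}

#' @rdname visit_config
#' @param config A `visit_config`.
#' @export
gen_visit_records <- function(config) {
  stopifnot(inherits(config, "visit_config"))
  n <- config$n_records
  mix <- config$age_mixture
  if (n == 0L) {
    return(tibble(visit_id = character(), year = integer(), age = integer()))
  }
  with_seed(config$seed, {
    comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    width <- mix$hi - mix$lo + 1L
    age <- mix$lo[comp] + floor(runif(n) * width[comp])
    tibble(visit_id = sprintf("v%07d", seq_len(n)),
           year = sample(seq(config$start_year, config$end_year), n,
                         replace = TRUE),
           age = as.integer(age))
  })
}
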