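#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames quantile sd var optim predict
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "opinionpulse_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_proportion <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1], got %s.", name, format(x)),
          class = "opinionpulse_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "opinionpulse_config_error")
  }
  invisible(as.integer(x))
}

# Largest-remainder allocation of `n` units to proportions `p` (sums to 1).
allocate_counts <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# log-sum-exp over a numeric vector
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
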