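#' Lasso regression by cyclic coordinate descent
#'
#' Minimizes \eqn{\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 +
#' \lambda \lVert\beta\rVert_1} by cyclic coordinate descent with
#' soft-thresholding. The intercept is handled by centering and never
#' penalized. Iteration stops when the largest coefficient change in a
#' sweep falls below `tol`.
#'
#' @param x Numeric predictor matrix (callers normally pass standardized
#'   columns, e.g. from [preprocess_panel()]).
#' @param y Numeric response.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Sweep cap.
#' @param beta_init Optional warm start.
#' @return A list with `beta` (named), `intercept`, `lambda`, `iterations`.
#' @examples
#' x <- scale(matrix(rnorm(200), 50, 4)); y <- x[, 1] + rnorm(50, sd = 0.1)
#' lasso_cd(x, y, lambda = 0.05)$beta
#' @export
lasso_cd <- function(x, y, lambda, tol = 1e-8, max_iter = 10000,
                     beta_init = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("non-finite values in the design or response.",
          class = "opinionpulse_config_error")
  }
  if (lambda < 0) {
    abort("`lambda` must be >= 0.", class = "opinionpulse_config_error")
  }
  n <- nrow(x)
  p <- ncol(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  yc <- y - ym
  d <- colSums(xc^2) / n          # curvature per coordinate
  beta <- beta_init %||% numeric(p)
  r <- yc - xc %*% beta
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  it <- 0L
  repeat {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      if (d[j] == 0) next
      zj <- sum(xc[, j] * r) / n + d[j] * beta[j]
      bj <- soft(zj, lambda) / d[j]
      if (bj != beta[j]) {
        r <- r - xc[, j] * (bj - beta[j])
        delta_max <- max(delta_max, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta_max < tol || it >= max_iter) break
  }
  beta <- as.numeric(beta)
  names(beta) <- colnames(x)
  list(beta = beta, intercept = ym - sum(xm * beta), lambda = lambda,
       iterations = it)
}

lasso_lambda_max <- function(x, y) {
  xc <- sweep(as.matrix(x), 2L, colMeans(x))
  max(abs(crossprod(xc, y - mean(y)))) / nrow(xc)
}

# Warm-started coefficient path along a decreasing lambda grid.
lasso_path <- function(x, y, lambda_grid, tol = 1e-8) {
  p <- ncol(x)
  betas <- matrix(0, length(lambda_grid), p,
                  dimnames = list(NULL, colnames(x)))
  intercepts <- numeric(length(lambda_grid))
  warm <- numeric(p)
  for (i in seq_along(lambda_grid)) {
    fit <- lasso_cd(x, y, lambda_grid[i], tol = tol, beta_init = warm)
    warm <- fit$beta
    betas[i, ] <- fit$beta
    intercepts[i] <- fit$intercept
  }
  list(betas = betas, intercepts = intercepts)
}

#' Cross-validated Lasso factor selection
#'
#' Fits the coordinate-descent Lasso along a log-spaced penalty grid,
#' estimates out-of-sample error by k-fold cross-validation with a seeded
#' fold shuffle, and returns the fit at the error-minimizing penalty
#' together with the full CV curve and coefficient path.
#'
#' @param x Standardized predictor matrix.
#' @param y Response (at least `n_folds` observations).
#' @param n_folds Number of CV folds.
#' @param lambda_grid Optional decreasing penalty grid; default is 50
#'   log-spaced values from the annihilating penalty down to 0.1% of it.
#' @param seed Seed for the fold assignment.
#' @return A list of class `lasso_fit`: `lambda`, `beta`, `intercept`,
#'   `cv_curve` (tibble `lambda`, `mean_error`, `sd_error`), `path`
#'   (coefficients along the grid), `folds`, `seed`.
#' @export
lasso_cv <- function(x, y, n_folds = 10, lambda_grid = NULL, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < n_folds) {
    abort("fewer observations than folds.", class = "opinionpulse_config_error")
  }
  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(x, y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  errs <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    pathf <- lasso_path(x[tr, , drop = FALSE], y[tr], lambda_grid)
    pred <- sweep(x[!tr, , drop = FALSE] %*% t(pathf$betas), 2L,
                  pathf$intercepts, `+`)
    errs[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_curve <- tibble(lambda = lambda_grid,
                     mean_error = colMeans(errs),
                     sd_error = apply(errs, 2L, sd) / sqrt(n_folds))
  best <- which.min(cv_curve$mean_error)
  full_path <- lasso_path(x, y, lambda_grid)
  structure(list(lambda = lambda_grid[best],
                 beta = full_path$betas[best, ],
                 intercept = full_path$intercepts[best],
                 cv_curve = cv_curve, path = full_path$betas,
                 lambda_grid = lambda_grid, folds = folds, seed = seed),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<lasso_fit> lambda = %.4g, %d/%d nonzero coefficients\n",
              x$lambda, nz, length(x$beta)))
  invisible(x)
}
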