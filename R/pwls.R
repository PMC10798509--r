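## Performance-weighted least squares (PWLS) polynomial regression.
##
## The core statistical method of the package: a polynomial y(v) is fitted
## by minimising || beta (*) (y - V omega) ||^2, the elementwise
## (Hadamard-) weighted residual norm, where each gait record's weight
## beta_j = A^((cotbar_j - cot_j)/cotbar_j) grows exponentially with how
## much more efficient (lower CoT) the record is than the local mean CoT
## around its velocity. A = 1 recovers ordinary least squares.

#' Moving-average CoT around a record
#'
#' Mean CoT over the window `[j - M, j + M]` of a velocity-sorted dataset
#' (full window width `2M + 1`; 251 points at the default `M = 125`). At
#' the dataset boundaries the window shrinks to the valid index range.
#'
#' @param cot Numeric vector of CoT values, sorted by velocity.
#' @param j Record index (1-based). May be a vector.
#' @param M Half-window size (data points).
#' @return Mean CoT for each requested index.
#' @examples
#' moving_average_cot(c(1, 2, 3, 4, 5), 3, M = 1)  # 3
#' moving_average_cot(c(1, 2, 3, 4, 5), 1, M = 1)  # mean(1, 2) = 1.5
#' @export
moving_average_cot <- function(cot, j, M = 125L) {
  n <- length(cot)
  if (n == 0L) stop("empty dataset")
  if (any(j < 1L | j > n)) stop("index out of range")
  if (M < 0L) stop("M must be non-negative")
  vapply(j, function(jj) {
    lo <- max(1L, jj - M)
    hi <- min(n, jj + M)
    mean(cot[lo:hi])
  }, numeric(1))
}

#' Performance weight of a record
#'
#' `beta = A^((cot_bar - cot) / cot_bar)`: records more efficient than the
#' local mean CoT get weight above 1, less efficient ones below 1, with the
#' bias strength set by `A >= 1`. `A = 1` gives uniform weights (ordinary
#' least squares).
#'
#' @param cot CoT of the record(s).
#' @param cot_bar Local mean CoT (must be positive).
#' @param A Bias strength, `A >= 1`.
#' @return Weight(s) `beta > 0`.
#' @examples
#' performance_weights(0.45, 0.5, A = 100)  # 100^0.1 ~ 1.5849
#' @export
performance_weights <- function(cot, cot_bar, A) {
  if (any(cot_bar <= 0)) stop("cot_bar must be positive")
  if (A < 1) stop("A must be >= 1")
  A^((cot_bar - cot) / cot_bar)
}

## log-space weights for extreme A, renormalised so max(beta) = 1
## (allowed by the scale invariance of the weighted fit)
log_performance_weights <- function(cot, M, A) {
  cot_bar <- moving_average_cot(cot, seq_along(cot), M)
  log_beta <- log(A) * (cot_bar - cot) / cot_bar
  list(log_beta = log_beta - max(log_beta), cot_bar = cot_bar)
}

## centred/scaled power basis: z = (v - center)/scale, columns z^0..z^m
scaled_power_basis <- function(v, degree, center, scale) {
  z <- (v - center) / scale
  outer(z, 0:degree, `^`)
}

## coefficients of P(v) = sum_j a_j ((v - c)/s)^j in the raw power basis
rescale_coefficients <- function(a, center, scale) {
  m <- length(a) - 1L
  out <- numeric(m + 1L)
  base <- c(-center / scale, 1 / scale)  # the polynomial (v - c)/s
  pw <- 1                                 # ((v - c)/s)^0
  for (j in 0:m) {
    out[seq_along(pw)] <- out[seq_along(pw)] + a[j + 1L] * pw
    if (j < m) {
      ## polynomial multiplication by base (convolution of coefficients)
      npw <- numeric(length(pw) + 1L)
      npw[seq_along(pw)] <- npw[seq_along(pw)] + pw * base[1L]
      npw[seq_along(pw) + 1L] <- npw[seq_along(pw) + 1L] + pw * base[2L]
      pw <- npw
    }
  }
  out
}

#' Fit a performance-weighted polynomial (PWLS)
#'
#' Fits the degree-`m` polynomial minimising the performance-weighted
#' squared error `||beta (*) (y - V omega)||^2` over the raw power-basis
#' coefficients `omega`. The solve uses an orthogonal (QR) weighted
#' least-squares factorisation on a centred/scaled velocity basis for
#' conditioning; coefficients are transformed back to the raw basis, which
#' is the serialisation convention. Equivalent to the explicit
#' normal-equations solution, but stable at degree 6.
#'
#' Weights may be given directly (`beta`, or `log_beta` for extreme bias
#' strengths) or derived from CoT values via `cot` + `A` + `M`.
#'
#' @param v Numeric vector of velocities (m/s).
#' @param y Numeric vector of parameter values (same length).
#' @param beta Positive weights (recycled); default uniform.
#' @param degree Polynomial degree `m` (default 6).
#' @param cot Optional CoT vector (requires `v`-sorted data) from which
#'   weights are computed as `A^((cotbar - cot)/cotbar)`.
#' @param A Bias strength (used with `cot`).
#' @param M Half-window for the local mean CoT (used with `cot`).
#' @param log_beta Optional log-weights, overriding `beta`.
#' @return Object of class `pwls` with components `coefficients` (raw
#'   ascending powers), `degree`, `fitted.values`, `residuals`, `weights`
#'   (normalised so the largest is 1), `v`, `y`, `center`, `scale`.
#' @examples
#' fit <- pwls(c(0, 1, 2), c(1, 2, 5), degree = 2)
#' coef(fit)  # 1 0 1: interpolation
#' @export
pwls <- function(v, y, beta = NULL, degree = 6L, cot = NULL,
                 A = 1, M = 125L, log_beta = NULL) {
  n <- length(v)
  if (length(y) != n) stop("v and y must have equal length")
  if (n < degree + 1L) {
    stop("need at least degree + 1 = ", degree + 1L, " points, got ", n)
  }
  if (!is.null(cot)) {
    lw <- log_performance_weights(cot, M, A)
    log_beta <- lw$log_beta
  } else if (is.null(log_beta)) {
    if (is.null(beta)) beta <- rep(1, n)
    beta <- rep_len(beta, n)
    if (any(beta <= 0)) stop("weights beta must be positive")
    log_beta <- log(beta) - max(log(beta))
  } else {
    log_beta <- log_beta - max(log_beta)
  }
  if (length(unique(v)) < degree + 1L) {
    stop("singular fit: only ", length(unique(v)),
         " distinct velocities for degree ", degree)
  }

  center <- mean(v)
  scale <- stats::sd(v)
  if (!is.finite(scale) || scale == 0) scale <- 1
  Z <- scaled_power_basis(v, degree, center, scale)
  w <- exp(2 * log_beta)  # squared weights: ||b(y - Zc)||^2 = sum w r^2
  fit <- stats::lm.wfit(Z, y, w)
  if (fit$rank < degree + 1L) {
    stop("singular fit: rank ", fit$rank, " < ", degree + 1L,
         " (velocities too clustered for the requested degree)")
  }
  a <- fit$coefficients
  omega <- rescale_coefficients(a, center, scale)
  fitted <- drop(Z %*% a)
  structure(list(coefficients = stats::setNames(omega, paste0("v^", 0:degree)),
                 scaled_coefficients = stats::setNames(a, NULL),
                 degree = as.integer(degree),
                 fitted.values = fitted,
                 residuals = y - fitted,
                 weights = exp(log_beta),
                 v = v, y = y, center = center, scale = scale,
                 call = match.call()),
            class = "pwls")
}

#' Evaluate a polynomial given ascending-power coefficients
#'
#' Horner evaluation of `sum_j omega_j * v^j`.
#'
#' @param omega Coefficients, ascending powers.
#' @param v Evaluation points.
#' @return Numeric vector.
#' @export
predict_polynomial <- function(omega, v) {
  out <- rep(0, length(v))
  for (j in rev(seq_along(omega))) out <- out * v + omega[[j]]
  out
}

#' @export
coef.pwls <- function(object, ...) object$coefficients

#' @export
fitted.pwls <- function(object, ...) object$fitted.values

#' @export
residuals.pwls <- function(object, ...) object$residuals

#' Predict from a PWLS fit
#' @param object A `pwls` fit.
#' @param newdata Velocities at which to evaluate (default: training v).
#' @param ... Ignored.
#' @return Predicted parameter values.
#' @export
predict.pwls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  v <- if (is.list(newdata)) newdata$v else newdata
  ## evaluate in the conditioned basis for accuracy
  drop(scaled_power_basis(v, object$degree, object$center, object$scale) %*%
         object$scaled_coefficients)
}

#' @export
print.pwls <- function(x, ...) {
  cat("Performance-weighted polynomial fit (degree ", x$degree, ")\n", sep = "")
  cat("  n = ", length(x$v), ", velocity range [",
      format(min(x$v), digits = 3), ", ", format(max(x$v), digits = 3),
      "] m/s\n", sep = "")
  cat("  coefficients (ascending powers):\n")
  print(zapsmall(x$coefficients, digits = 10))
  invisible(x)
}

#' @export
summary.pwls <- function(object, ...) {
  r <- object$residuals
  w <- object$weights
  out <- list(degree = object$degree, n = length(object$v),
              rmse = sqrt(mean(r^2)),
              weighted_rmse = sqrt(sum((w * r)^2) / sum(w^2)),
              weight_range = range(w),
              coefficients = object$coefficients)
  class(out) <- "summary.pwls"
  out
}

#' @export
print.summary.pwls <- function(x, ...) {
  cat("PWLS fit: degree", x$degree, "on", x$n, "records\n")
  cat("  RMSE:", format(x$rmse, digits = 6),
      " weighted RMSE:", format(x$weighted_rmse, digits = 6), "\n")
  cat("  normalised weight range: [",
      format(x$weight_range[1], digits = 4), ", ",
      format(x$weight_range[2], digits = 4), "]\n", sep = "")
  print(zapsmall(x$coefficients, digits = 10))
  invisible(x)
}

#' Plot a PWLS fit
#'
#' Data points shaded by weight (darker = higher performance weight) with
#' the fitted polynomial overlaid.
#'
#' @param x A `pwls` fit.
#' @param n_grid Curve resolution.
#' @param ... Passed to `plot()`.
#' @export
plot.pwls <- function(x, n_grid = 200L, ...) {
  shade <- grDevices::gray(0.8 * (1 - x$weights / max(x$weights)))
  graphics::plot(x$v, x$y, col = shade, pch = 16,
                 xlab = "velocity (m/s)", ylab = "parameter value", ...)
  vg <- seq(min(x$v), max(x$v), length.out = n_grid)
  graphics::lines(vg, predict(x, vg), col = "red", lwd = 2)
  invisible(x)
}
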