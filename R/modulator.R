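## The velocity-indexed parameter modulator: one fitted polynomial per
## control parameter, mapping a target velocity to a full 56-entry reflex
## parameter set; plus hybrid modulators for circuit-substitution
## experiments.

#' Fit a parameter modulator by PWLS
#'
#' Fits one degree-`m` polynomial per control parameter over achieved
#' velocity, all sharing the single performance-weight vector derived from
#' the dataset's CoT values (local-mean window `M`, bias strength `A`).
#' The resulting bank of 56 polynomials is the parameter modulator: it
#' coordinates the whole reflex parameter set for an input target velocity.
#'
#' @param dataset A `gait_dataset` (velocity-sorted).
#' @param degree Polynomial degree `m` (default 6, the smallest degree
#'   found sufficient to generate gaits).
#' @param A Bias strength toward low-CoT records (`A = 1` = ordinary least
#'   squares; default `1e6`).
#' @param M Half-window for the local mean CoT (default 125, i.e. windows
#'   of 251 records).
#' @return Object of class `gait_modulator`: `coefficients` is a
#'   `56 x (degree+1)` matrix (rows = registry parameters, columns =
#'   ascending powers of raw velocity), plus `velocity_range`, `degree`,
#'   `A`, `M`, `center`/`scale` of the fitting basis and per-parameter
#'   `provenance`.
#' @examples
#' ds <- make_twolevel_dataset()
#' # a single-parameter example lives in ds$G_HFL; full fits need 56 columns
#' @export
fit_modulator <- function(dataset, degree = 6L, A = 1e6, M = 125L) {
  stopifnot(inherits(dataset, "gait_dataset"))
  n <- nrow(dataset)
  if (n <= degree) stop("need more records than the polynomial degree")
  lw <- log_performance_weights(dataset$cot, M, A)
  pmat <- dataset_params(dataset)
  coefs <- matrix(NA_real_, nrow = 56L, ncol = degree + 1L,
                  dimnames = list(parameter_names(),
                                  paste0("v^", 0:degree)))
  for (name in parameter_names()) {
    fit <- tryCatch(
      pwls(dataset$v_x, pmat[, name], degree = degree,
           log_beta = lw$log_beta),
      error = function(e) {
        stop("PWLS fit failed for parameter '", name, "': ",
             conditionMessage(e), call. = FALSE)
      })
    coefs[name, ] <- coef(fit)
  }
  structure(list(coefficients = coefs,
                 degree = as.integer(degree),
                 velocity_range = range(dataset$v_x),
                 A = A, M = as.integer(M),
                 n_records = n,
                 provenance = stats::setNames(rep("fit", 56L),
                                              parameter_names())),
            class = "gait_modulator")
}

#' Build a modulator directly from a coefficient matrix
#'
#' @param coefficients `56 x (degree+1)` matrix, rows named by registry
#'   parameters, columns ascending powers of raw velocity.
#' @param velocity_range Length-2 numeric, the valid velocity range (m/s).
#' @param A,M Fit metadata (defaults NA when constructed by hand).
#' @return A `gait_modulator`.
#' @export
modulator <- function(coefficients, velocity_range, A = NA_real_,
                      M = NA_integer_) {
  coefficients <- as.matrix(coefficients)
  stopifnot(nrow(coefficients) == 56L, length(velocity_range) == 2L,
            velocity_range[1] < velocity_range[2])
  if (is.null(rownames(coefficients))) {
    rownames(coefficients) <- parameter_names()
  }
  coefficients <- coefficients[parameter_names(), , drop = FALSE]
  colnames(coefficients) <- paste0("v^", 0:(ncol(coefficients) - 1L))
  structure(list(coefficients = coefficients,
                 degree = ncol(coefficients) - 1L,
                 velocity_range = as.numeric(velocity_range),
                 A = A, M = M, n_records = NA_integer_,
                 provenance = stats::setNames(rep("manual", 56L),
                                              parameter_names())),
            class = "gait_modulator")
}

#' Map a target velocity to a full control parameter set
#'
#' Evaluates all 56 polynomials at `v_tar`. Targets outside the fitted
#' velocity range are clamped to it with a warning (behaviour outside the
#' range is undefined) unless `clamp_range = FALSE`, in which case they
#' raise an error. Parameter values falling outside the registry's
#' feasible bounds are clamped to the bounds with a warning.
#'
#' @param mod A `gait_modulator`.
#' @param v_tar Target velocity (m/s), scalar.
#' @param clamp_range Clamp out-of-range targets (default) or error?
#' @param clamp_bounds Clamp modulated values to registry bounds?
#' @return Named 56-entry control parameter vector in registry order.
#' @export
modulate <- function(mod, v_tar, clamp_range = TRUE, clamp_bounds = TRUE) {
  stopifnot(inherits(mod, "gait_modulator"), length(v_tar) == 1L)
  rng <- mod$velocity_range
  if (v_tar < rng[1] || v_tar > rng[2]) {
    if (!clamp_range) {
      stop("target velocity ", v_tar, " outside fitted range [",
           rng[1], ", ", rng[2], "]")
    }
    warning("target velocity ", format(v_tar), " clamped to fitted range [",
            format(rng[1]), ", ", format(rng[2]), "]")
    v_tar <- min(max(v_tar, rng[1]), rng[2])
  }
  y <- apply(mod$coefficients, 1L, predict_polynomial, v = v_tar)
  names(y) <- parameter_names()
  if (clamp_bounds) y <- clamp_parameters(y, warn = TRUE) else y
}

#' Predict parameter values over a velocity grid
#' @param object A `gait_modulator`.
#' @param newdata Velocities (m/s); default 50 points over the fitted range.
#' @param ... Ignored.
#' @return Matrix `length(newdata) x 56` of parameter values (not clamped).
#' @export
predict.gait_modulator <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- seq(object$velocity_range[1], object$velocity_range[2],
                   length.out = 50L)
  }
  out <- sapply(parameter_names(), function(nm) {
    predict_polynomial(object$coefficients[nm, ], newdata)
  })
  out <- matrix(out, nrow = length(newdata),
                dimnames = list(NULL, parameter_names()))
  out
}

#' @export
coef.gait_modulator <- function(object, ...) object$coefficients

#' @export
print.gait_modulator <- function(x, ...) {
  cat("Gait parameter modulator: 56 polynomials of degree ", x$degree, "\n",
      sep = "")
  cat("  velocity range [", format(x$velocity_range[1], digits = 3), ", ",
      format(x$velocity_range[2], digits = 3), "] m/s", sep = "")
  if (is.finite(x$A)) cat(", A = ", format(x$A), ", M = ", x$M, sep = "")
  cat("\n")
  subs <- names(x$provenance)[x$provenance == "substituted"]
  if (length(subs)) {
    cat("  substituted entries:", paste(subs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot modulator curves for selected parameters
#' @param x A `gait_modulator`.
#' @param params Parameter names to draw (default: the two key circuits).
#' @param ... Passed to `matplot`.
#' @export
plot.gait_modulator <- function(x, params = unlist(circuit_groups()), ...) {
  vg <- seq(x$velocity_range[1], x$velocity_range[2], length.out = 200L)
  yy <- sapply(params, function(nm) predict_polynomial(x$coefficients[nm, ], vg))
  graphics::matplot(vg, yy, type = "l", lty = 1,
                    xlab = "target velocity (m/s)",
                    ylab = "parameter value", ...)
  graphics::legend("topleft", legend = params, col = seq_along(params),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Substitute parameter functions from a donor modulator
#'
#' Builds the hybrid modulator used in circuit-substitution experiments:
#' identical to `base` except that the polynomials of the named parameters
#' are copied from `donor`. Idempotent, and disjoint substitutions commute.
#'
#' @param base Base `gait_modulator`.
#' @param donor Donor `gait_modulator` (same degree).
#' @param names Character vector of registry parameter names to replace
#'   (may be empty).
#' @return A `gait_modulator` with provenance recorded per entry.
#' @export
substitute_functions <- function(base, donor, names = character()) {
  stopifnot(inherits(base, "gait_modulator"),
            inherits(donor, "gait_modulator"))
  if (base$degree != donor$degree) {
    stop("base and donor modulators must share the polynomial degree")
  }
  unknown <- setdiff(names, parameter_names())
  if (length(unknown)) {
    stop("unknown control parameter name(s): ", paste(unknown, collapse = ", "))
  }
  out <- base
  if (length(names)) {
    out$coefficients[names, ] <- donor$coefficients[names, , drop = FALSE]
    out$provenance[names] <- "substituted"
    out$velocity_range <- c(max(base$velocity_range[1], donor$velocity_range[1]),
                            min(base$velocity_range[2], donor$velocity_range[2]))
  }
  out
}

#' Write a modulator to JSON
#'
#' Serialises degree, velocity range, fit metadata and the per-parameter
#' coefficient arrays (ascending powers of raw velocity).
#'
#' @param mod A `gait_modulator`.
#' @param path Output path.
#' @export
write_modulator <- function(mod, path) {
  stopifnot(inherits(mod, "gait_modulator"))
  obj <- list(schema_version = 1L,
              degree = mod$degree,
              velocity_range = mod$velocity_range,
              A = mod$A, M = mod$M,
              coefficients = apply(mod$coefficients, 1L, identity,
                                   simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a modulator from JSON
#' @param path File written by [write_modulator()].
#' @return A `gait_modulator`.
#' @export
read_modulator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- do.call(rbind, obj$coefficients[parameter_names()])
  mod <- modulator(coefs, obj$velocity_range,
                   A = if (is.null(obj$A)) NA_real_ else obj$A,
                   M = if (is.null(obj$M)) NA_integer_ else obj$M)
  mod
}
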