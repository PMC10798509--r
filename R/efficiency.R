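## Energy-efficiency analysis: quadratic CoT-velocity curves, integrated
## CoT over a velocity range, and reflex-circuit substitution experiments.

#' Fit a quadratic CoT-velocity curve
#'
#' Unweighted least-squares fit of `CoT = c2 v^2 + c1 v + c0` to achieved
#' (velocity, CoT) samples.
#'
#' @param v_x Achieved velocities (>= 3 distinct values).
#' @param cot CoT values.
#' @return Object of class `cot_curve` with `coefficients` (c0, c1, c2
#'   ascending) and `range` (velocity span of the samples).
#' @export
fit_cot_curve <- function(v_x, cot) {
  if (length(unique(v_x)) < 3L) {
    stop("singular fit: need at least 3 distinct velocities")
  }
  stopifnot(length(v_x) == length(cot))
  fit <- stats::lm.fit(cbind(1, v_x, v_x^2), cot)
  if (fit$rank < 3L) stop("singular fit: velocities too clustered")
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                c("c0", "c1", "c2")),
                 range = range(v_x)),
            class = "cot_curve")
}

#' @export
print.cot_curve <- function(x, ...) {
  co <- x$coefficients
  cat("CoT curve: ", format(co[["c2"]], digits = 4), " v^2 + ",
      format(co[["c1"]], digits = 4), " v + ",
      format(co[["c0"]], digits = 4), "  over [",
      format(x$range[1], digits = 3), ", ", format(x$range[2], digits = 3),
      "] m/s\n", sep = "")
  invisible(x)
}

#' @export
predict.cot_curve <- function(object, newdata, ...) {
  co <- object$coefficients
  co[["c0"]] + co[["c1"]] * newdata + co[["c2"]] * newdata^2
}

#' Integrated CoT over a velocity range
#'
#' Evaluates the exact antiderivative of the quadratic CoT curve between
#' the limits: `integral of (c2 v^2 + c1 v + c0) dv` from `v_min` to
#' `v_max`.
#'
#' @param curve A `cot_curve`, or a numeric vector `c(c0, c1, c2)` of
#'   ascending-power coefficients.
#' @param v_min,v_max Integration limits (m/s), `v_min <= v_max`; default
#'   the curve's fitted range.
#' @return The integrated CoT (units CoT * m/s).
#' @examples
#' integrate_cot(c(0.4, 0, 0), 0.7, 1.6)  # 0.36
#' @export
integrate_cot <- function(curve, v_min = NULL, v_max = NULL) {
  if (inherits(curve, "cot_curve")) {
    co <- curve$coefficients
    if (is.null(v_min)) v_min <- curve$range[1]
    if (is.null(v_max)) v_max <- curve$range[2]
  } else {
    co <- curve
  }
  if (is.null(v_min) || is.null(v_max)) stop("integration limits required")
  if (v_min > v_max) stop("v_min must not exceed v_max")
  anti <- function(v) co[[1]] * v + co[[2]] * v^2 / 2 + co[[3]] * v^3 / 3
  anti(v_max) - anti(v_min)
}

#' Relative change in integrated CoT
#'
#' `100 * (test - baseline) / |baseline|` (percent); negative means the
#' test condition is more energy-efficient than the baseline.
#'
#' @param test,baseline Integrated CoT values; baseline must be non-zero.
#' @return Percent change.
#' @export
relative_icot <- function(test, baseline) {
  if (any(baseline == 0)) stop("baseline must be non-zero")
  100 * (test - baseline) / abs(baseline)
}

#' Evaluate a modulator's CoT across velocities
#'
#' Runs the evaluator at each target velocity (with one trial per
#' replicate seed), applying the steady-walking gate (the trial must cover
#' more than `min_distance` metres without falling) and the
#' velocity-tracking exclusion rule (target velocities whose achieved
#' speed deviates by more than `v_tol` are excluded from curve fitting).
#' CoT per velocity is the mean over surviving replicates.
#'
#' @param mod A `gait_modulator`.
#' @param evaluator Gait evaluator `(Y, v_tar, seed) -> trial_trace`.
#' @param v_grid Target velocities (m/s).
#' @param seeds Integer vector of replicate seeds (default one replicate).
#' @param weights A `cost_weights`.
#' @param v_tol Velocity-tracking tolerance (m/s, default 0.05).
#' @param min_distance Steady-walking distance gate (m, default 30).
#' @return data.frame with one row per target velocity: `v_tar`, achieved
#'   `v_x`, `cot`, `n_ok` surviving replicates, `excluded` flag.
#' @export
evaluate_modulator_cot <- function(mod, evaluator, v_grid, seeds = 1L,
                                   weights = cost_weights(), v_tol = 0.05,
                                   min_distance = 30) {
  rows <- lapply(v_grid, function(v_tar) {
    Y <- suppressWarnings(modulate(mod, v_tar))
    vx <- c(); cc <- c()
    for (s in seeds) {
      tr <- evaluator(Y, v_tar, s)
      if (!tr$fell && tr$total_distance > min_distance) {
        vx <- c(vx, mean(tr$v_x))
        cc <- c(cc, trace_cot(tr, weights))
      }
    }
    if (!length(vx)) {
      return(data.frame(v_tar = v_tar, v_x = NA_real_, cot = NA_real_,
                        n_ok = 0L, excluded = TRUE))
    }
    data.frame(v_tar = v_tar, v_x = mean(vx), cot = mean(cc),
               n_ok = length(vx),
               excluded = abs(mean(vx) - v_tar) > v_tol)
  })
  do.call(rbind, rows)
}

#' Integrated CoT of a modulator on an evaluator
#'
#' Convenience wrapper: evaluates the modulator across the velocity grid,
#' drops excluded velocities, fits the quadratic CoT curve on the
#' survivors and integrates it.
#'
#' @inheritParams evaluate_modulator_cot
#' @param v_range Optional integration limits (default: span of surviving
#'   velocities).
#' @return List with `samples` (the evaluation table), `curve`
#'   (`cot_curve`), `icot`, and the integration `range` used.
#' @export
modulator_icot <- function(mod, evaluator, v_grid, seeds = 1L,
                           weights = cost_weights(), v_tol = 0.05,
                           min_distance = 30, v_range = NULL) {
  samples <- evaluate_modulator_cot(mod, evaluator, v_grid, seeds, weights,
                                    v_tol, min_distance)
  ok <- !samples$excluded
  if (sum(ok) < 3L) {
    stop("fewer than 3 surviving velocities; integrated CoT not computable")
  }
  curve <- fit_cot_curve(samples$v_x[ok], samples$cot[ok])
  if (is.null(v_range)) v_range <- range(samples$v_x[ok])
  list(samples = samples, curve = curve,
       icot = integrate_cot(curve, v_range[1], v_range[2]),
       range = v_range)
}

#' Circuit-substitution experiment
#'
#' For each parameter group, builds the hybrid modulator in which only
#' that group's polynomials are replaced by the donor's, evaluates it over
#' the velocity grid, fits a quadratic CoT curve on the velocities that
#' pass the steady-walking gate and the `v_tol` tracking rule, and
#' integrates over the common velocity range (intersection of the
#' baseline's and all groups' surviving ranges, so all conditions are
#' compared on identical limits).
#'
#' @param base Baseline `gait_modulator` (e.g. the A = 1 fit).
#' @param donor Donor `gait_modulator` (e.g. the A = 1e6 fit).
#' @param groups Named list of character vectors of parameter names (see
#'   [circuit_groups()]).
#' @param evaluator Gait evaluator.
#' @param v_grid Target velocities.
#' @param seeds Replicate seeds.
#' @param weights A `cost_weights`.
#' @param v_tol Velocity-tracking tolerance (m/s).
#' @param min_distance Steady-walking gate (m).
#' @return data.frame of class `substitution_result`: one row per group
#'   with `group`, `baseline_icot`, `substituted_icot`,
#'   `relative_change_pct`, `abs_change_pct`, `n_excluded`, `computable`.
#' @export
substitution_experiment <- function(base, donor, groups, evaluator, v_grid,
                                    seeds = 1L, weights = cost_weights(),
                                    v_tol = 0.05, min_distance = 30) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))

  base_samples <- evaluate_modulator_cot(base, evaluator, v_grid, seeds,
                                         weights, v_tol, min_distance)
  cond_samples <- lapply(groups, function(nms) {
    hybrid <- substitute_functions(base, donor, nms)
    evaluate_modulator_cot(hybrid, evaluator, v_grid, seeds, weights,
                           v_tol, min_distance)
  })

  ## common integration range: intersection of surviving spans
  spans <- lapply(c(list(base_samples), cond_samples), function(s) {
    ok <- !s$excluded
    if (sum(ok) < 3L) NULL else range(s$v_x[ok])
  })
  spans <- spans[!vapply(spans, is.null, logical(1))]
  if (!length(spans)) stop("no condition has 3 surviving velocities")
  v_lo <- max(vapply(spans, `[`, numeric(1), 1L))
  v_hi <- min(vapply(spans, `[`, numeric(1), 2L))
  if (v_lo >= v_hi) stop("surviving velocity ranges do not overlap")

  ok <- !base_samples$excluded
  base_icot <- integrate_cot(fit_cot_curve(base_samples$v_x[ok],
                                           base_samples$cot[ok]),
                             v_lo, v_hi)

  rows <- mapply(function(nm, s) {
    ok <- !s$excluded
    if (sum(ok) < 3L) {
      return(data.frame(group = nm, baseline_icot = base_icot,
                        substituted_icot = NA_real_,
                        relative_change_pct = NA_real_,
                        abs_change_pct = NA_real_,
                        n_excluded = sum(s$excluded), computable = FALSE))
    }
    icot <- integrate_cot(fit_cot_curve(s$v_x[ok], s$cot[ok]), v_lo, v_hi)
    rel <- relative_icot(icot, base_icot)
    data.frame(group = nm, baseline_icot = base_icot,
               substituted_icot = icot, relative_change_pct = rel,
               abs_change_pct = abs(rel), n_excluded = sum(s$excluded),
               computable = TRUE)
  }, names(groups), cond_samples, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("substitution_result", "data.frame")
  attr(out, "range") <- c(v_lo, v_hi)
  out
}

#' Per-muscle energy over the first stretch of a walk
#'
#' Sums each muscle's metabolic energy over the first `distance` metres of
#' a trial, optionally reporting per-muscle differences against a baseline
#' trace over the same distance.
#'
#' @param trace A `trial_trace` carrying either a per-step, per-muscle
#'   energy matrix or per-muscle totals (`muscle_energy`).
#' @param distance Window length (m, default 30); the trace must cover it.
#' @param baseline Optional baseline `trial_trace`.
#' @return data.frame with columns `muscle`, `energy` and, with a
#'   baseline, `baseline_energy` and `diff`.
#' @export
muscle_energy_breakdown <- function(trace, distance = 30, baseline = NULL) {
  window_energy <- function(tr) {
    cum <- cumsum(tr$distance)
    if (cum[length(cum)] < distance) {
      stop("trace covers only ", format(cum[length(cum)], digits = 4),
           " m < requested ", distance, " m")
    }
    k <- which(cum >= distance)[1L]
    if (!is.null(tr$energy)) {
      colSums(tr$energy[seq_len(k), , drop = FALSE])
    } else if (!is.null(tr$muscle_energy)) {
      frac <- sum(tr$energy_steps[seq_len(k)]) / tr$total_energy
      tr$muscle_energy * frac
    } else {
      stop("trace has no per-muscle energy information")
    }
  }
  e <- window_energy(trace)
  out <- data.frame(muscle = names(e), energy = as.numeric(e),
                    row.names = NULL)
  if (!is.null(baseline)) {
    b <- window_energy(baseline)
    out$baseline_energy <- as.numeric(b[out$muscle])
    out$diff <- out$energy - out$baseline_energy
  }
  out
}
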