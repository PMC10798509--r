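## Deterministic surrogate gait evaluator. This is explicitly NOT a
## physics model: it encodes only the structural features the modulation
## method exploits — a velocity-dependent optimal parameter set, CoT that
## grows with deviation from it, a concave-up quadratic CoT-velocity law,
## instability (falls) far from the optimum, and a baseline fall rate so
## that roughly half of all optimisation trials are admitted.

#' Surrogate evaluator configuration
#'
#' Defines the surrogate's ground truth: per-parameter smooth optimal
#' curves `y*_i(v)` (quadratic in `v - 1.25`, centred on the registry
#' defaults, with slopes/curvatures drawn once from `seed`), the quadratic
#' CoT-velocity law `CoT = c2 v^2 + c1 v + c0` (default minimum 0.3 at
#' 1.2 m/s, matching the plausible human band), the efficiency penalty
#' mapping parameter deviation to excess CoT, the velocity coupling that
#' makes achieved speed depend on the parameters, the stability radius
#' beyond which the model falls, a baseline stochastic fall rate, and
#' noise scales.
#'
#' @param seed Seed fixing the ground-truth curves (part of the config, not
#'   of trial randomness).
#' @param cot_curve Named numeric `c(c2, c1, c0)`; `c2` must be positive.
#' @param penalty_scale Excess CoT per unit squared parameter deviation.
#' @param v_gain Achieved-velocity sensitivity to the signed parameter
#'   deviation projection.
#' @param stability_radius RMS parameter deviation beyond which the trial
#'   falls.
#' @param fall_rate Baseline probability that a trial falls regardless of
#'   parameters (emulates the roughly 50% of optimisation trials that do
#'   not survive to the timestep limit).
#' @param noise_v,noise_cot Standard deviations of velocity and CoT noise.
#' @param T Trial length in timesteps.
#' @param dt Timestep (s).
#' @return List of class `surrogate_config` including the `56 x 3`
#'   ground-truth coefficient matrix `truth` (columns: constant, linear,
#'   quadratic in `v - 1.25`) and the signed coupling vector `w_v`.
#' @export
surrogate_config <- function(seed = 42L,
                             cot_curve = c(c2 = 0.4, c1 = -0.96, c0 = 0.876),
                             penalty_scale = 3.0, v_gain = 2.0,
                             stability_radius = 0.8, fall_rate = 0.45,
                             noise_v = 0.02, noise_cot = 0.002,
                             T = 5000L, dt = 0.005) {
  if (cot_curve[["c2"]] <= 0) stop("c2 must be positive (concave-up CoT)")
  if (stability_radius <= 0) stop("stability radius must be positive")
  reg <- parameter_registry()
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  scale <- (reg$upper - reg$lower) / 4
  truth <- cbind(const = reg$default,
                 lin = scale * stats::runif(56, -0.10, 0.10),
                 quad = scale * stats::runif(56, -0.05, 0.05))
  rownames(truth) <- reg$name
  w_v <- sample(c(-1, 1), 56, replace = TRUE)
  structure(list(seed = seed, cot_curve = cot_curve,
                 penalty_scale = penalty_scale, v_gain = v_gain,
                 stability_radius = stability_radius, fall_rate = fall_rate,
                 noise_v = noise_v, noise_cot = noise_cot,
                 T = as.integer(T), dt = dt,
                 truth = truth, w_v = w_v),
            class = "surrogate_config")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

#' Ground-truth optimal parameters at a velocity
#'
#' Evaluates the surrogate's velocity-dependent optimal parameter curves
#' `y*_i(v)`.
#'
#' @param config A `surrogate_config`.
#' @param v Velocity (m/s), scalar.
#' @return Named 56-entry parameter vector.
#' @export
surrogate_truth <- function(config, v) {
  dv <- v - 1.25
  stats::setNames(config$truth[, 1] + config$truth[, 2] * dv +
                    config$truth[, 3] * dv^2,
                  rownames(config$truth))
}

## RMS deviation from the optimal parameter set (raw parameter units)
surrogate_deviation <- function(config, Y, v) {
  dy <- Y - surrogate_truth(config, v)
  sqrt(mean(dy^2))
}

#' Surrogate CoT at a velocity and deviation
#'
#' `CoT(v, d) = c2 v^2 + c1 v + c0 + penalty_scale * d^2`, floored at 0.05.
#'
#' @param config A `surrogate_config`.
#' @param v_x Achieved velocity (m/s).
#' @param d RMS parameter deviation (default 0: on the optimum).
#' @return CoT value.
#' @export
surrogate_cot <- function(config, v_x, d = 0) {
  cc <- config$cot_curve
  pmax(0.05, cc[["c2"]] * v_x^2 + cc[["c1"]] * v_x + cc[["c0"]] +
         config$penalty_scale * d^2)
}

#' Evaluate a control parameter set on the surrogate
#'
#' Deterministic (given `seed`) stand-in for a full musculoskeletal trial:
#' the achieved velocity is the target plus a bias proportional to the
#' signed deviation projection plus noise; the CoT follows the quadratic
#' velocity law plus an efficiency penalty growing with the squared
#' deviation from the optimal parameters; the trial falls when the
#' deviation exceeds the stability radius, or with the baseline fall
#' probability. The returned trace has per-step velocity, torso angle,
#' energy and distance fields so [trial_cost()] is computable, plus
#' per-muscle total energies for breakdown analyses.
#'
#' @param Y Named 56-entry control parameter vector.
#' @param v_tar Target velocity (m/s).
#' @param seed Integer trial seed.
#' @param config A `surrogate_config`.
#' @param weights A `cost_weights` (mass/gravity used to translate CoT to
#'   energy).
#' @return A `trial_trace` with an extra `muscle_energy` field (named
#'   per-muscle total energies, J).
#' @export
surrogate_evaluate <- function(Y, v_tar, seed = 1L,
                               config = surrogate_config(),
                               weights = cost_weights()) {
  Y <- validate_parameters(Y)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed %% .Machine$integer.max))

  d <- surrogate_deviation(config, Y, v_tar)
  dy <- Y - surrogate_truth(config, v_tar)
  proj <- mean(config$w_v * dy)
  v_x <- max(0.05, v_tar + config$v_gain * proj +
               stats::rnorm(1, 0, config$noise_v))
  cot_val <- surrogate_cot(config, v_x, d) +
    stats::rnorm(1, 0, config$noise_cot)
  cot_val <- max(0.05, cot_val)

  fell <- d > config$stability_radius ||
    stats::runif(1) < config$fall_rate
  T_prime <- if (fell) {
    max(2L, as.integer(stats::runif(1, 0.1, 0.98) * config$T))
  } else {
    config$T
  }

  dist_step <- rep(v_x * config$dt, T_prime)
  total_dist <- sum(dist_step)
  J <- cot_val * weights$mass * weights$gravity * total_dist
  energy_steps <- rep(J / T_prime, T_prime)
  theta_t <- rep(0.02 + 0.1 * min(d, 1), T_prime)

  trace <- trial_trace(v_x = rep(v_x, T_prime), theta_t = theta_t,
                       energy = energy_steps, distance = dist_step,
                       fell = fell, dt = config$dt)
  mp <- muscle_params()
  share <- mp$F0 * mp$l0 / sum(mp$F0 * mp$l0)
  trace$muscle_energy <- stats::setNames(J * share, mp$name)
  trace
}

#' Wrap a surrogate config as a gait evaluator
#'
#' @param config A `surrogate_config`.
#' @param weights A `cost_weights`.
#' @return Function `(Y, v_tar, seed) -> trial_trace` suitable for
#'   [velocity_sweep()] and [substitution_experiment()].
#' @export
surrogate_evaluator <- function(config = surrogate_config(),
                                weights = cost_weights()) {
  force(config); force(weights)
  function(Y, v_tar, seed) surrogate_evaluate(Y, v_tar, seed, config, weights)
}

#' Two-level illustrative PWLS dataset
#'
#' The 18 x 9 toy dataset used to illustrate performance weighting: at each
#' of 18 velocities (0.4 to 2.1 m/s) one record lies exactly on a smooth
#' efficient curve and carries the low CoT value 0.5, while the eight
#' others are offset from the curve and carry the high CoT value 1.0. Only
#' the `G_HFL` column varies; all other parameters sit at registry
#' defaults.
#'
#' @return A `gait_dataset` with 162 records (velocity-sorted).
#' @export
make_twolevel_dataset <- function() {
  v <- seq(0.4, 2.1, by = 0.1)
  curve <- function(v) 1.0 + 0.5 * sin(2.5 * (v - 1.2))
  offsets <- c(0, 0.15, 0.3, 0.45, 0.6, 0.75, -0.15, -0.3, -0.45)
  v_all <- rep(v, each = length(offsets))
  y_all <- curve(v_all) + rep(offsets, times = length(v))
  cot_all <- ifelse(rep(offsets == 0, times = length(v)), 0.5, 1.0)
  params <- matrix(rep(parameter_vector(), each = length(v_all)),
                   nrow = length(v_all),
                   dimnames = list(NULL, parameter_names()))
  params[, "G_HFL"] <- y_all
  gait_dataset(v_all, cot_all, params)
}

#' Generate a bulk synthetic gait dataset
#'
#' Samples `n` records with velocities uniform over `v_range`, control
#' parameters scattered around the surrogate's optimal curves with the
#' given normalised spread, and CoT following the quadratic velocity law
#' plus the deviation penalty and observation noise. With `param_noise = 0`
#' and `cot_noise = 0` every record lies exactly on `y*(v)` and the CoT
#' curve.
#'
#' @param n Number of records.
#' @param config A `surrogate_config`.
#' @param seed Integer seed.
#' @param v_range Velocity range (m/s).
#' @param param_noise Per-parameter deviation scale (raw units).
#' @param cot_noise CoT observation noise sd.
#' @return A `gait_dataset`.
#' @export
generate_dataset <- function(n, config = surrogate_config(), seed = 1L,
                             v_range = c(0.4, 2.0), param_noise = 0.01,
                             cot_noise = 0.02) {
  if (n <= 0) stop("n must be positive")
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(as.integer(seed %% .Machine$integer.max))
  v <- stats::runif(n, v_range[1], v_range[2])
  params <- t(vapply(v, function(vv) surrogate_truth(config, vv),
                     numeric(56)))
  if (param_noise > 0) {
    params <- params + matrix(stats::rnorm(n * 56, 0, param_noise), n, 56)
  }
  colnames(params) <- parameter_names()
  d <- sqrt(rowMeans((params - t(vapply(v, function(vv)
    surrogate_truth(config, vv), numeric(56))))^2))
  cot_val <- surrogate_cot(config, v, d)
  if (cot_noise > 0) cot_val <- cot_val + stats::rnorm(n, 0, cot_noise)
  cot_val <- pmax(0.05, cot_val)
  gait_dataset(v, cot_val, params)
}
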