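## Trial evaluation: per-step rewards, fall penalty, metabolic energy, CoT
## and the total gait-optimization objective.

#' Objective cost weights
#'
#' The weights and constants of the gait objective: `alpha_E` scales the
#' CoT term, `alpha_v` the velocity-tracking penalty, `alpha_t` the torso
#' penalty; `cot_offset` is the deviation subtracted from the CoT before
#' weighting; `T` is the per-trial timestep limit (5000 steps = 25 s at a
#' 5 ms step); a fall within `fall_window` steps incurs `fall_penalty`.
#' `cot_cap` bounds the CoT term for zero-distance trials (immediate falls)
#' so the objective stays finite. `forward_shift` optionally subtracts 1
#' from the velocity penalty so it spans \[-1, 0\] instead of \[0, 1\].
#'
#' @param alpha_E,alpha_v,alpha_t Weight coefficients.
#' @param cot_offset CoT deviation constant.
#' @param T Maximum trial length in timesteps.
#' @param fall_window Fall-penalty window in timesteps.
#' @param fall_penalty Penalty added for an early fall.
#' @param cot_cap CoT value substituted when distance is zero.
#' @param forward_shift Subtract 1 from the velocity penalty?
#' @param mass Model mass (kg).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param dt Simulation timestep (s).
#' @return A list of class `cost_weights`.
#' @export
cost_weights <- function(alpha_E = 5000, alpha_v = 5, alpha_t = 1.0,
                         cot_offset = 0.3, T = 5000L, fall_window = 700L,
                         fall_penalty = 5000, cot_cap = 10,
                         forward_shift = FALSE,
                         mass = 80, gravity = 9.81, dt = 0.005) {
  structure(list(alpha_E = alpha_E, alpha_v = alpha_v, alpha_t = alpha_t,
                 cot_offset = cot_offset, T = as.integer(T),
                 fall_window = as.integer(fall_window),
                 fall_penalty = fall_penalty, cot_cap = cot_cap,
                 forward_shift = forward_shift,
                 mass = mass, gravity = gravity, dt = dt),
            class = "cost_weights")
}

#' Per-step reward components
#'
#' `r_alive = -1` (rewards surviving steps), `r_forward =
#' min(1, alpha_v * |v_x - v_tar|^2)` (velocity tracking penalty, capped),
#' `r_torso = alpha_t * theta_t^2` (upright-torso penalty). Vectorised over
#' steps.
#'
#' @param v_x Horizontal velocity (m/s).
#' @param v_tar Target velocity (m/s).
#' @param theta_t Torso angle (rad).
#' @param weights A `cost_weights` object.
#' @return List with `r_alive`, `r_forward`, `r_torso`.
#' @export
step_reward <- function(v_x, v_tar, theta_t, weights = cost_weights()) {
  r_forward <- pmin(1, weights$alpha_v * abs(v_x - v_tar)^2)
  if (isTRUE(weights$forward_shift)) r_forward <- r_forward - 1
  list(r_alive = rep(-1, length(v_x)),
       r_forward = r_forward,
       r_torso = weights$alpha_t * theta_t^2)
}

#' Early-fall penalty
#'
#' Adds `fall_penalty` only when the model fell and did so within
#' `fall_window` timesteps of the start; discourages local minima where the
#' model pitches forward immediately.
#'
#' @param fell Logical fall flag.
#' @param T_prime Trial length in timesteps.
#' @param weights A `cost_weights` object.
#' @return Penalty (0 or `fall_penalty`).
#' @export
fall_cost <- function(fell, T_prime, weights = cost_weights()) {
  if (T_prime < 0) stop("T_prime must be non-negative")
  if (isTRUE(fell) && T_prime <= weights$fall_window) weights$fall_penalty else 0
}

#' Metabolic model constants
#'
#' The adopted metabolic-energy model follows the usual activation /
#' maintenance / shortening-heat plus positive-mechanical-work structure.
#' Rates are normalised by `F0 * l0` so constants are dimensionless except
#' where noted. All terms are non-negative and the rate is non-decreasing
#' in activation at fixed kinematics.
#'
#' @return Named list: `c_basal` basal rate (1/s), `c_act` activation heat
#'   coefficient (1/s), `c_maint` maintenance heat coefficient (1/s),
#'   `c_short` shortening heat coefficient, `eff_work` efficiency divisor
#'   for positive mechanical work.
#' @export
metabolic_constants <- function() {
  list(c_basal = 0.01, c_act = 0.4, c_maint = 0.3, c_short = 0.25,
       eff_work = 0.25)
}

#' Metabolic energy rate of one muscle
#'
#' Rate (W) = `F0*l0*(c_basal + c_act*a^2 + c_maint*a*Fl(l))` +
#' shortening heat `c_short*F*max(0, -v)` + positive mechanical work
#' `F*max(0, -v)/eff_work` (shortening does positive work under the
#' convention that negative scaled velocity is shortening; `v` here is the
#' unscaled velocity in m/s).
#'
#' @param a Activation in \[0, 1\].
#' @param F Muscle force (N).
#' @param v Muscle velocity (m/s), negative = shortening.
#' @param F0 Maximum isometric force (N).
#' @param l0 Rest length (m).
#' @param l_scaled Scaled length (for the maintenance-heat factor).
#' @param const Metabolic constants, see [metabolic_constants()].
#' @return Energy rate in W (non-negative).
#' @export
metabolic_rate <- function(a, F, v, F0, l0, l_scaled = 1,
                           const = metabolic_constants()) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  fl <- force_factors(l_scaled, 0)$Fl
  heat <- F0 * l0 * (const$c_basal + const$c_act * a^2 +
                       const$c_maint * a * fl)
  short_v <- pmax(0, -v)
  heat + const$c_short * F * short_v + F * short_v / const$eff_work
}

#' Cost of transport
#'
#' `CoT = J / (M * g * distance)`: metabolic energy per unit weight per
#' unit distance travelled. Dimensionless; lower is more efficient.
#'
#' @param J Total metabolic energy (J).
#' @param mass Mass (kg).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param distance Distance travelled (m), must be positive.
#' @return CoT value.
#' @examples
#' cot(784.8, 80, 9.81, 1)  # 1
#' @export
cot <- function(J, mass = 80, gravity = 9.81, distance) {
  if (mass <= 0 || gravity <= 0) stop("mass and gravity must be positive")
  if (any(distance <= 0)) stop("distance must be positive")
  J / (mass * gravity * distance)
}

#' Construct a trial trace
#'
#' The per-timestep record of one gait evaluation: horizontal velocity,
#' torso angle, per-muscle metabolic energy increments and distance
#' increments, plus the terminal length `T_prime` and fall flag.
#'
#' @param v_x Numeric vector (length `T_prime`) of velocities (m/s).
#' @param theta_t Numeric vector of torso angles (rad).
#' @param energy Matrix `T_prime x 8` of per-muscle energy increments (J),
#'   columns named by muscle; or a numeric vector of per-step totals.
#' @param distance Numeric vector of per-step distance increments (m).
#' @param fell Logical fall flag.
#' @param dt Timestep (s).
#' @return List of class `trial_trace` with derived fields `T_prime`,
#'   `total_energy`, `total_distance`.
#' @export
trial_trace <- function(v_x, theta_t, energy, distance, fell = FALSE,
                        dt = 0.005) {
  T_prime <- length(v_x)
  stopifnot(length(theta_t) == T_prime, length(distance) == T_prime)
  if (is.matrix(energy)) {
    stopifnot(nrow(energy) == T_prime)
    energy_steps <- rowSums(energy)
  } else {
    stopifnot(length(energy) == T_prime)
    energy_steps <- energy
    energy <- NULL
  }
  if (any(energy_steps < -1e-12)) stop("energy increments must be >= 0")
  structure(list(v_x = v_x, theta_t = theta_t,
                 energy = energy, energy_steps = energy_steps,
                 distance = distance, fell = isTRUE(fell), dt = dt,
                 T_prime = T_prime,
                 total_energy = sum(energy_steps),
                 total_distance = sum(distance)),
            class = "trial_trace")
}

#' CoT of a trial trace
#'
#' @param trace A `trial_trace`.
#' @param weights A `cost_weights` (mass, gravity, zero-distance cap).
#' @return The CoT; for zero (or negative) distance the configured
#'   `cot_cap` is returned so downstream objectives stay finite.
#' @export
trace_cot <- function(trace, weights = cost_weights()) {
  if (trace$total_distance <= 0) return(weights$cot_cap)
  cot(trace$total_energy, weights$mass, weights$gravity,
      trace$total_distance)
}

#' Total objective cost of a trial
#'
#' `f = sum_t (r_alive + r_forward + r_torso) + fall_cost +
#' alpha_E * (CoT - cot_offset)`. Lower is better; a perfect full-length
#' trial with exact tracking, upright torso and CoT equal to the offset
#' scores `-T`.
#'
#' @param trace A `trial_trace`.
#' @param v_tar Target velocity (m/s).
#' @param weights A `cost_weights` object.
#' @return Scalar objective value.
#' @export
trial_cost <- function(trace, v_tar, weights = cost_weights()) {
  r <- step_reward(trace$v_x, v_tar, trace$theta_t, weights)
  sum(r$r_alive + r$r_forward + r$r_torso) +
    fall_cost(trace$fell, trace$T_prime, weights) +
    weights$alpha_E * (trace_cot(trace, weights) - weights$cot_offset)
}
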