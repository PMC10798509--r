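## Hill-type muscle actuator: scaled state, force curves, activation dynamics.

#' Muscle actuator parameter table
#'
#' Per-muscle constants of the Hill-type actuators: maximum isometric force
#' `F0` (N), tendon rest/equilibrium length `l0` (m) and the sensory time
#' delay `delay` (s) of the pathway the muscle's afferents travel. The eight
#' muscles per leg are soleus (SOL), tibialis anterior (TA), gastrocnemius
#' (GAS), vasti (VAS), hamstring (HAM), rectus femoris (RF), gluteal (GLU)
#' and hip flexor (HFL). The default `F0` values are the standard ones for
#' this model family. Delays default to 20 ms for the ankle muscles, 10 ms
#' for the knee and 5 ms for the hip pathway.
#'
#' @param overrides Optional data.frame with a `name` column plus any of
#'   `F0`, `l0`, `delay` to override defaults.
#' @return data.frame with columns `name`, `F0`, `l0`, `delay`.
#' @examples
#' muscle_params()$F0  # SOL 4000 ... HFL 2000
#' @export
muscle_params <- function(overrides = NULL) {
  tab <- data.frame(
    name  = c("SOL", "TA", "GAS", "VAS", "HAM", "RF", "GLU", "HFL"),
    F0    = c(4000, 800, 1500, 6000, 3000, 1000, 1500, 2000),
    l0    = c(0.04, 0.06, 0.05, 0.08, 0.10, 0.08, 0.11, 0.11),
    delay = c(0.020, 0.020, 0.020, 0.010, 0.010, 0.010, 0.005, 0.005),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "name" %in% names(overrides))
    for (col in intersect(c("F0", "l0", "delay"), names(overrides))) {
      idx <- match(overrides$name, tab$name)
      if (anyNA(idx)) stop("unknown muscle name in overrides")
      tab[[col]][idx] <- overrides[[col]]
    }
  }
  if (any(tab$F0 <= 0) || any(tab$l0 <= 0) || any(tab$delay < 0)) {
    stop("invalid muscle parameters: need F0 > 0, l0 > 0, delay >= 0")
  }
  tab
}

#' Constants of the adopted muscle force curves
#'
#' The exact force-length, force-velocity and passive-force curves of the
#' source controller are not public; the package adopts the standard
#' Geyer/Herr-style closed forms (bell-shaped force-length peaking at the
#' rest length, Hill-type force-velocity equal to 1 at zero velocity and 0
#' at the maximum shortening speed, passive force zero at or below rest
#' length and growing quadratically above it). All curve constants live in
#' this one block so the assumption is explicit and overridable.
#'
#' @return Named list: `w` force-length width, `c` log of the residual
#'   force at the curve edge, `v_max` maximum shortening speed (rest
#'   lengths/s), `K` force-velocity curvature, `N` eccentric force
#'   enhancement, `w_p` passive-force reference stretch.
#' @export
muscle_curve_constants <- function() {
  list(w = 0.56, c = log(0.05), v_max = 12, K = 5, N = 1.5, w_p = 0.56)
}

#' Scale muscle length and velocity by the rest length
#'
#' Dimensionless muscle state: length and contraction velocity are divided
#' by the tendon equilibrium length `l0`, so a scaled length of 1 is the
#' rest length and scaled velocity has units 1/s.
#'
#' @param l Muscle length (m).
#' @param v Muscle velocity (m/s); negative = shortening.
#' @param l0 Rest/equilibrium length (m), must be positive.
#' @return List with `l_scaled` and `v_scaled`.
#' @examples
#' scale_state(0.6, 0.1, 0.5)  # l_scaled 1.2, v_scaled 0.2
#' @export
scale_state <- function(l, v, l0) {
  if (!is.numeric(l0) || any(l0 <= 0)) stop("l0 must be positive")
  list(l_scaled = l / l0, v_scaled = v / l0)
}

#' Force-length, force-velocity and passive force factors
#'
#' Evaluates the three dimensionless factors of the Hill-type force law at
#' a scaled muscle state. `Fl` is bell-shaped with maximum 1 at scaled
#' length 1; `Fv` equals 1 at zero velocity, falls to 0 at the maximum
#' shortening speed and rises toward the eccentric plateau for lengthening;
#' `Fp` is 0 at or below the rest length and increases monotonically above
#' it.
#'
#' @param l_scaled Scaled length (dimensionless, > 0). Vectorised.
#' @param v_scaled Scaled velocity (1/s); negative = shortening. Vectorised.
#' @param const Curve constants, see [muscle_curve_constants()].
#' @return List with numeric `Fl`, `Fv`, `Fp`.
#' @examples
#' force_factors(1, 0)  # Fl = 1, Fv = 1, Fp = 0
#' @export
force_factors <- function(l_scaled, v_scaled, const = muscle_curve_constants()) {
  if (any(l_scaled <= 0)) stop("l_scaled must be positive")
  n <- max(length(l_scaled), length(v_scaled))
  l_scaled <- rep_len(l_scaled, n)
  v_scaled <- rep_len(v_scaled, n)

  Fl <- exp(const$c * abs((l_scaled - 1) / const$w)^3)

  Fv <- numeric(n)
  sh <- v_scaled <= 0  # shortening (or isometric)
  vs <- pmax(v_scaled[sh], -const$v_max)
  Fv[sh] <- (const$v_max + vs) / (const$v_max - const$K * vs)
  vl <- v_scaled[!sh]
  Fv[!sh] <- const$N + (const$N - 1) *
    (const$v_max + vl) / (7.56 * const$K * vl - const$v_max)
  Fv <- pmax(Fv, 0)

  Fp <- ifelse(l_scaled > 1, ((l_scaled - 1) / const$w_p)^2, 0)

  list(Fl = Fl, Fv = Fv, Fp = Fp)
}

#' Hill-type actuator force
#'
#' `F = (a * Fl * Fv + Fp) * F0`: active force scaled by activation and the
#' force-length/velocity factors, plus the always-present passive force.
#' Affine in the activation at fixed kinematic state.
#'
#' @param a Activation level in \[0, 1\].
#' @param l_scaled,v_scaled Scaled muscle state.
#' @param F0 Maximum isometric force (N).
#' @param const Curve constants.
#' @return Force in N (non-negative).
#' @examples
#' actuator_force(1, 1, 0, F0 = 4000)  # 4000
#' @export
actuator_force <- function(a, l_scaled, v_scaled, F0,
                           const = muscle_curve_constants()) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  if (any(F0 <= 0)) stop("F0 must be positive")
  ff <- force_factors(l_scaled, v_scaled, const)
  (a * ff$Fl * ff$Fv + ff$Fp) * F0
}

#' Activation time constant
#'
#' The first-order excitation-activation dynamics use an asymmetric time
#' constant: fast during activation (`u > a`), slower during deactivation,
#' both modulated by the current activation level:
#' `tau = 0.01 * (0.5 + 1.5 a)` when `u > a`, `tau = 0.04 / (0.5 + 1.5 a)`
#' when `u <= a` (seconds).
#'
#' @param u Stimulation in \[0, 1\].
#' @param a Activation in \[0, 1\].
#' @return Time constant in s.
#' @examples
#' activation_tau(0.6, 0.2)  # 0.008
#' activation_tau(0.1, 0.5)  # 0.032
#' @export
activation_tau <- function(u, a) {
  ifelse(u > a, 0.01 * (0.5 + 1.5 * a), 0.04 / (0.5 + 1.5 * a))
}

#' One explicit-Euler step of the activation dynamics
#'
#' Integrates `da/dt = (u - a) / tau(u, a)` over one timestep and clamps
#' the result to \[0, 1\].
#'
#' @param u Stimulation in \[0, 1\].
#' @param a Current activation in \[0, 1\].
#' @param dt Timestep (s), default 0.005 (the simulation step).
#' @return Updated activation.
#' @export
activation_step <- function(u, a, dt = 0.005) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar")
  }
  if (any(u < 0 | u > 1)) stop("stimulation must lie in [0, 1]")
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  a_new <- a + dt * (u - a) / activation_tau(u, a)
  pmin(pmax(a_new, 0), 1)
}

#' Simulate activation dynamics over a stimulation sequence
#'
#' @param u Numeric vector of stimulations in \[0, 1\] (one per step).
#' @param a0 Initial activation.
#' @param dt Timestep (s).
#' @return Numeric vector of activations after each step.
#' @export
simulate_activation <- function(u, a0 = 0, dt = 0.005) {
  a <- numeric(length(u))
  cur <- a0
  for (k in seq_along(u)) {
    cur <- activation_step(u[k], cur, dt)
    a[k] <- cur
  }
  a
}
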