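## Reflex-based stimulation laws: delayed sensory feedback, force/length
## feedback, muscle-driven PD control, phase gating per leg.

MUSCLES <- c("SOL", "TA", "GAS", "VAS", "HAM", "RF", "GLU", "HFL")
LEG_PHASES <- c("stance", "late_stance", "swing", "late_swing",
                "stance_preparation")

#' Construct a sensory sample
#'
#' A snapshot of the delayed-sensing channels the reflex controller reads:
#' per-muscle scaled force and scaled length, joint angles/velocities
#' (torso `t`, hip `h`, knee `k`; rad, rad/s), ground-contact flag,
#' horizontal velocity and the hip-to-ankle horizontal offset `d` used by
#' SIMBICON foot placement.
#'
#' @param time Time (s).
#' @param force Named numeric (8): scaled muscle forces, non-negative.
#' @param length Named numeric (8): scaled muscle lengths.
#' @param theta Named numeric with entries `t`, `h`, `k` (rad).
#' @param theta_dot Named numeric with entries `t`, `h`, `k` (rad/s).
#' @param contact Logical ground-contact flag for the leg.
#' @param v_x Horizontal velocity (m/s).
#' @param d Hip-to-ankle horizontal offset (m).
#' @return A list of class `sensory_sample`.
#' @export
sensory_sample <- function(time, force = NULL, length = NULL,
                           theta = c(t = 0, h = 0, k = 0),
                           theta_dot = c(t = 0, h = 0, k = 0),
                           contact = TRUE, v_x = 0, d = 0) {
  if (is.null(force)) force <- stats::setNames(rep(0, 8), MUSCLES)
  if (is.null(length)) length <- stats::setNames(rep(1, 8), MUSCLES)
  force <- force[MUSCLES]; length <- length[MUSCLES]
  if (any(is.na(force)) || any(force < 0)) {
    stop("scaled muscle forces must be present for all muscles and >= 0")
  }
  structure(list(time = time, force = force, length = length,
                 theta = theta[c("t", "h", "k")],
                 theta_dot = theta_dot[c("t", "h", "k")],
                 contact = isTRUE(contact), v_x = v_x, d = d),
            class = "sensory_sample")
}

#' Create an empty sensory delay buffer
#'
#' Ring of timestamped sensory samples from which the controller reads
#' delayed signals. Lookups never extrapolate: before enough history
#' exists, the earliest stored sample is held (zero-order hold).
#'
#' @param capacity Maximum number of samples retained; must cover the
#'   largest sensory delay at the simulation timestep.
#' @return A list of class `delay_buffer`.
#' @export
delay_buffer <- function(capacity = 64L) {
  structure(list(samples = vector("list", 0L), capacity = as.integer(capacity)),
            class = "delay_buffer")
}

#' Append a sample to a delay buffer
#' @param buffer A `delay_buffer`.
#' @param sample A `sensory_sample` with time >= the last stored time.
#' @return The updated buffer.
#' @export
buffer_push <- function(buffer, sample) {
  stopifnot(inherits(buffer, "delay_buffer"),
            inherits(sample, "sensory_sample"))
  n <- length(buffer$samples)
  if (n > 0 && sample$time < buffer$samples[[n]]$time) {
    stop("sample times must be non-decreasing")
  }
  buffer$samples <- c(buffer$samples, list(sample))
  if (length(buffer$samples) > buffer$capacity) {
    buffer$samples <- buffer$samples[-1L]
  }
  buffer
}

#' Read a delayed sensory sample
#'
#' Returns the stored sample with the largest time not exceeding
#' `t - delay` (zero-order hold). For lookups before history exists the
#' earliest sample is returned.
#'
#' @param buffer A non-empty `delay_buffer`.
#' @param t Current time (s).
#' @param delay Sensory delay (s), non-negative.
#' @return A `sensory_sample`.
#' @export
sample_delayed <- function(buffer, t, delay) {
  stopifnot(inherits(buffer, "delay_buffer"))
  if (delay < 0) stop("delay must be non-negative")
  if (length(buffer$samples) == 0L) stop("delay buffer is empty")
  times <- vapply(buffer$samples, `[[`, numeric(1), "time")
  target <- t - delay
  idx <- findInterval(target, times)
  if (idx < 1L) idx <- 1L
  buffer$samples[[idx]]
}

#' Force feedback stimulation
#'
#' Positive force feedback (Golgi tendon organ pathway): the stimulation is
#' the gain times the delayed scaled muscle force, `u = G * F_scaled`.
#'
#' @param G Non-negative gain.
#' @param F_scaled Delayed scaled force (dimensionless, >= 0).
#' @return Stimulation contribution (>= 0).
#' @export
force_feedback <- function(G, F_scaled) {
  if (any(G < 0)) stop("gain must be non-negative")
  G * F_scaled
}

#' Length feedback stimulation (stretch reflex)
#'
#' `u = max(0, G * (l - l_tar))`: the muscle-spindle stretch reflex fires
#' only when the delayed scaled length exceeds the target length.
#'
#' @param G Non-negative gain.
#' @param l Delayed scaled muscle length.
#' @param l_tar Target scaled length.
#' @return Stimulation contribution (>= 0).
#' @export
length_feedback <- function(G, l, l_tar) {
  if (any(G < 0)) stop("gain must be non-negative")
  pmax(0, G * (l - l_tar))
}

#' Muscle-driven PD stimulation
#'
#' Proportional-derivative law driving a joint toward a target angle via a
#' muscle that applies torque in the positive (`direction = "+"`) or
#' negative (`direction = "-"`) joint direction:
#' positive: `max(0, K*(theta_tar - theta) - D*theta_dot)`;
#' negative: `max(0, K*(theta - theta_tar) + D*theta_dot)`.
#'
#' @param K,D Non-negative proportional and derivative gains.
#' @param theta Delayed joint angle (rad).
#' @param theta_dot Delayed joint angular velocity (rad/s).
#' @param theta_tar Target joint angle (rad).
#' @param direction `"+"` or `"-"`.
#' @return Stimulation contribution (>= 0).
#' @export
pd_stimulation <- function(K, D, theta, theta_dot, theta_tar, direction = "+") {
  if (any(K < 0) || any(D < 0)) stop("PD gains must be non-negative")
  direction <- match.arg(direction, c("+", "-"))
  if (direction == "+") {
    pmax(0, K * (theta_tar - theta) - D * theta_dot)
  } else {
    pmax(0, K * (theta - theta_tar) + D * theta_dot)
  }
}

#' SIMBICON swing-hip target angle
#'
#' Linear foot-placement law: the stance-preparation target hip angle is
#' `theta_h0 + c_d * d + c_v * v_x`, with `d` the hip-to-ankle horizontal
#' offset and `v_x` the horizontal velocity.
#'
#' @param params Named control parameter vector (uses `theta_h0`, `c_d`,
#'   `c_v`).
#' @param d Hip-to-ankle offset (m).
#' @param v_x Horizontal velocity (m/s).
#' @return Target hip angle (rad).
#' @export
simbicon_hip_target <- function(params, d, v_x) {
  params[["theta_h0"]] + params[["c_d"]] * d + params[["c_v"]] * v_x
}

#' Update the gait phase of each leg
#'
#' Stance/swing switching is driven by ground contact; sub-phases come from
#' configurable thresholds carried in the parameter registry: within stance
#' the leg enters late stance once the hip is extended beyond `phi_ls_on`;
#' within swing the leg enters stance preparation once the foot has moved
#' ahead of the hip by more than `d_sp_on`, and late swing once the hip is
#' flexed beyond `phi_lsw_on` with the leg retracting. A fall is flagged
#' when any above-knee segment touches the ground.
#'
#' @param contact Named/ordered logical of length 2 (left, right):
#'   ground contact per leg.
#' @param hip_angle Numeric length 2: hip angles (rad).
#' @param hip_velocity Numeric length 2: hip angular velocities (rad/s).
#' @param d Numeric length 2: hip-to-ankle horizontal offsets (m).
#' @param params Named control parameter vector (thresholds).
#' @param torso_contact Logical: any above-knee segment in ground contact.
#' @return List with `phase` (character length 2) and `fell` (logical).
#' @export
update_phase <- function(contact, hip_angle = c(0, 0), hip_velocity = c(0, 0),
                         d = c(0, 0), params = parameter_vector(),
                         torso_contact = FALSE) {
  stopifnot(length(contact) == 2L)
  phase <- character(2L)
  for (i in 1:2) {
    if (contact[i]) {
      phase[i] <- if (hip_angle[i] < params[["phi_ls_on"]])
        "late_stance" else "stance"
    } else {
      if (d[i] > params[["d_sp_on"]]) {
        phase[i] <- "stance_preparation"
      } else if (hip_angle[i] > params[["phi_lsw_on"]] && hip_velocity[i] < 0) {
        phase[i] <- "late_swing"
      } else {
        phase[i] <- "swing"
      }
    }
  }
  list(phase = phase, fell = isTRUE(torso_contact))
}

## stimulation contributions of the stance-phase circuits for one leg
stance_circuit <- function(s, params, late = FALSE) {
  u <- stats::setNames(rep(0, 8), MUSCLES)
  u["SOL"] <- force_feedback(params[["G_SOL"]], s$force[["SOL"]])
  u["VAS"] <- force_feedback(params[["G_VAS"]], s$force[["VAS"]])
  u["GLU"] <- force_feedback(params[["G_GLU_st"]], s$force[["GLU"]])
  u["GAS"] <- force_feedback(params[["G_GAS"]], s$force[["GAS"]])
  ## TA stretch reflex, suppressed by SOL force (ankle overextension guard)
  u["TA"] <- length_feedback(params[["G_TA_st"]], s$length[["TA"]],
                             params[["l_TA_st_tar"]]) -
    force_feedback(params[["G_SOL_TA"]], s$force[["SOL"]])
  ## torso balance PD: lean error drives hip extensors (-) vs flexors (+)
  th <- s$theta[["t"]]; thd <- s$theta_dot[["t"]]; tt <- params[["theta_t_tar"]]
  u["HFL"] <- u["HFL"] + pd_stimulation(params[["K_HFL_st"]], params[["D_HFL_st"]],
                                        th, thd, tt, "+")
  u["RF"]  <- u["RF"] + pd_stimulation(params[["K_RF_st"]], params[["D_RF_st"]],
                                       th, thd, tt, "+")
  u["GLU"] <- u["GLU"] + pd_stimulation(params[["K_GLU_st"]], params[["D_GLU_st"]],
                                        th, thd, tt, "-")
  u["HAM"] <- u["HAM"] + pd_stimulation(params[["K_HAM_st"]], params[["D_HAM_st"]],
                                        th, thd, tt, "-")
  if (late) {
    ## pre-swing: hip-flexor onset, VAS unloading, extra push-off
    u["HFL"] <- u["HFL"] + length_feedback(params[["G_HFL_ls"]],
                                           s$length[["HFL"]],
                                           params[["l_HFL_ls_tar"]])
    u["VAS"] <- u["VAS"] - force_feedback(params[["G_VAS_ls_sup"]],
                                          s$force[["VAS"]])
    u["GAS"] <- u["GAS"] + force_feedback(params[["G_GAS_ls"]],
                                          s$force[["GAS"]])
  }
  u
}

## stimulation contributions of the swing-phase circuits for one leg
swing_circuit <- function(s, params, late = FALSE, prep = FALSE) {
  u <- stats::setNames(rep(0, 8), MUSCLES)
  if (!prep) {
    ## circuit 1: HFL stretch reflex drives the swing
    ## circuit 2: HAM stretch inhibits HFL
    u["HFL"] <- length_feedback(params[["G_HFL"]], s$length[["HFL"]],
                                params[["l_HFL_tar"]]) -
      length_feedback(params[["G_HAM_HFL"]], s$length[["HAM"]],
                      params[["l_HAM_HFL_tar"]])
    ## braking force feedback on the swing leg
    u["GLU"] <- force_feedback(params[["G_GLU_sw"]], s$force[["GLU"]])
    u["HAM"] <- force_feedback(params[["G_HAM_sw"]], s$force[["HAM"]])
    ## toe clearance
    u["TA"] <- length_feedback(params[["G_TA_sw"]], s$length[["TA"]],
                               params[["l_TA_sw_tar"]])
  }
  if (late) {
    u["GLU"] <- u["GLU"] + force_feedback(params[["G_GLU_lsw"]],
                                          s$force[["GLU"]])
    u["HAM"] <- u["HAM"] + force_feedback(params[["G_HAM_lsw"]],
                                          s$force[["HAM"]])
    u["VAS"] <- u["VAS"] + pd_stimulation(params[["K_knee_lsw"]],
                                          params[["D_knee_lsw"]],
                                          s$theta[["k"]], s$theta_dot[["k"]],
                                          params[["theta_k_sp_tar"]], "+")
  }
  if (prep) {
    ## SIMBICON hip targeting + knee fixation before heel strike
    th_tar <- simbicon_hip_target(params, s$d, s$v_x)
    u["HFL"] <- u["HFL"] + pd_stimulation(params[["K_HFL_sp"]],
                                          params[["D_HFL_sp"]],
                                          s$theta[["h"]], s$theta_dot[["h"]],
                                          th_tar, "+")
    u["GLU"] <- u["GLU"] + pd_stimulation(params[["K_GLU_sp"]],
                                          params[["D_GLU_sp"]],
                                          s$theta[["h"]], s$theta_dot[["h"]],
                                          th_tar, "-")
    u["VAS"] <- u["VAS"] + pd_stimulation(params[["K_VAS_sp"]],
                                          params[["D_VAS_sp"]],
                                          s$theta[["k"]], s$theta_dot[["k"]],
                                          params[["theta_k_sp_tar"]], "+")
    u["HAM"] <- u["HAM"] + pd_stimulation(params[["K_HAM_sp"]],
                                          params[["D_HAM_sp"]],
                                          s$theta[["k"]], s$theta_dot[["k"]],
                                          params[["theta_k_sp_tar"]], "-")
  }
  u
}

#' Compute per-muscle stimulations for one leg
#'
#' Evaluates the phase-gated reflex wiring. During stance: positive force
#' feedback on GLU/VAS/SOL/GAS, TA stretch reflex suppressed by SOL force,
#' and torso-balance PD control through the hip muscles (late stance adds
#' hip-flexor onset, VAS unloading and extra push-off). During swing: the
#' HFL stretch reflex (circuit 1) inhibited by HAM stretch (circuit 2),
#' braking force feedback on GLU/HAM, and TA toe clearance; late swing adds
#' retraction feedback; stance preparation applies SIMBICON hip targeting
#' and knee-fixation PD control. The circuits of the inactive phase
#' contribute exactly zero. Each muscle additionally receives its
#' pre-stimulation offset, and the result is clamped to `[u_min, 1]`.
#'
#' @param phase One of `"stance"`, `"late_stance"`, `"swing"`,
#'   `"late_swing"`, `"stance_preparation"`.
#' @param buffer A `delay_buffer` holding the leg's sensory history.
#' @param params Named control parameter vector (56 entries).
#' @param t Current time (s).
#' @param delays Named numeric of per-muscle sensory delays (s); defaults
#'   from [muscle_params()].
#' @param u_min Stimulation floor (default 0.01).
#' @return Named numeric vector of 8 stimulations in `[u_min, 1]`.
#' @export
compute_stimulations <- function(phase, buffer, params, t,
                                 delays = NULL, u_min = 0.01) {
  phase <- match.arg(phase, LEG_PHASES)
  params <- validate_parameters(params)
  if (is.null(delays)) {
    mp <- muscle_params()
    delays <- stats::setNames(mp$delay, mp$name)
  }
  ## delayed sample per distinct delay (zero-order hold)
  uniq <- sort(unique(delays))
  samples <- lapply(uniq, function(dly) sample_delayed(buffer, t, dly))
  names(samples) <- as.character(uniq)

  ## assemble one composite sample whose per-muscle channels are read at
  ## that muscle's own delay; joint/global channels use the hip delay
  hip_key <- as.character(delays[["HFL"]])
  comp <- samples[[hip_key]]
  for (m in MUSCLES) {
    sm <- samples[[as.character(delays[[m]])]]
    comp$force[m] <- sm$force[[m]]
    comp$length[m] <- sm$length[[m]]
  }

  u <- switch(phase,
    stance = stance_circuit(comp, params, late = FALSE),
    late_stance = stance_circuit(comp, params, late = TRUE),
    swing = swing_circuit(comp, params, late = FALSE, prep = FALSE),
    late_swing = swing_circuit(comp, params, late = TRUE, prep = FALSE),
    stance_preparation = swing_circuit(comp, params, late = FALSE, prep = TRUE)
  )
  u0 <- params[paste0("u0_", MUSCLES)]
  pmin(pmax(u + as.numeric(u0), u_min), 1)
}
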