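#' Reflex control parameter registry
#'
#' The reflex-based walking controller is tuned by a set of 56 named control
#' parameters: feedback gains, target muscle lengths (in scaled-length
#' units), proportional/derivative gains and target joint angles for the
#' muscle-driven PD laws, pre-stimulation offsets, SIMBICON foot-placement
#' coefficients, and phase-switching thresholds. The registry fixes the
#' canonical ordering used whenever a parameter set is flattened to a
#' 56-element numeric vector (dataset rows, CMA-ES search space, modulator
#' coefficient tables).
#'
#' The full parameter list of the original controller is not public; this
#' registry is an explicit reconstruction organised around the key stance
#' and swing reflex circuits (positive force feedback on the extensors,
#' length feedback on TA and the hip flexor, torso-balance PD control,
#' stance-preparation PD control with SIMBICON hip targeting). The five
#' parameters named in the circuit-substitution analysis — `G_HFL`,
#' `l_HFL_tar`, `G_HAM_HFL`, `l_HAM_HFL_tar`, `theta_t_tar` — are mandatory
#' registry members.
#'
#' @return A data.frame with one row per control parameter and columns
#'   `name`, `group` (reflex circuit block), `phase` (gait phase the entry
#'   acts in), `lower`, `upper` (feasible bounds used when clamping
#'   modulated values) and `default`.
#' @examples
#' reg <- parameter_registry()
#' nrow(reg)  # 56
#' @export
parameter_registry <- function() {
  cached <- get0("registry", envir = .pwlsgait_cache)
  if (!is.null(cached)) return(cached)
  row <- function(name, group, phase, lower, upper, default) {
    data.frame(name = name, group = group, phase = phase,
               lower = lower, upper = upper, default = default,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    ## stance: positive force feedback generating compliant leg behaviour
    row("G_SOL",        "stance_F",   "stance", 0, 5, 1.0),
    row("G_VAS",        "stance_F",   "stance", 0, 5, 1.1),
    row("G_GLU_st",     "stance_F",   "stance", 0, 5, 0.6),
    ## stance: TA length feedback with SOL force suppression
    row("G_TA_st",      "stance_TA",  "stance", 0, 5, 1.1),
    row("l_TA_st_tar",  "stance_TA",  "stance", 0, 2, 0.71),
    row("G_SOL_TA",     "stance_TA",  "stance", 0, 5, 0.3),
    ## stance: GAS push-off
    row("G_GAS",        "stance_F",   "stance", 0, 5, 1.0),
    ## stance: torso-balance PD via hip muscles
    row("K_HFL_st",     "torso_PD",   "stance", 0, 10, 1.0),
    row("D_HFL_st",     "torso_PD",   "stance", 0, 2,  0.3),
    row("K_GLU_st",     "torso_PD",   "stance", 0, 10, 1.0),
    row("D_GLU_st",     "torso_PD",   "stance", 0, 2,  0.3),
    row("K_HAM_st",     "torso_PD",   "stance", 0, 10, 0.5),
    row("D_HAM_st",     "torso_PD",   "stance", 0, 2,  0.15),
    row("theta_t_tar",  "torso_PD",   "stance", -0.5, 0.5, 0.105),
    row("K_RF_st",      "torso_PD",   "stance", 0, 10, 0.3),
    row("D_RF_st",      "torso_PD",   "stance", 0, 2,  0.1),
    ## late stance: pre-swing hip flexion onset, VAS unloading, extra push-off
    row("G_HFL_ls",     "late_stance", "late_stance", 0, 5, 0.4),
    row("l_HFL_ls_tar", "late_stance", "late_stance", 0, 2, 0.6),
    row("G_VAS_ls_sup", "late_stance", "late_stance", 0, 5, 0.5),
    row("G_GAS_ls",     "late_stance", "late_stance", 0, 5, 0.4),
    ## swing: circuit 1 (HFL stretch reflex) and circuit 2 (HAM inhibition)
    row("G_HFL",         "circuit1",  "swing", 0, 5, 0.5),
    row("l_HFL_tar",     "circuit1",  "swing", 0, 2, 0.6),
    row("G_HAM_HFL",     "circuit2",  "swing", 0, 5, 2.0),
    row("l_HAM_HFL_tar", "circuit2",  "swing", 0, 2, 0.85),
    ## swing: braking force feedback and toe clearance
    row("G_GLU_sw",     "swing_brake", "swing", 0, 5, 0.4),
    row("G_HAM_sw",     "swing_brake", "swing", 0, 5, 0.65),
    row("G_TA_sw",      "swing_TA",    "swing", 0, 5, 1.1),
    row("l_TA_sw_tar",  "swing_TA",    "swing", 0, 2, 0.71),
    ## late swing: leg retraction
    row("G_GLU_lsw",    "late_swing", "late_swing", 0, 5, 0.4),
    row("G_HAM_lsw",    "late_swing", "late_swing", 0, 5, 0.65),
    row("K_knee_lsw",   "late_swing", "late_swing", 0, 10, 0.3),
    row("D_knee_lsw",   "late_swing", "late_swing", 0, 2,  0.1),
    ## stance preparation: hip PD toward the SIMBICON target, knee fixation
    row("K_HFL_sp",     "stance_prep", "stance_preparation", 0, 10, 2.0),
    row("D_HFL_sp",     "stance_prep", "stance_preparation", 0, 2,  0.3),
    row("K_GLU_sp",     "stance_prep", "stance_preparation", 0, 10, 2.0),
    row("D_GLU_sp",     "stance_prep", "stance_preparation", 0, 2,  0.3),
    row("K_VAS_sp",     "stance_prep", "stance_preparation", 0, 10, 2.0),
    row("D_VAS_sp",     "stance_prep", "stance_preparation", 0, 2,  0.3),
    row("K_HAM_sp",     "stance_prep", "stance_preparation", 0, 10, 1.0),
    row("D_HAM_sp",     "stance_prep", "stance_preparation", 0, 2,  0.2),
    row("theta_k_sp_tar", "stance_prep", "stance_preparation", -2, 0, -0.3),
    ## SIMBICON foot placement: theta_h_tar = theta_h0 + c_d*d + c_v*v_x
    row("theta_h0",     "simbicon",   "stance_preparation", -1, 1, 0.4),
    row("c_d",          "simbicon",   "stance_preparation", 0, 2, 0.25),
    row("c_v",          "simbicon",   "stance_preparation", 0, 2, 0.25),
    ## pre-stimulation offsets (stimulation floor contribution per muscle)
    row("u0_SOL",       "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_TA",        "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_GAS",       "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_VAS",       "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_HAM",       "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_RF",        "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_GLU",       "prestim",    "all", 0.01, 0.1, 0.02),
    row("u0_HFL",       "prestim",    "all", 0.01, 0.1, 0.02),
    ## phase thresholds (configurable sub-phase triggers)
    row("phi_ls_on",    "phase",      "all", -1, 1, -0.15),
    row("phi_lsw_on",   "phase",      "all", -1, 1, 0.3),
    row("d_sp_on",      "phase",      "all", -1, 1, 0.05),
    row("knee_off_k",   "phase",      "all", 0, 5, 0.5)
  )
  stopifnot(nrow(reg) == 56L, !anyDuplicated(reg$name))
  assign("registry", reg, envir = .pwlsgait_cache)
  reg
}

.pwlsgait_cache <- new.env(parent = emptyenv())

#' Names of the 56 control parameters in registry order
#' @return Character vector of length 56.
#' @export
parameter_names <- function() parameter_registry()$name

#' Construct a named control parameter vector
#'
#' Builds a full 56-entry parameter vector in registry order, starting from
#' registry defaults and overriding any entries supplied in `...` or
#' `values`.
#'
#' @param values Named numeric vector (or list) of overrides.
#' @param ... Further named overrides, e.g. `G_HFL = 0.8`.
#' @return Named numeric vector of length 56, in registry order.
#' @examples
#' Y <- parameter_vector(G_HFL = 0.8)
#' Y[["G_HFL"]]
#' @export
parameter_vector <- function(values = NULL, ...) {
  reg <- parameter_registry()
  y <- stats::setNames(reg$default, reg$name)
  over <- c(as.list(values), list(...))
  if (length(over)) {
    over <- unlist(over)
    unknown <- setdiff(names(over), reg$name)
    if (length(unknown)) {
      stop("unknown control parameter name(s): ",
           paste(unknown, collapse = ", "))
    }
    y[names(over)] <- over
  }
  y
}

#' Validate a control parameter vector against the registry
#'
#' Checks length, names/order and (optionally) feasible bounds.
#'
#' @param y Numeric vector of length 56. If unnamed, registry order is
#'   assumed and names are attached.
#' @param check_bounds Reject values outside registry bounds?
#' @return The validated, named vector (invisibly usable).
#' @export
validate_parameters <- function(y, check_bounds = FALSE) {
  reg <- parameter_registry()
  if (length(y) != nrow(reg)) {
    stop("control parameter vector must have exactly ", nrow(reg),
         " entries, got ", length(y))
  }
  if (is.null(names(y))) {
    names(y) <- reg$name
  } else if (!identical(sort(names(y)), sort(reg$name))) {
    stop("control parameter names do not match the registry")
  }
  y <- y[reg$name]  # canonical order
  if (!all(is.finite(y))) stop("control parameters must be finite")
  if (check_bounds && any(y < reg$lower - 1e-12 | y > reg$upper + 1e-12)) {
    bad <- reg$name[y < reg$lower - 1e-12 | y > reg$upper + 1e-12]
    stop("control parameter(s) outside registry bounds: ",
         paste(bad, collapse = ", "))
  }
  y
}

#' Clamp a parameter vector to registry bounds
#' @param y Named numeric vector of length 56.
#' @param warn Emit a warning listing clamped entries?
#' @return The clamped vector.
#' @export
clamp_parameters <- function(y, warn = TRUE) {
  reg <- parameter_registry()
  y <- validate_parameters(y)
  clipped <- pmin(pmax(y, reg$lower), reg$upper)
  if (warn && any(clipped != y)) {
    warning("clamped control parameter(s) to registry bounds: ",
            paste(reg$name[clipped != y], collapse = ", "))
  }
  clipped
}

#' Built-in reflex circuit groups
#'
#' The two swing-phase length-feedback circuits identified as key to energy
#' efficiency: circuit 1 is the positive stretch reflex driving the hip
#' flexor (`G_HFL`, `l_HFL_tar`); circuit 2 is the hamstring-stretch
#' inhibition of the hip flexor (`G_HAM_HFL`, `l_HAM_HFL_tar`).
#'
#' @return Named list of character vectors of registry parameter names.
#' @export
circuit_groups <- function() {
  list(
    circuit1 = c("G_HFL", "l_HFL_tar"),
    circuit2 = c("G_HAM_HFL", "l_HAM_HFL_tar")
  )
}
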