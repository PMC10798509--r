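test_that("registry has 56 uniquely named entries with the mandatory names", {
  reg <- parameter_registry()
  expect_equal(nrow(reg), 56L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(c("G_HFL", "l_HFL_tar", "G_HAM_HFL", "l_HAM_HFL_tar",
                    "theta_t_tar") %in% reg$name))
  expect_true(all(reg$lower <= reg$default & reg$default <= reg$upper))
  cg <- circuit_groups()
  expect_equal(cg$circuit1, c("G_HFL", "l_HFL_tar"))
  expect_equal(cg$circuit2, c("G_HAM_HFL", "l_HAM_HFL_tar"))
})

test_that("parameter vectors validate, round-trip and clamp", {
  y <- parameter_vector(G_HFL = 0.8)
  expect_length(y, 56L)
  expect_equal(y[["G_HFL"]], 0.8)
  expect_error(parameter_vector(NOT_A_PARAM = 1), "unknown")
  # unnamed vectors are interpreted in registry order
  expect_equal(validate_parameters(unname(y)), y)
  expect_error(validate_parameters(y[1:10]), "56")
  y2 <- y; y2[["G_HFL"]] <- 99
  expect_warning(cl <- clamp_parameters(y2), "G_HFL")
  expect_equal(cl[["G_HFL"]],
               parameter_registry()$upper[match("G_HFL",
                                                parameter_registry()$name)])
})

test_that("delayed sampling is a zero-order hold over stored history", {
  # constant signal comes back unchanged
  buf <- make_buffer(seq(0, 0.2, by = 0.01), v_x = 1.3)
  expect_equal(sample_delayed(buf, 0.2, 0.05)$v_x, 1.3)
  # ramp: x(t) = t read with delay 0.02 at t = 0.1 gives ~0.08
  buf2 <- delay_buffer()
  for (tt in seq(0, 0.1, by = 0.01)) {
    buf2 <- buffer_push(buf2, sensory_sample(time = tt, v_x = tt))
  }
  expect_equal(sample_delayed(buf2, 0.1, 0.02)$v_x, 0.08, tolerance = 0.011)
  # before history exists the earliest sample is held
  expect_equal(sample_delayed(buf2, 0, 0.02)$v_x, 0)
  expect_error(sample_delayed(delay_buffer(), 1, 0.1), "empty")
  expect_error(sample_delayed(buf2, 1, -0.1), "non-negative")
})

test_that("feedback laws match direct substitution", {
  expect_equal(force_feedback(1.2, 0.5), 0.6)
  expect_equal(force_feedback(1.2, 0), 0)
  expect_equal(force_feedback(2.4, 0.5), 2 * force_feedback(1.2, 0.5))
  expect_error(force_feedback(-1, 0.5), "non-negative")

  expect_equal(length_feedback(1, 0.8, 1.0), 0)   # below target clips
  expect_equal(length_feedback(2, 1.1, 1.0), 0.2)
  expect_equal(length_feedback(2, 1.0, 1.0), 0)   # continuous at target

  expect_equal(pd_stimulation(2, 0.5, 0.2, 0, 0.2, "+"), 0)
  expect_equal(pd_stimulation(2, 0.5, 0.2, 0, 0.2, "-"), 0)
  expect_equal(pd_stimulation(2, 0.5, 0, 0, 0.2, "+"), 0.4)
  expect_equal(pd_stimulation(2, 0.5, 0.5, 0, 0.2, "+"), 0)  # wrong side clips
  expect_equal(pd_stimulation(2, 0.5, 0.5, 0.1, 0.2, "-"), 0.65)
})

test_that("phase update follows contact and thresholds and flags falls", {
  p <- update_phase(c(TRUE, TRUE))
  expect_equal(p$phase, c("stance", "stance"))
  expect_false(p$fell)
  p <- update_phase(c(TRUE, FALSE), hip_angle = c(0, 0), d = c(0, 0))
  expect_equal(p$phase[2], "swing")
  # foot ahead of the hip triggers stance preparation
  p <- update_phase(c(FALSE, TRUE), d = c(0.2, 0))
  expect_equal(p$phase[1], "stance_preparation")
  # hip extension beyond threshold in stance -> late stance
  p <- update_phase(c(TRUE, TRUE), hip_angle = c(-0.5, 0))
  expect_equal(p$phase, c("late_stance", "stance"))
  # flexed and retracting in swing -> late swing
  p <- update_phase(c(FALSE, FALSE), hip_angle = c(0.6, 0),
                    hip_velocity = c(-1, 0), d = c(-0.2, -0.2))
  expect_equal(p$phase, c("late_swing", "swing"))
  expect_true(update_phase(c(TRUE, TRUE), torso_contact = TRUE)$fell)
})

test_that("stimulations are clamped to [u_min, 1] for arbitrary traces", {
  set.seed(21)
  for (rep in 1:15) {
    force <- setNames(runif(8, 0, 3), c("SOL", "TA", "GAS", "VAS", "HAM",
                                        "RF", "GLU", "HFL"))
    len <- setNames(runif(8, 0.4, 1.8), names(force))
    buf <- make_buffer(seq(0, 0.1, by = 0.005), force = force, length_ = len,
                       theta = c(t = rnorm(1, 0, 0.3), h = rnorm(1, 0, 0.5),
                                 k = rnorm(1, 0, 0.5)),
                       theta_dot = c(t = rnorm(1), h = rnorm(1), k = rnorm(1)),
                       v_x = runif(1, 0.4, 2), d = rnorm(1, 0, 0.2))
    params <- parameter_vector()
    idx <- sample(56, 10)
    reg <- parameter_registry()
    params[idx] <- runif(10, reg$lower[idx], reg$upper[idx])
    phase <- sample(c("stance", "late_stance", "swing", "late_swing",
                      "stance_preparation"), 1)
    u <- compute_stimulations(phase, buf, params, t = 0.1)
    expect_length(u, 8)
    expect_true(all(u >= 0.01 - 1e-15 & u <= 1 + 1e-15))
  }
})

test_that("phase gating isolates circuits and wiring is deterministic", {
  force <- setNames(rep(0.5, 8), c("SOL", "TA", "GAS", "VAS", "HAM", "RF",
                                   "GLU", "HFL"))
  len <- setNames(rep(1.2, 8), names(force))
  buf <- make_buffer(seq(0, 0.1, by = 0.005), force = force, length_ = len)
  base <- parameter_vector()

  # stance output is unaffected by the swing-circuit gains
  p_sw <- base
  p_sw[c("G_HFL", "l_HFL_tar", "G_HAM_HFL", "G_GLU_sw", "G_HAM_sw",
         "G_TA_sw")] <- c(3, 0.1, 3, 3, 3, 3)
  u_a <- compute_stimulations("stance", buf, base, t = 0.1)
  u_b <- compute_stimulations("stance", buf, p_sw, t = 0.1)
  expect_equal(u_a, u_b)

  # swing with all swing gains zeroed sits at the stimulation floor
  p_zero <- base
  p_zero[c("G_HFL", "G_HAM_HFL", "G_GLU_sw", "G_HAM_sw", "G_TA_sw")] <- 0
  p_zero[paste0("u0_", names(force))] <- 0.01
  u_floor <- compute_stimulations("swing", buf, p_zero, t = 0.1)
  expect_equal(unname(u_floor), rep(0.01, 8))

  # identical inputs give identical outputs (pure function)
  expect_identical(compute_stimulations("swing", buf, base, t = 0.1),
                   compute_stimulations("swing", buf, base, t = 0.1))
})

test_that("hamstring stretch suppresses hip-flexor stimulation in swing", {
  force <- setNames(rep(0, 8), c("SOL", "TA", "GAS", "VAS", "HAM", "RF",
                                 "GLU", "HFL"))
  len_slack <- setNames(rep(1.0, 8), names(force))
  len_slack[["HFL"]] <- 1.4               # HFL stretched: reflex active
  len_tight <- len_slack
  len_tight[["HAM"]] <- 1.6               # HAM stretched: inhibition active
  params <- parameter_vector(G_HFL = 1.5, l_HFL_tar = 0.8,
                             G_HAM_HFL = 2.0, l_HAM_HFL_tar = 0.85)
  buf_slack <- make_buffer(seq(0, 0.1, by = 0.005), force = force,
                           length_ = len_slack)
  buf_tight <- make_buffer(seq(0, 0.1, by = 0.005), force = force,
                           length_ = len_tight)
  u_slack <- compute_stimulations("swing", buf_slack, params, t = 0.1)
  u_tight <- compute_stimulations("swing", buf_tight, params, t = 0.1)
  expect_lt(u_tight[["HFL"]], u_slack[["HFL"]])
})

test_that("shifting the sensory trace in time shifts the outputs", {
  mk <- function(shift) {
    buf <- delay_buffer(capacity = 128L)
    for (tt in seq(0, 0.3, by = 0.005)) {
      s <- 1.1 + 0.5 * sin(20 * (tt - shift))   # shifted signal
      buf <- buffer_push(buf, sensory_sample(
        time = tt,
        force = setNames(rep(abs(s) / 2, 8),
                         c("SOL", "TA", "GAS", "VAS", "HAM", "RF", "GLU",
                           "HFL")),
        length = setNames(rep(s, 8), c("SOL", "TA", "GAS", "VAS", "HAM",
                                       "RF", "GLU", "HFL"))))
    }
    buf
  }
  params <- parameter_vector()
  delta <- 0.05  # >= max sensory delay (20 ms)
  u_ref <- compute_stimulations("stance", mk(0), params, t = 0.2)
  u_shift <- compute_stimulations("stance", mk(delta), params, t = 0.2 + delta)
  expect_equal(u_shift, u_ref, tolerance = 1e-10)
})
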