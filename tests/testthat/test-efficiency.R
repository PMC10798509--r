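test_that("quadratic CoT curves are recovered from clean samples", {
  v <- seq(0.5, 1.8, length.out = 25)
  cc <- c(c0 = 0.9, c1 = -1.0, c2 = 0.45)
  curve <- fit_cot_curve(v, cc[["c0"]] + cc[["c1"]] * v + cc[["c2"]] * v^2)
  expect_equal(unname(curve$coefficients), unname(cc), tolerance = 1e-9)
  # constant samples give a flat curve
  flat <- fit_cot_curve(v, rep(0.4, 25))
  expect_equal(unname(flat$coefficients), c(0.4, 0, 0), tolerance = 1e-10)
  expect_error(fit_cot_curve(c(1, 1, 1), c(1, 2, 3)), "singular")
  # recovery from noisy surrogate samples within confidence bounds
  cfg <- surrogate_config()
  ds <- generate_dataset(2000, cfg, seed = 6)
  est <- fit_cot_curve(ds$v_x, ds$cot)$coefficients
  expect_equal(est[["c2"]], cfg$cot_curve[["c2"]], tolerance = 0.05)
  expect_equal(est[["c1"]], cfg$cot_curve[["c1"]], tolerance = 0.1)
})

test_that("integrated CoT equals the exact antiderivative", {
  expect_equal(integrate_cot(c(0.4, 0, 0), 0.7, 1.6), 0.36)
  expect_equal(integrate_cot(c(0, 1, 0), 0, 1), 0.5)
  # agrees with adaptive numerical quadrature
  co <- c(-0.1, -1.2, 0.6)   # ascending: c0, c1, c2
  direct <- integrate_cot(co, 0.7, 1.6)
  quad <- stats::integrate(function(v) co[1] + co[2] * v + co[3] * v^2,
                           0.7, 1.6, rel.tol = 1e-12)$value
  expect_equal(direct, quad, tolerance = 1e-10)
  expect_equal(direct, -0.5814, tolerance = 1e-10)
  expect_error(integrate_cot(co, 2, 1), "exceed")
})

test_that("relative integrated-CoT changes behave as percentages", {
  expect_equal(relative_icot(1.0, 1.0), 0)
  expect_equal(relative_icot(0.9, 1.0), -10)
  expect_error(relative_icot(1, 0), "non-zero")
  # antisymmetry under role swap holds only approximately
  set.seed(91)
  a <- runif(20, 0.5, 2); b <- runif(20, 0.5, 2)
  r_ab <- relative_icot(a, b); r_ba <- relative_icot(b, a)
  expect_true(all(sign(r_ab) == -sign(r_ba) | (r_ab == 0 & r_ba == 0)))
  expect_false(isTRUE(all.equal(r_ab, -r_ba)))  # not exactly antisymmetric
})

test_that("substituting an identical donor changes nothing", {
  cfg <- surrogate_config(fall_rate = 0, T = 10000L)
  ds <- generate_dataset(300, cfg, seed = 13, param_noise = 0.05)
  base <- fit_modulator(ds, degree = 2, A = 1, M = 30)
  res <- substitution_experiment(base, base, circuit_groups(),
                                 surrogate_evaluator(cfg),
                                 v_grid = seq(0.8, 1.6, by = 0.1),
                                 seeds = 1:2)
  expect_s3_class(res, "substitution_result")
  expect_true(all(res$computable))
  expect_equal(res$relative_change_pct, c(0, 0), tolerance = 1e-10)
  expect_equal(res$abs_change_pct, c(0, 0), tolerance = 1e-10)
})

test_that("substituting everything reproduces the donor's efficiency", {
  cfg <- surrogate_config(fall_rate = 0, T = 10000L)
  ds <- generate_dataset(300, cfg, seed = 14, param_noise = 0.05)
  base <- fit_modulator(ds, degree = 2, A = 1, M = 30)
  donor <- fit_modulator(ds, degree = 2, A = 1e6, M = 30)
  ev <- surrogate_evaluator(cfg)
  grid <- seq(0.8, 1.6, by = 0.1)
  res <- substitution_experiment(base, donor, list(all = parameter_names()),
                                 ev, grid, seeds = 1:2)
  rng <- attr(res, "range")
  donor_icot <- modulator_icot(donor, ev, grid, seeds = 1:2,
                               v_range = rng)$icot
  expect_equal(res$substituted_icot, donor_icot, tolerance = 1e-6)
})

test_that("the exclusion rule removes exactly the off-target velocities", {
  cfg <- surrogate_config(fall_rate = 0, T = 10000L)
  ds <- generate_dataset(300, cfg, seed = 15, param_noise = 0.05)
  mod <- fit_modulator(ds, degree = 2, A = 1, M = 30)
  # an evaluator with a deliberate speed offset at one target velocity
  ev <- function(Y, v_tar, seed) {
    tr <- surrogate_evaluate(Y, v_tar, seed, cfg)
    if (abs(v_tar - 1.2) < 1e-9) tr$v_x <- tr$v_x + 0.2
    tr
  }
  samples <- evaluate_modulator_cot(mod, ev, seq(0.9, 1.5, by = 0.1),
                                    seeds = 1)
  expect_true(all(abs(samples$v_x[!samples$excluded] -
                        samples$v_tar[!samples$excluded]) <= 0.05))
  expect_true(all(abs(samples$v_x[samples$excluded] -
                        samples$v_tar[samples$excluded]) > 0.05))
  expect_true(samples$excluded[abs(samples$v_tar - 1.2) < 1e-9])
})

test_that("per-muscle energy breakdown conserves the window total", {
  cfg <- surrogate_config(fall_rate = 0, noise_v = 0, noise_cot = 0)
  Y <- surrogate_truth(cfg, 1.0)
  tr <- surrogate_evaluate(Y, 1.0, seed = 1, cfg)   # 25 s at 1 m/s < 30 m
  expect_error(muscle_energy_breakdown(tr, distance = 30), "covers only")
  bd <- muscle_energy_breakdown(tr, distance = 20)
  cum <- cumsum(tr$distance)
  k <- which(cum >= 20)[1]
  expect_equal(sum(bd$energy), sum(tr$energy_steps[seq_len(k)]),
               tolerance = 1e-9)
  # identical traces show zero differences muscle by muscle
  bd2 <- muscle_energy_breakdown(tr, distance = 20, baseline = tr)
  expect_equal(bd2$diff, rep(0, 8))
  # a per-step energy matrix is accepted too
  mat <- matrix(rep(tr$energy_steps / 8, 8), ncol = 8,
                dimnames = list(NULL, muscle_params()$name))
  tr_mat <- trial_trace(tr$v_x, tr$theta_t, mat, tr$distance)
  bd3 <- muscle_energy_breakdown(tr_mat, distance = 20)
  expect_equal(sum(bd3$energy), sum(bd$energy), tolerance = 1e-9)
})

test_that("substitution recovers the surrogate's efficiency-critical groups", {
  # ground truth: donor tracks y*(v); base is corrupted on circuit 1 only.
  # substituting circuit 1 must recover (nearly) all of the efficiency gap,
  # substituting circuit 2 (already correct in base) must change little.
  cfg <- surrogate_config(fall_rate = 0, noise_v = 0, noise_cot = 0, T = 10000L)
  ds <- generate_dataset(400, cfg, seed = 16, param_noise = 0,
                         cot_noise = 0)
  donor <- fit_modulator(ds, degree = 2, A = 1, M = 30)
  base <- donor
  base$coefficients["G_HFL", 1] <- base$coefficients["G_HFL", 1] + 0.8
  base$coefficients["l_HFL_tar", 1] <- base$coefficients["l_HFL_tar", 1] + 0.4
  res <- substitution_experiment(base, donor, circuit_groups(),
                                 surrogate_evaluator(cfg),
                                 v_grid = seq(0.8, 1.6, by = 0.1), seeds = 1)
  r1 <- res$abs_change_pct[res$group == "circuit1"]
  r2 <- res$abs_change_pct[res$group == "circuit2"]
  expect_gt(r1, 10 * max(r2, 1e-6))
  expect_lt(res$relative_change_pct[res$group == "circuit1"], 0)
})
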