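test_that("noise-free polynomial parameter curves are recovered exactly", {
  set.seed(61)
  v <- sort(runif(60, 0.5, 1.8))
  degree <- 6
  truth <- matrix(rnorm(56 * (degree + 1)), 56,
                  dimnames = list(parameter_names(), NULL))
  truth <- truth / matrix(4^(0:degree), 56, degree + 1, byrow = TRUE)
  params <- sapply(parameter_names(), function(nm) {
    sapply(v, function(vv) sum(truth[nm, ] * vv^(0:degree)))
  })
  ds <- gait_dataset(v, runif(60, 0.3, 0.6), params)
  for (A in c(1, 1e6)) {
    mod <- fit_modulator(ds, degree = degree, A = A, M = 10)
    expect_lt(max(abs(coef(mod) - truth)), 1e-6)
    # modulate() reproduces the generating curves
    for (vv in c(0.7, 1.2, 1.6)) {
      y_true <- sapply(parameter_names(), function(nm)
        sum(truth[nm, ] * vv^(0:degree)))
      y_mod <- suppressWarnings(modulate(mod, vv, clamp_bounds = FALSE))
      expect_lt(max(abs(y_mod - y_true)), 1e-6)
    }
  }
})

test_that("the uniform-weight modulator equals per-parameter OLS", {
  ds <- generate_dataset(150, seed = 8)
  mod <- fit_modulator(ds, degree = 3, A = 1, M = 20)
  for (nm in c("G_HFL", "theta_t_tar", "u0_SOL")) {
    ols <- lm(ds[[nm]] ~ poly(ds$v_x, 3, raw = TRUE))
    expect_equal(unname(coef(mod)[nm, ]), unname(coef(ols)),
                 tolerance = 1e-7)
  }
})

test_that("modulate is deterministic, clamps and respects the range", {
  coefs <- matrix(0, 56, 3, dimnames = list(parameter_names(), NULL))
  coefs[, 1] <- parameter_registry()$default
  mod <- modulator(coefs, velocity_range = c(0.7, 1.6))
  # constant polynomials give the same vector at every velocity
  expect_identical(modulate(mod, 0.8), modulate(mod, 1.5))
  expect_identical(modulate(mod, 1.2), modulate(mod, 1.2))
  # out-of-range targets clamp with a warning, or error when disabled
  expect_warning(y <- modulate(mod, 2.5), "clamped")
  expect_equal(y, modulate(mod, 1.6))
  expect_error(modulate(mod, 2.5, clamp_range = FALSE), "outside")
  # values beyond registry bounds are clamped to bounds
  coefs2 <- coefs; coefs2["G_HFL", 1] <- 99
  mod2 <- modulator(coefs2, c(0.7, 1.6))
  expect_warning(y2 <- modulate(mod2, 1.0), "G_HFL")
  expect_equal(y2[["G_HFL"]], 5)
})

test_that("modulated curves are continuous in the target velocity", {
  ds <- generate_dataset(200, seed = 12)
  mod <- fit_modulator(ds, degree = 4, A = 100, M = 20)
  vg <- seq(mod$velocity_range[1], mod$velocity_range[2], length.out = 400)
  pred <- predict(mod, vg)
  h <- diff(vg)[1]
  # finite differences bounded by a (generous) polynomial derivative bound
  max_step <- max(abs(apply(pred, 2, diff)))
  deriv_bound <- max(abs(pred)) * 4 / h / length(vg) * 50
  expect_lt(max_step, max(1, deriv_bound))
})

test_that("substitution replaces exactly the named entries", {
  ds <- generate_dataset(150, seed = 3)
  base <- fit_modulator(ds, degree = 3, A = 1, M = 20)
  donor <- fit_modulator(ds, degree = 3, A = 1e4, M = 20)
  expect_equal(substitute_functions(base, donor, character())$coefficients,
               base$coefficients)
  expect_equal(substitute_functions(base, donor,
                                    parameter_names())$coefficients,
               donor$coefficients)
  both <- unlist(circuit_groups())
  hyb <- substitute_functions(base, donor, both)
  differs <- rowSums(hyb$coefficients != base$coefficients) > 0
  expect_equal(sort(names(which(differs))),
               sort(c("G_HFL", "l_HFL_tar", "G_HAM_HFL", "l_HAM_HFL_tar")))
  expect_error(substitute_functions(base, donor, "nope"), "unknown")
})

test_that("substitution is idempotent and disjoint substitutions commute", {
  ds <- generate_dataset(150, seed = 3)
  base <- fit_modulator(ds, degree = 3, A = 1, M = 20)
  donor <- fit_modulator(ds, degree = 3, A = 1e4, M = 20)
  g1 <- circuit_groups()$circuit1
  g2 <- circuit_groups()$circuit2
  once <- substitute_functions(base, donor, g1)
  twice <- substitute_functions(once, donor, g1)
  expect_equal(twice$coefficients, once$coefficients)
  ab <- substitute_functions(substitute_functions(base, donor, g1), donor, g2)
  ba <- substitute_functions(substitute_functions(base, donor, g2), donor, g1)
  expect_equal(ab$coefficients, ba$coefficients)
})

test_that("modulators round-trip through JSON", {
  ds <- generate_dataset(150, seed = 5)
  mod <- fit_modulator(ds, degree = 4, A = 100, M = 20)
  path <- tempfile(fileext = ".json")
  write_modulator(mod, path)
  back <- read_modulator(path)
  expect_equal(back$coefficients, mod$coefficients, tolerance = 1e-12)
  expect_equal(back$degree, mod$degree)
  expect_equal(back$velocity_range, mod$velocity_range, tolerance = 1e-12)
  expect_equal(back$A, mod$A)
  unlink(path)
})

test_that("gait datasets sort by velocity and round-trip through CSV", {
  v <- c(1.5, 0.8, 1.2)
  params <- matrix(rep(parameter_vector(), each = 3), 3,
                   dimnames = list(NULL, parameter_names()))
  ds <- gait_dataset(v, c(0.5, 0.4, 0.45), params)
  expect_equal(ds$v_x, sort(v))
  path <- tempfile(fileext = ".csv")
  write_gait_dataset(ds, path)
  header <- readLines(path, n = 1)
  expect_match(header, '^"v_x","cot","G_SOL"')
  back <- read_gait_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)
  unlink(path)
  # merged datasets are globally sorted regardless of input order
  ds2 <- gait_dataset(c(0.5, 2.0), c(0.6, 0.7),
                      matrix(rep(parameter_vector(), each = 2), 2))
  merged <- merge_gait_datasets(ds, ds2)
  expect_equal(merged$v_x, sort(c(v, 0.5, 2.0)))
})
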