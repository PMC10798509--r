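test_that("moving-average CoT uses a shrinking window at the edges", {
  expect_equal(moving_average_cot(rep(0.4, 500), 250, M = 125), 0.4)
  expect_equal(moving_average_cot(c(1, 2, 3, 4, 5), 3, M = 1), 3)
  expect_equal(moving_average_cot(c(1, 2, 3, 4, 5), 1, M = 1), 1.5)
  expect_equal(moving_average_cot(c(1, 2, 3, 4, 5), 5, M = 1), 4.5)
  expect_error(moving_average_cot(numeric(0), 1), "empty")
  expect_error(moving_average_cot(1:5, 6), "range")
})

test_that("performance weights follow the relative-CoT power law", {
  expect_equal(performance_weights(0.5, 0.5, A = 10), 1)
  expect_equal(performance_weights(0.9, 0.5, A = 1), 1)
  expect_equal(performance_weights(0.45, 0.5, A = 100), 100^0.1,
               tolerance = 1e-12)
  # beta > 1 exactly when the record beats the local mean
  expect_gt(performance_weights(0.4, 0.5, A = 10), 1)
  expect_lt(performance_weights(0.6, 0.5, A = 10), 1)
  expect_error(performance_weights(0.5, 0, A = 10), "positive")
  expect_error(performance_weights(0.5, 0.5, A = 0.5), ">= 1")
})

test_that("n = m + 1 distinct points interpolate exactly for any weights", {
  for (beta in list(NULL, c(1, 10, 0.1), c(5, 5, 5))) {
    fit <- pwls(c(0, 1, 2), c(1, 2, 5), beta = beta, degree = 2)
    expect_equal(unname(coef(fit)), c(1, 0, 1), tolerance = 1e-10)
  }
})

test_that("uniform weights reduce PWLS to ordinary least squares", {
  set.seed(31)
  v <- sort(runif(40, 0.5, 2)); y <- sin(3 * v) + rnorm(40, 0, 0.1)
  fit_pwls <- pwls(v, y, degree = 4)
  fit_ols <- lm(y ~ poly(v, 4, raw = TRUE))
  expect_equal(unname(coef(fit_pwls)), unname(coef(fit_ols)),
               tolerance = 1e-8)
  # scaling all weights by a constant leaves the fit unchanged
  fit_c <- pwls(v, y, beta = rep(3.7, 40), degree = 4)
  expect_equal(coef(fit_c), coef(fit_pwls), tolerance = 1e-10)
  set.seed(32)
  b <- runif(40, 0.5, 4)
  f1 <- pwls(v, y, beta = b, degree = 4)
  f2 <- pwls(v, y, beta = 100 * b, degree = 4)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("the QR solve agrees with brute-force minimisation and explicit
           normal equations", {
  set.seed(41)
  for (k in 1:25) {
    degree <- sample(1:6, 1)
    n <- sample((degree + 2):60, 1)
    inst <- random_pwls_instance(n, degree)
    fit <- pwls(inst$v, inst$y, beta = inst$beta, degree = degree)
    # independent brute-force minimisation of the weighted error
    fitted_oracle <- oracle_pwls_fitted(inst$v, inst$y, inst$beta, degree)
    expect_lt(max(abs(fitted(fit) - fitted_oracle)), 1e-6)
    # optimality: no worse than the OLS coefficients under these weights
    e_pwls <- pwls_error(inst$v, inst$y, inst$beta, unname(coef(fit)))
    ols <- pwls(inst$v, inst$y, degree = degree)
    e_ols <- pwls_error(inst$v, inst$y, inst$beta, unname(coef(ols)))
    expect_lte(e_pwls, e_ols * (1 + 1e-10))
    # explicit normal-equations solution (well-conditioned degrees)
    if (degree <= 4) {
      fitted_ne <- oracle_pwls_normal_eq(inst$v, inst$y, inst$beta, degree)
      expect_lt(max(abs(fitted(fit) - fitted_ne)), 1e-7)
    }
  }
})

test_that("weights derived from CoT bias the fit toward efficient records", {
  ds <- make_twolevel_dataset()
  eff <- ds$cot == 0.5
  res_eff <- sapply(c(1, 10, 1e2, 1e4, 1e6), function(A) {
    f <- pwls(ds$v_x, ds$G_HFL, cot = ds$cot, A = A, M = 125)
    mean((fitted(f)[eff] - ds$G_HFL[eff])^2)
  })
  expect_true(all(diff(res_eff) <= 1e-12))
  res_ineff <- sapply(c(1, 10, 1e2, 1e4, 1e6), function(A) {
    f <- pwls(ds$v_x, ds$G_HFL, cot = ds$cot, A = A, M = 125)
    mean((fitted(f)[!eff] - ds$G_HFL[!eff])^2)
  })
  expect_true(all(diff(res_ineff) >= -1e-12))
})

test_that("extreme bias strengths stay finite via log-space weights", {
  ds <- make_twolevel_dataset()
  fit <- pwls(ds$v_x, ds$G_HFL, cot = ds$cot, A = 1e200, M = 125)
  expect_true(all(is.finite(coef(fit))))
  expect_true(all(is.finite(fit$weights)))
  expect_equal(max(fit$weights), 1)   # renormalised to the best record
})

test_that("rank-deficient designs raise a singular-fit error", {
  expect_error(pwls(rep(c(1, 2), 10), rnorm(20), degree = 3), "singular")
  expect_error(pwls(1:3, 1:3, degree = 5), "at least")
})

test_that("polynomial prediction matches the naive power sum", {
  expect_equal(predict_polynomial(c(1, 0, 1), 2), 5)
  expect_equal(predict_polynomial(c(7), c(-3, 0, 11)), c(7, 7, 7))
  set.seed(51)
  omega <- rnorm(7)
  v <- runif(20, -2, 2)
  naive <- sapply(v, function(vv) sum(omega * vv^(0:6)))
  expect_equal(predict_polynomial(omega, v), naive, tolerance = 1e-12)
  # predict() on the fit agrees with the raw-coefficient evaluation
  fit <- pwls(sort(runif(30, 0.5, 2)), rnorm(30), degree = 3)
  vg <- seq(0.6, 1.9, length.out = 11)
  expect_equal(predict(fit, vg), predict_polynomial(unname(coef(fit)), vg),
               tolerance = 1e-8)
})
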