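# Independent oracles and small fixture builders used across tests.

# Brute-force numerical minimisation of the performance-weighted squared
# error E = || beta (*) (y - P(v)) ||^2 over polynomials of the given
# degree, via BFGS with an analytic gradient on an inline centred/scaled
# basis. Returns the fitted values at the data points. Independent of the
# package's QR solve path.
oracle_pwls_fitted <- function(v, y, beta, degree) {
  z <- (v - mean(v)) / stats::sd(v)
  Z <- outer(z, 0:degree, `^`)
  w <- beta^2
  obj <- function(cc) sum(w * (y - drop(Z %*% cc))^2)
  grad <- function(cc) -2 * drop(crossprod(Z, w * (y - drop(Z %*% cc))))
  fit <- stats::optim(rep(0, degree + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  # polish once more from the found point
  fit <- stats::optim(fit$par, obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  drop(Z %*% fit$par)
}

# Explicit normal-equations solution in the raw power basis: the weighted
# Vandermonde system solved exactly as written (Hadamard-expanded weight
# matrix), usable at moderate degree where it is well-conditioned.
oracle_pwls_normal_eq <- function(v, y, beta, degree) {
  V <- outer(v, 0:degree, `^`)
  BV <- beta * V           # B (*) V: each row of V scaled by beta_i
  omega <- solve(crossprod(BV), crossprod(BV, beta * y))
  drop(V %*% omega)
}

# the weighted squared error the PWLS fit minimises
pwls_error <- function(v, y, beta, omega) {
  V <- outer(v, 0:(length(omega) - 1), `^`)
  sum((beta * (y - drop(V %*% omega)))^2)
}

# random PWLS problem instance with heterogeneous weights
random_pwls_instance <- function(n, degree) {
  v <- sort(stats::runif(n, 0.5, 2.0))
  y <- stats::rnorm(1) + stats::rnorm(1) * v + stats::rnorm(1) * v^2 +
    0.3 * sin(3 * v) + stats::rnorm(n, 0, 0.1)
  beta <- stats::runif(n, 0.2, 5)
  list(v = v, y = y, beta = beta, degree = degree)
}

# evaluator stubs for collection tests
stub_evaluator_survive <- function(Y, v_tar, seed) {
  trial_trace(v_x = rep(v_tar, 5000), theta_t = rep(0, 5000),
              energy = rep(0.03, 5000), distance = rep(v_tar * 0.005, 5000),
              fell = FALSE)
}

stub_evaluator_fall <- function(Y, v_tar, seed) {
  trial_trace(v_x = rep(v_tar, 100), theta_t = rep(0, 100),
              energy = rep(0.03, 100), distance = rep(v_tar * 0.005, 100),
              fell = TRUE)
}

# small uniform sensory history for reflex tests
make_buffer <- function(times, force = NULL, length_ = NULL,
                        theta = c(t = 0, h = 0, k = 0),
                        theta_dot = c(t = 0, h = 0, k = 0),
                        v_x = 1, d = 0) {
  buf <- delay_buffer()
  for (tt in times) {
    buf <- buffer_push(buf, sensory_sample(
      time = tt, force = force, length = length_,
      theta = theta, theta_dot = theta_dot, v_x = v_x, d = d))
  }
  buf
}
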