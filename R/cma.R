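## Covariance matrix adaptation evolution strategy (CMA-ES), standard
## rank-mu update rules. Only lambda, mu, sigma0 and the generation budget
## are problem-specific here; all strategy constants take their standard
## defaults.

#' Initialise a CMA-ES state
#'
#' @param mean Initial mean vector of the search distribution.
#' @param sigma0 Initial step size.
#' @param lambda Population size per generation (default 20).
#' @param mu Number of selected parents (default 7).
#' @return List of class `cma_state`: search distribution (`mean`, `sigma`,
#'   `C`), evolution paths (`p_sigma`, `p_C`), recombination weights and
#'   strategy constants, generation counter.
#' @export
cma_init <- function(mean, sigma0 = 0.1, lambda = 20L, mu = 7L) {
  n <- length(mean)
  stopifnot(n >= 1L, sigma0 > 0, lambda >= 2L, mu >= 1L, mu <= lambda)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cs <- (mueff + 2) / (n + mueff + 5)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  structure(list(n = n, lambda = as.integer(lambda), mu = as.integer(mu),
                 weights = w, mueff = mueff, cs = cs, ds = ds, cc = cc,
                 c1 = c1, cmu = cmu, chiN = chiN,
                 mean = as.numeric(mean), sigma = sigma0, sigma0 = sigma0,
                 C = diag(n), p_sigma = numeric(n), p_C = numeric(n),
                 generation = 0L, candidates = NULL),
            class = "cma_state")
}

#' Sample one generation of candidates
#'
#' Draws `lambda` candidates from `N(mean, sigma^2 C)` using the current R
#' random stream and caches them in the state for the subsequent
#' [cma_step()].
#'
#' @param state A `cma_state`.
#' @return The state with a `candidates` matrix (`lambda x n`) attached.
#' @export
cma_ask <- function(state) {
  stopifnot(inherits(state, "cma_state"))
  eg <- eigen(state$C, symmetric = TRUE)
  D <- sqrt(pmax(eg$values, 1e-20))
  Z <- matrix(stats::rnorm(state$lambda * state$n), state$lambda, state$n)
  Y <- Z %*% diag(D, state$n) %*% t(eg$vectors)
  state$candidates <- sweep(state$sigma * Y, 2L, state$mean, `+`)
  state$eigen_cache <- list(B = eg$vectors, D = D)
  state
}

#' One CMA-ES update from evaluated candidates
#'
#' Standard rank-mu update of mean, step size, covariance and both
#' evolution paths from the objective values of the current candidates
#' (lower is better). Non-finite objectives are assigned the worst rank.
#'
#' @param state A `cma_state` holding candidates from [cma_ask()].
#' @param values Numeric vector of `lambda` objective values.
#' @return The updated `cma_state` (generation counter advanced, candidate
#'   cache cleared).
#' @export
cma_step <- function(state, values) {
  stopifnot(inherits(state, "cma_state"), !is.null(state$candidates),
            length(values) == state$lambda)
  values[!is.finite(values)] <- Inf
  ord <- order(values)
  X <- state$candidates[ord[seq_len(state$mu)], , drop = FALSE]

  old_mean <- state$mean
  Yk <- sweep(X, 2L, old_mean, `-`) / state$sigma
  y_w <- drop(crossprod(Yk, state$weights))
  state$mean <- old_mean + state$sigma * y_w

  B <- state$eigen_cache$B; D <- state$eigen_cache$D
  C_inv_sqrt_yw <- B %*% ((t(B) %*% y_w) / D)
  state$p_sigma <- (1 - state$cs) * state$p_sigma +
    sqrt(state$cs * (2 - state$cs) * state$mueff) * drop(C_inv_sqrt_yw)

  g1 <- state$generation + 1L
  hsig <- sqrt(sum(state$p_sigma^2)) /
    sqrt(1 - (1 - state$cs)^(2 * g1)) / state$chiN < 1.4 + 2 / (state$n + 1)
  state$p_C <- (1 - state$cc) * state$p_C +
    (if (hsig) sqrt(state$cc * (2 - state$cc) * state$mueff) else 0) * y_w

  rank_mu <- crossprod(Yk * sqrt(state$weights))
  state$C <- (1 - state$c1 - state$cmu) * state$C +
    state$c1 * (tcrossprod(state$p_C) +
                  (if (hsig) 0 else state$cc * (2 - state$cc)) * state$C) +
    state$cmu * rank_mu
  state$C <- (state$C + t(state$C)) / 2

  state$sigma <- state$sigma *
    exp(state$cs / state$ds * (sqrt(sum(state$p_sigma^2)) / state$chiN - 1))
  state$generation <- g1
  state$candidates <- NULL
  state$eigen_cache <- NULL
  state
}

#' Reset the strategy for a new target velocity
#'
#' When the collection schedule moves to the next target velocity the step
#' size is reset to its initial value and both evolution paths are emptied,
#' while the mean and covariance are carried over (so search continues from
#' the previously optimized region).
#'
#' @param state A `cma_state`.
#' @param sigma0 Step size after the reset (default: the state's own
#'   initial value).
#' @return The reset `cma_state`.
#' @export
reset_for_new_velocity <- function(state, sigma0 = state$sigma0) {
  stopifnot(inherits(state, "cma_state"))
  state$sigma <- sigma0
  state$p_sigma <- numeric(state$n)
  state$p_C <- numeric(state$n)
  state$candidates <- NULL
  state$eigen_cache <- NULL
  state
}

#' Minimise a function with CMA-ES
#'
#' Convenience driver around [cma_ask()]/[cma_step()].
#'
#' @param fn Objective function of a numeric vector (lower is better).
#' @param mean Initial mean.
#' @param sigma0 Initial step size.
#' @param lambda,mu Population and parent count.
#' @param generations Number of generations.
#' @return List with `par`, `value`, `state`, `best_by_generation`.
#' @export
cma_optimize <- function(fn, mean, sigma0 = 0.3, lambda = 20L, mu = 7L,
                         generations = 100L) {
  state <- cma_init(mean, sigma0, lambda, mu)
  best_par <- mean
  best_val <- Inf
  hist <- numeric(generations)
  for (g in seq_len(generations)) {
    state <- cma_ask(state)
    vals <- apply(state$candidates, 1L, fn)
    k <- which.min(vals)
    if (is.finite(vals[k]) && vals[k] < best_val) {
      best_val <- vals[k]
      best_par <- state$candidates[k, ]
    }
    hist[g] <- best_val
    state <- cma_step(state, vals)
  }
  list(par = best_par, value = best_val, state = state,
       best_by_generation = hist)
}
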