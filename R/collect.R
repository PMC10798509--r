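## Two-thread incremental-velocity dataset collection: CMA-ES optimisation
## of the 56 control parameters at each target velocity, admitting every
## trial that survives to the timestep limit.

#' Dataset collection schedule
#'
#' The two-thread incremental target-velocity schedule: one thread starts
#' at 1.3 m/s (the human self-selected speed) and steps up to 2.0 m/s; the
#' other starts at 1.2 m/s and steps down to 0.4 m/s, both in 0.1 m/s
#' increments, with `G` CMA-ES generations of `lambda` trials at each
#' target velocity. Velocity grids are materialised with integer step
#' counts so no floating-point drift accumulates.
#'
#' @param up_start,up_end Thread A start and end velocities (m/s).
#' @param down_start,down_end Thread B start and end velocities (m/s).
#' @param step Velocity increment (m/s, positive).
#' @param G Generations per target velocity (default 300).
#' @param lambda Population size (default 20).
#' @param mu Parent count (default 7).
#' @param sigma0 Initial CMA-ES step size (default 0.1).
#' @return List of class `collection_schedule`.
#' @export
collection_schedule <- function(up_start = 1.3, up_end = 2.0,
                                down_start = 1.2, down_end = 0.4,
                                step = 0.1, G = 300L, lambda = 20L,
                                mu = 7L, sigma0 = 0.1) {
  stopifnot(step > 0, up_end >= up_start, down_end <= down_start,
            G >= 1L, lambda >= 2L, mu >= 1L, mu <= lambda, sigma0 > 0)
  structure(list(up_start = up_start, up_end = up_end,
                 down_start = down_start, down_end = down_end,
                 step = step, G = as.integer(G), lambda = as.integer(lambda),
                 mu = as.integer(mu), sigma0 = sigma0),
            class = "collection_schedule")
}

## integer-count velocity grid: start + k*step without fp drift
velocity_grid <- function(start, end, step) {
  k <- round(abs(end - start) / step)
  s <- sign(end - start)
  if (k == 0) return(start)
  round((start * 1e6 + s * (0:k) * step * 1e6)) / 1e6
}

#' Target velocities of both collection threads
#' @param schedule A `collection_schedule`.
#' @return List with numeric vectors `up` and `down`.
#' @export
schedule_velocities <- function(schedule) {
  list(up = velocity_grid(schedule$up_start, schedule$up_end, schedule$step),
       down = velocity_grid(schedule$down_start, schedule$down_end,
                            schedule$step))
}

#' Total number of evaluation trials in a schedule
#'
#' `(#velocities thread A + #velocities thread B) * G * lambda`. The
#' default schedule gives 17 target velocities and 102,000 trials.
#'
#' @param schedule A `collection_schedule`.
#' @return Integer trial count.
#' @examples
#' schedule_trial_count(collection_schedule())  # 102000
#' @export
schedule_trial_count <- function(schedule) {
  vs <- schedule_velocities(schedule)
  (length(vs$up) + length(vs$down)) * schedule$G * schedule$lambda
}

#' Collect a gait dataset over the velocity schedule
#'
#' Runs both collection threads sequentially from identical initial control
#' parameters. At each target velocity the CMA-ES step size and evolution
#' paths are reset (mean and covariance carried over) and `G` generations
#' of `lambda` candidates are evaluated with the supplied gait evaluator.
#' Every candidate whose trial survives to the timestep limit is admitted
#' to the dataset as a `(v_x, Y, CoT)` record; candidates that fall (or
#' whose evaluation fails) are scored by the objective only. The merged
#' dataset is sorted ascending by achieved velocity, making the result
#' independent of thread execution order.
#'
#' @param schedule A `collection_schedule`.
#' @param evaluator Function `(Y, v_tar, seed) -> trial_trace` —
#'   deterministic for a given seed. See [surrogate_evaluator()].
#' @param weights A `cost_weights` used for the objective and CoT.
#' @param seed Integer seed controlling both CMA-ES sampling and the
#'   per-trial evaluator seeds.
#' @param init_params Initial mean of the search distribution (56-entry
#'   named vector); shared by both threads.
#' @return List of class `collection_result`: `dataset` (a
#'   `gait_dataset`), `log` (per-generation data.frame: thread, target
#'   velocity, generation, best objective, admitted count), `n_trials`.
#' @export
velocity_sweep <- function(schedule, evaluator, weights = cost_weights(),
                           seed = 1L, init_params = parameter_vector()) {
  stopifnot(inherits(schedule, "collection_schedule"), is.function(evaluator))
  init_params <- validate_parameters(init_params)
  vs <- schedule_velocities(schedule)
  threads <- list(up = vs$up, down = vs$down)

  rec_v <- numeric(0); rec_cot <- numeric(0); rec_Y <- list()
  log_rows <- vector("list", 0L)
  trial_counter <- 0L

  set.seed(seed)
  for (tname in names(threads)) {
    state <- cma_init(init_params, schedule$sigma0, schedule$lambda,
                      schedule$mu)
    for (v_tar in threads[[tname]]) {
      state <- reset_for_new_velocity(state, schedule$sigma0)
      for (g in seq_len(schedule$G)) {
        state <- cma_ask(state)
        vals <- numeric(schedule$lambda)
        admitted_g <- 0L
        for (k in seq_len(schedule$lambda)) {
          trial_counter <- trial_counter + 1L
          eval_seed <- (seed %% 100000L) * 20000L + trial_counter
          Y <- stats::setNames(state$candidates[k, ], parameter_names())
          trace <- tryCatch(evaluator(Y, v_tar, eval_seed),
                            error = function(e) NULL)
          if (is.null(trace)) {
            vals[k] <- Inf
            next
          }
          vals[k] <- trial_cost(trace, v_tar, weights)
          if (!trace$fell && trace$T_prime >= weights$T) {
            admitted_g <- admitted_g + 1L
            rec_v <- c(rec_v, mean(trace$v_x))
            rec_cot <- c(rec_cot, trace_cot(trace, weights))
            rec_Y <- c(rec_Y, list(Y))
          }
        }
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          thread = tname, v_tar = v_tar, generation = g,
          best_f = min(vals), admitted = admitted_g)
        state <- cma_step(state, vals)
      }
    }
  }

  dataset <- if (length(rec_v)) {
    gait_dataset(rec_v, rec_cot, do.call(rbind, rec_Y))
  } else {
    gait_dataset(numeric(0), numeric(0), NULL)
  }
  structure(list(dataset = dataset,
                 log = do.call(rbind, log_rows),
                 n_trials = trial_counter),
            class = "collection_result")
}

#' @export
print.collection_result <- function(x, ...) {
  cat("Collection result: ", x$n_trials, " trials, ",
      nrow(x$dataset), " admitted records (",
      format(100 * nrow(x$dataset) / max(1L, x$n_trials), digits = 3),
      "%)\n", sep = "")
  invisible(x)
}
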