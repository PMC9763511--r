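#' Generalized simulated annealing (maximization)
#'
#' Native annealing maximizer with a geometric temperature schedule, Gaussian
#' proposal steps whose scale shrinks with temperature, Metropolis
#' acceptance, box constraints by clamping, and a keep-best guarantee: the
#' returned value is at least the objective at the starting point. Fully
#' deterministic under a fixed seed.
#'
#' @param fn Objective function to maximize (higher is better).
#' @param x0 Numeric starting point.
#' @param lower,upper Numeric bounds (recycled to `length(x0)`).
#' @param n_eval Total objective evaluations (budget).
#' @param seed Integer seed for the proposal stream.
#' @param t0,tmin Initial and final temperature of the geometric schedule,
#'   on the scale of objective differences.
#' @return List with `par` (best point), `value` (best objective),
#'   `start_value`, `n_eval`.
#' @export
anneal_maximize <- function(fn, x0, lower, upper, n_eval = 2000, seed = 1L,
                            t0 = 0.3, tmin = 1e-4) {
  d <- length(x0)
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  span <- upper - lower
  withr::with_seed(as.integer(seed), {
    cur <- clamp(x0)
    f_cur <- fn(cur)
    best <- cur
    f_best <- f_start <- f_cur
    evals <- 1L
    while (evals < n_eval) {
      temp <- t0 * (tmin / t0)^(evals / n_eval)
      step <- 0.15 * span * max(sqrt(temp / t0), 0.02)
      prop <- clamp(cur + stats::rnorm(d, 0, step))
      f_prop <- fn(prop)
      evals <- evals + 1L
      if (f_prop >= f_cur ||
          stats::runif(1) < exp((f_prop - f_cur) / temp)) {
        cur <- prop
        f_cur <- f_prop
      }
      if (f_prop > f_best) {
        best <- prop
        f_best <- f_prop
      }
    }
    list(par = best, value = f_best, start_value = f_start, n_eval = evals)
  })
}

#' Default weight bounds
#'
#' Symmetric boxes: the intercept `w0` absorbs the prior log odds and may be
#' large; the exponents `w1..w4` rescale log likelihood ratios.
#'
#' @return List with elements `w0` and `w` (each `c(lower, upper)`).
#' @export
default_weight_bounds <- function() list(w0 = c(-50, 50), w = c(-10, 10))
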