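#' Combine per-data-type log likelihood ratios with five weights
#'
#' The combined score is, in log space,
#' `w0 + w1*loglr_sex + w2*loglr_growth + w3*loglr_dev + w4*loglr_hpo`.
#' `w0` is the additive intercept playing the role of the prior: with
#' `w0 = log(prior odds)` and unit weights the score reduces exactly to the
#' naive Bayes log posterior odds. A score greater than 0 is a classification
#' to the gene.
#'
#' @param w Numeric weight vector of length 5, in order `w0..w4` (names
#'   ignored).
#' @param lr Data frame (or matrix) with columns `loglr_sex`, `loglr_growth`,
#'   `loglr_dev`, `loglr_hpo`.
#' @return Numeric vector of combined scores, one per row of `lr`.
#' @export
combine_scores <- function(w, lr) {
  stopifnot(length(w) == 5L)
  w <- as.numeric(w)
  m <- as.matrix(as.data.frame(lr)[, c("loglr_sex", "loglr_growth",
                                       "loglr_dev", "loglr_hpo")])
  as.numeric(w[1L] + m %*% w[2:5])
}

#' Classification calls from combined scores
#' @param scores Numeric combined scores.
#' @return Logical vector, `TRUE` where score > 0.
#' @export
score_calls <- function(scores) scores > 0

# F1 used as the annealing objective: defined as 0 whenever there are no
# positive calls or no true positives (precision or recall would be 0 or
# undefined).
f1_objective <- function(calls, labels) {
  tp <- sum(calls & labels)
  fp <- sum(calls & !labels)
  fn <- sum(!calls & labels)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Optimize combination weights by simulated annealing on F1
#'
#' Maximizes the F1 score of the calls `combine_scores(w, lr) > 0` over the
#' cohort, for one gene. The canonical start is the naive Bayes solution
#' (`w0 = log prior odds` from the label frequency, unit weights on the
#' active data types); additional starting points (e.g. solutions of
#' single-data-type optimizations) can be supplied and the evaluation budget
#' is split across starts, keeping the best solution overall. Weights outside
#' `active` are fixed at 0, which is how single-data-type and HPO-only models
#' are optimized. An F1 producing no positive calls counts as 0.
#'
#' @param lr Likelihood table rows for one gene (columns `loglr_*`).
#' @param labels Logical vector: diagnosed with the gene.
#' @param active Character subset of `c("sex","growth","dev","hpo")`: data
#'   types whose weight is free; the rest are fixed at 0.
#' @param seed Integer seed (deterministic output).
#' @param n_eval Total annealing budget across all starts.
#' @param bounds As [default_weight_bounds()].
#' @param extra_starts Optional list of full weight vectors (length 5) used
#'   as additional annealing starts.
#' @return List with `weights` (named numeric `w0..w4`), `f1`, `start_f1`
#'   (F1 at the canonical start), `active`.
#' @export
optimize_weights <- function(lr, labels, active = c("sex", "growth", "dev",
                                                    "hpo"),
                             seed = 1L, n_eval = 2000,
                             bounds = default_weight_bounds(),
                             extra_starts = NULL) {
  stopifnot(all(active %in% c("sex", "growth", "dev", "hpo")),
            length(active) >= 1L)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("need at least one positive and one negative label")
  }
  m <- as.matrix(as.data.frame(lr)[, c("loglr_sex", "loglr_growth",
                                       "loglr_dev", "loglr_hpo")])
  stopifnot(nrow(m) == length(labels))
  act_idx <- match(active, c("sex", "growth", "dev", "hpo"))
  expand <- function(par) {
    w <- numeric(5)
    w[1L] <- par[1L]
    w[1L + act_idx] <- par[-1L]
    w
  }
  fn <- function(par) {
    w <- expand(par)
    f1_objective(as.numeric(w[1L] + m %*% w[2:5]) > 0, labels)
  }
  prior <- mean(labels)
  start0 <- c(log(prior / (1 - prior)), rep(1, length(act_idx)))
  starts <- list(start0)
  for (s in extra_starts %||% list()) {
    stopifnot(length(s) == 5L)
    starts[[length(starts) + 1L]] <- c(s[1L], s[1L + act_idx])
  }
  lower <- c(bounds$w0[1L], rep(bounds$w[1L], length(act_idx)))
  upper <- c(bounds$w0[2L], rep(bounds$w[2L], length(act_idx)))
  per_start <- max(50L, as.integer(floor(n_eval / length(starts))))
  best <- NULL
  start_f1 <- fn(pmin(pmax(start0, lower), upper))
  for (i in seq_along(starts)) {
    res <- anneal_maximize(fn, starts[[i]], lower, upper,
                           n_eval = per_start,
                           seed = as.integer(seed) + i - 1L)
    if (is.null(best) || res$value > best$value) best <- res
  }
  w <- expand(best$par)
  names(w) <- paste0("w", 0:4)
  list(weights = w, f1 = best$value, start_f1 = start_f1, active = active)
}

#' Optimize an HPO-only model (prior and HPO weight)
#'
#' Same optimizer and contracts as [optimize_weights()] with the sex, growth
#' and development weights fixed at 0: only the intercept `w0` and the HPO
#' weight `w4` are free. This is the ablation that isolates what categorical
#' ontology terms alone can achieve.
#'
#' @inheritParams optimize_weights
#' @return As [optimize_weights()], with `weights` having `w1=w2=w3=0`.
#' @export
optimize_hpo_only <- function(lr, labels, seed = 1L, n_eval = 2000,
                              bounds = default_weight_bounds(),
                              extra_starts = NULL) {
  optimize_weights(lr, labels, active = "hpo", seed = seed, n_eval = n_eval,
                   bounds = bounds, extra_starts = extra_starts)
}
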