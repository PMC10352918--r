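# Random frog algorithm (RFA): MCMC-style subset search over wavelengths.

#' Random frog wavelength selection
#'
#' Simulates a Markov chain over variable subsets. From the current subset of
#' size q, a candidate size q* is proposed from a normal distribution
#' (sd = `theta * q`, clamped to `[2, p]`). A smaller candidate keeps the q*
#' variables with the largest standardized PLS coefficients; a larger one
#' draws `omega * (q* - q)` random candidates from outside the subset, fits a
#' PLS model on the union, and keeps the top q* variables by standardized
#' coefficient, so additions are competitively filtered. Candidates with lower
#' cross-validated RMSE are always accepted; worse candidates are accepted
#' with probability `eta * RMSECV_old / RMSECV_new`. After `burn_in`
#' iterations, each variable's selection probability is its inclusion
#' frequency along the chain. The chain is restarted `n_restarts` times and
#' the best subset encountered (lowest RMSE_CV, ties to the smaller subset)
#' is returned; selection probabilities are averaged over restarts.
#'
#' @inheritParams cars_select
#' @param n_iter chain length per restart after `burn_in` (default 1000).
#' @param burn_in iterations discarded before counting (default 100).
#' @param n_restarts independent chain restarts (default 100, matching the
#'   convention of re-running the stochastic search many times and keeping
#'   the lowest-RMSE_CV subset; reduce for quick exploration).
#' @param q_init initial subset size; default `max(2, round(0.05 * p))`.
#' @param theta proposal sd factor on the subset size (default 0.3).
#' @param eta acceptance factor for worse subsets (default 0.1).
#' As in [cars_select()], the models used inside the search (for ranking
#' variables and scoring candidate subsets) are capped at `score_lv`
#' components so the chain cannot overfit its own acceptance criterion; the
#' final calibration model is refit afterwards.
#'
#' @return a `selection_result`; `scores` are selection probabilities in
#'   `[0, 1]`, `rmsecv_trace` the per-restart best RMSE_CV.
#' @param score_lv component cap inside the search (default 2).
#' @param omega candidate-pool multiplier for growth proposals (default 3).
#' @export
random_frog_select <- function(X, y, n_iter = 1000, burn_in = 100,
                               n_restarts = 100, q_init = NULL, theta = 0.3,
                               eta = 0.1, omega = 3, folds = 5, max_lv = 10,
                               score_lv = 2, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("random frog requires at least 2 variables")
  if (n_iter <= 0) stop("chain length after burn-in must be positive")
  if (burn_in < 0) stop("burn_in must be non-negative")
  if (is.null(q_init)) q_init <- max(2L, round(0.05 * p))
  q_init <- min(max(2L, as.integer(q_init)), p)

  score_subset <- function(idx, s) {
    cap <- min(score_lv, max_feasible_lv(n, length(idx), folds, max_lv))
    curve <- rmsecv_curve(X[, idx, drop = FALSE], y, max_lv = cap,
                          folds = folds, seed = s)
    min(curve)
  }

  probs <- matrix(0, n_restarts, p)
  best_per_restart <- numeric(n_restarts)
  best_subsets <- vector("list", n_restarts)
  best_lv <- integer(n_restarts)
  total_iter <- n_iter + burn_in

  for (r in seq_len(n_restarts)) {
    seed_r <- derive_seed(seed, paste0("rfa-restart-", r))
    with_seed(seed_r, {
      V <- sort(sample(p, q_init))
      rm_V <- score_subset(V, seed_r)
      counts <- numeric(p)
      best_rm <- rm_V; best_V <- V
      for (it in seq_len(total_iter)) {
        q <- length(V)
        q_star <- round(stats::rnorm(1, q, theta * q))
        q_star <- min(max(2L, q_star), p)
        if (q_star == q) {
          V_star <- V
          rm_star <- rm_V
        } else {
          if (q_star < q) {
            fit <- fit_plsr(X[, V, drop = FALSE], y,
                            n_lv = min(score_lv,
                                       max_feasible_lv(n, q, folds, max_lv)))
            wgt <- abs(coef(fit)) * apply(X[, V, drop = FALSE], 2L, stats::sd)
            keep <- order(wgt, decreasing = TRUE)[seq_len(q_star)]
            V_star <- sort(V[keep])
          } else {
            pool <- setdiff(seq_len(p), V)
            cand <- sample(pool, min(ceiling(omega * (q_star - q)), length(pool)))
            Tset <- c(V, cand)
            fit <- fit_plsr(X[, Tset, drop = FALSE], y,
                            n_lv = min(score_lv,
                                       max_feasible_lv(n, length(Tset), folds,
                                                       max_lv)))
            wgt <- abs(coef(fit)) * apply(X[, Tset, drop = FALSE], 2L, stats::sd)
            V_star <- sort(Tset[order(wgt, decreasing = TRUE)[seq_len(q_star)]])
          }
          rm_star <- score_subset(V_star, seed_r)
        }
        accept <- rm_star <= rm_V ||
          stats::runif(1) < min(1, eta * rm_V / rm_star)
        if (accept) {
          V <- V_star; rm_V <- rm_star
        }
        if (rm_V < best_rm || (rm_V == best_rm && length(V) < length(best_V))) {
          best_rm <- rm_V; best_V <- V
        }
        if (it > burn_in) counts[V] <- counts[V] + 1
      }
      probs[r, ] <- counts / n_iter
      best_per_restart[r] <- best_rm
      best_subsets[[r]] <- best_V
      cap <- max_feasible_lv(n, length(best_V), folds, max_lv)
      best_lv[r] <- which.min(rmsecv_curve(X[, best_V, drop = FALSE], y,
                                           max_lv = cap, folds = folds,
                                           seed = seed_r))
    })
  }

  sizes <- lengths(best_subsets)
  ord <- order(best_per_restart, sizes, seq_len(n_restarts))
  best <- ord[1]
  new_selection_result(
    method = "RFA",
    wavelengths = wl_from_colnames(X),
    scores = colMeans(probs),
    selected = best_subsets[[best]],
    rmsecv_trace = best_per_restart,
    best_rmsecv = best_per_restart[best],
    n_lv = best_lv[best],
    seed = seed,
    params = list(n_iter = n_iter, burn_in = burn_in, n_restarts = n_restarts,
                  q_init = q_init, theta = theta, eta = eta, omega = omega,
                  folds = folds,
                  max_lv = max_lv, score_lv = score_lv, best_restart = best)
  )
}
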