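# Competitive adaptive reweighted sampling (CARS) wavelength selection.

#' CARS decay schedule
#'
#' Enforced retention ratio at run i of N: \eqn{r_i = a e^{-k i}} with the
#' constants fixed so the first run keeps all p variables and the last keeps
#' exactly 2: \eqn{a = (p/2)^{1/(N-1)}}, \eqn{k = \ln(p/2)/(N-1)}.
#'
#' @param p number of variables.
#' @param n_runs number of sampling runs N.
#' @return list with `a`, `k`, and `ratio` (vector of length N).
#' @export
cars_schedule <- function(p, n_runs) {
  if (p < 2) stop("CARS requires at least 2 variables")
  if (n_runs < 2) stop("CARS requires at least 2 runs")
  if (p == 2) return(list(a = 1, k = 0, ratio = rep(1, n_runs)))
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  list(a = a, k = k, ratio = a * exp(-k * seq_len(n_runs)))
}

#' Competitive adaptive reweighted sampling
#'
#' Iterative Monte-Carlo wavelength selection: at each of `n_runs` runs a
#' random `mc_ratio` fraction of the samples is drawn, a PLS model is fitted
#' on the currently retained variables, and each variable is weighted by the
#' magnitude of its standardized regression coefficient (|coefficient| times
#' the variable's standard deviation, so bands compete on contribution
#' rather than on scale). An exponentially decaying schedule
#' ([cars_schedule()]) fixes how many variables survive the run (all of them
#' at run 1, exactly 2 at run N), and adaptive reweighted sampling draws
#' that many variables without replacement with probability proportional to
#' the weights. Each run's subset is scored by cross-validated RMSE on a
#' fold partition shared by all runs (component count chosen per subset by
#' minimum RMSE_CV up to `score_lv`); the subset with the smallest RMSE_CV
#' over all runs is returned, ties going first to the smaller subset and
#' then to the earlier run.
#'
#' The internal component cap `score_lv` is deliberately small: both the
#' weighting fits and the per-subset RMSE_CV are computed on the same
#' calibration samples that drive the retention, so generous model capacity
#' lets the search overfit its own selection criterion. Restraining the
#' within-selection models keeps the criterion honest; the final calibration
#' model is refit afterwards with its own cross-validated component count.
#'
#' @inheritParams fit_plsr
#' @param n_runs number of Monte-Carlo sampling runs (default 50).
#' @param mc_ratio fraction of samples drawn per run (default 0.8).
#' @param folds cross-validation folds for RMSE_CV (default 5).
#' @param max_lv component-count cap imposed by the data (default 10).
#' @param score_lv component cap for the internal weighting fits and subset
#'   scoring (default 2; see Details).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return a `selection_result`; `scores` hold each band's retention
#'   frequency over the runs, `rmsecv_trace` the per-run RMSE_CV.
#' @export
cars_select <- function(X, y, n_runs = 50, mc_ratio = 0.8, folds = 5,
                        max_lv = 10, score_lv = 2, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("CARS requires at least 2 variables")
  if (mc_ratio <= 0 || mc_ratio >= 1) stop("mc_ratio must be in (0, 1)")
  sched <- cars_schedule(p, n_runs)
  n_mc <- max(folds, round(mc_ratio * n))

  retained <- seq_len(p)
  subsets <- vector("list", n_runs)
  trace <- numeric(n_runs)
  lv_used <- integer(n_runs)
  hits <- numeric(p)
  warned_zero <- FALSE

  with_seed(seed, {
    for (i in seq_len(n_runs)) {
      rows <- sample(n, n_mc)
      a_fit <- min(score_lv, max_feasible_lv(n_mc, length(retained), folds, max_lv))
      fit <- tryCatch(fit_plsr(X[rows, retained, drop = FALSE], y[rows],
                               n_lv = a_fit),
                      error = function(e) NULL)
      w <- if (is.null(fit)) numeric(length(retained)) else {
        abs(coef(fit)) * apply(X[rows, retained, drop = FALSE], 2L, stats::sd)
      }
      if (sum(w) <= 0) {
        if (!warned_zero) {
          warning("degenerate PLS coefficients; falling back to uniform weights")
          warned_zero <- TRUE
        }
        w <- rep(1, length(retained))
      }
      n_keep <- min(length(retained), max(2L, round(sched$ratio[i] * p)))
      # adaptive reweighted sampling: draw the retained set without
      # replacement with probability proportional to |coefficient|, so the
      # retained count follows the decay schedule exactly
      keep <- if (n_keep == length(retained)) seq_along(retained) else
        sample(length(retained), n_keep, prob = w)
      retained <- sort(retained[keep])
      hits[retained] <- hits[retained] + 1

      cap <- min(score_lv, max_feasible_lv(n, length(retained), folds, max_lv))
      curve <- rmsecv_curve(X[, retained, drop = FALSE], y, max_lv = cap,
                            folds = folds, seed = seed)
      lv_used[i] <- which.min(curve)
      trace[i] <- min(curve)
      subsets[[i]] <- retained
    }
  })

  sizes <- lengths(subsets)
  ord <- order(trace, sizes, seq_len(n_runs))
  best <- ord[1]
  new_selection_result(
    method = "CARS",
    wavelengths = wl_from_colnames(X),
    scores = hits / n_runs,
    selected = subsets[[best]],
    rmsecv_trace = trace,
    best_rmsecv = trace[best],
    n_lv = lv_used[best],
    seed = seed,
    params = list(n_runs = n_runs, mc_ratio = mc_ratio, folds = folds,
                  max_lv = max_lv, score_lv = score_lv,
                  a = sched$a, k = sched$k, best_run = best)
  )
}
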