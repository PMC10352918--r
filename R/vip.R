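# Variable importance in projection (VIP) over a PLS1 fit.

#' VIP scores of a PLS regression
#'
#' For a PLS1 model with A components, the VIP score of predictor j is
#' \deqn{VIP_j = \sqrt{K \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' where K is the number of predictors, \eqn{w_{ja}} the normalized weight of
#' predictor j on component a, and \eqn{SSY_a = q_a^2 t_a' t_a} the response
#' variance explained by component a. The scores satisfy the normalization
#' identity \eqn{\sum_j VIP_j^2 = K}, so scores above 1 mark predictors that
#' carry more than an average share of the explained response variance.
#'
#' @inheritParams fit_plsr
#' @param n_lv number of PLS components A; `NULL` chooses it by
#'   cross-validated RMSE (see [select_n_lv()]).
#' @param threshold selection cut-off; predictors with VIP above it are
#'   selected (1 by convention).
#' @param folds,seed cross-validation settings used only when `n_lv` is
#'   `NULL` and for the reported RMSE_CV.
#' @param covariate_cols see [fit_plsr()].
#' @return a `selection_result` whose `scores` are the VIP values.
#' @export
vip_select <- function(X, y, n_lv = NULL, threshold = 1, folds = 5, seed = 1,
                       covariate_cols = character(0)) {
  X <- as.matrix(X)
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(n_lv)) {
    cap <- max_feasible_lv(nrow(X), ncol(X), folds, 10L)
    sel <- select_n_lv(X, y, max_lv = cap, folds = folds, seed = seed,
                       covariate_cols = covariate_cols)
    n_lv <- sel$n_lv
  }
  model <- fit_plsr(X, y, n_lv = n_lv, covariate_cols = covariate_cols)
  v <- vip_scores(model)
  selected <- which(v > threshold)
  if (length(selected) == 0L) selected <- which.max(v)
  rm_cv <- rmsecv_curve(X[, selected, drop = FALSE], y,
                        max_lv = max_feasible_lv(nrow(X), length(selected), folds, 10L),
                        folds = folds, seed = seed)
  new_selection_result(
    method = "VIP",
    wavelengths = wl_from_colnames(X),
    scores = v, selected = selected,
    rmsecv_trace = rm_cv, best_rmsecv = min(rm_cv), n_lv = which.min(rm_cv),
    seed = seed,
    params = list(n_lv = n_lv, threshold = threshold, folds = folds)
  )
}

#' Compute VIP scores from a fitted `pls_model`
#' @param model a [fit_plsr()] fit.
#' @return numeric vector of VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W2 <- model$weights^2            # columns already unit norm
  ssy <- model$ssy
  K <- nrow(W2)
  v <- sqrt(K * as.numeric(W2 %*% ssy) / sum(ssy))
  stats::setNames(v, model$predictor_names)
}

wl_from_colnames <- function(X) {
  cn <- colnames(X)
  wl <- suppressWarnings(as.numeric(cn))
  if (is.null(cn) || anyNA(wl)) seq_len(ncol(X)) else wl
}
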