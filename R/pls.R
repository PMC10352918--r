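# NIPALS partial least squares regression (PLS1) and cross-validated RMSE.
#
# Spectral predictor columns are mean-centered only (they share units).
# Covariate columns (plant height, biomass, water content) are autoscaled
# and then weighted so the covariate block's total variance matches the
# spectral block's (balanced-block scaling): a handful of covariates in
# arbitrary units can neither drown out nor vanish next to a thousand
# spectral bands. All statistics come from the training rows alone.

pls_center <- function(X, y, covariate_cols) {
  x_center <- colMeans(X)
  x_scale <- rep(1, ncol(X))
  if (length(covariate_cols)) {
    idx <- match_covariate_cols(X, covariate_cols)
    s <- apply(X[, idx, drop = FALSE], 2L, stats::sd)
    s[s == 0] <- 1
    spec_idx <- setdiff(seq_len(ncol(X)), idx)
    total_spec_var <- if (length(spec_idx)) {
      sum(apply(X[, spec_idx, drop = FALSE], 2L, stats::var))
    } else 0
    target_sd <- if (total_spec_var > 0) {
      sqrt(total_spec_var / length(idx))
    } else 1
    x_scale[idx] <- s / target_sd
  }
  list(x_center = x_center, x_scale = x_scale, y_center = mean(y))
}

match_covariate_cols <- function(X, covariate_cols) {
  if (is.numeric(covariate_cols)) return(as.integer(covariate_cols))
  idx <- match(covariate_cols, colnames(X))
  if (anyNA(idx)) stop("covariate column(s) not found: ",
                       paste(covariate_cols[is.na(idx)], collapse = ", "))
  idx
}

# Core NIPALS loop on centered data. Returns weights W, loadings P, y
# loadings q, and score norms; rank exhaustion raises an error.
nipals_pls1 <- function(Xc, yc, n_lv) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  q <- numeric(n_lv); ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w * w))
    if (wn < 1e-12) stop("requested ", n_lv, " components but the predictor ",
                         "matrix is exhausted after ", a - 1L)
    w <- w / wn
    t <- Xc %*% w
    tt <- sum(t * t)
    if (tt < 1e-12) stop("requested ", n_lv, " components but the predictor ",
                         "matrix is exhausted after ", a - 1L)
    pv <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pv)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  list(W = W, P = P, q = q, ssy = ssy)
}

# Centered predictions for all component counts 1..A in a single pass.
# Returns an n x A matrix whose column a is the centered fit with a LVs.
pls_predict_path <- function(core, Xc) {
  A <- length(core$q)
  out <- matrix(0, nrow(Xc), A)
  acc <- numeric(nrow(Xc))
  for (a in seq_len(A)) {
    t <- Xc %*% core$W[, a]
    acc <- acc + t * core$q[a]
    out[, a] <- acc
    if (a < A) Xc <- Xc - t %*% t(core$P[, a])
  }
  out
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response. Predictors are
#' mean-centered; columns named in `covariate_cols` are additionally scaled
#' to unit variance (training statistics only). The fitted model predicts the
#' training mean response at the training mean input.
#'
#' @param X numeric matrix, samples x predictors.
#' @param y numeric response vector (dS/m for salinity targets).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param covariate_cols names (or indices) of columns to autoscale.
#' @return an object of class `pls_model` with components `coefficients`
#'   (original units), `intercept`, `weights`, `loadings`, `y_loadings`,
#'   centering/scaling vectors and `n_lv`.
#' @examples
#' X <- matrix(rnorm(60), 30, 2); y <- 3 * X[, 1] - 2 * X[, 2]
#' m <- fit_plsr(X, y, n_lv = 2)
#' coef(m)
#' @export
fit_plsr <- function(X, y, n_lv, covariate_cols = character(0)) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!is.numeric(n_lv) || n_lv < 1) stop("n_lv must be a positive integer")
  n_lv <- as.integer(n_lv)
  if (n_lv > min(nrow(X) - 1L, ncol(X))) {
    stop("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(nrow(X) - 1L, ncol(X)))
  }
  ctr <- pls_center(X, y, covariate_cols)
  Xc <- sweep(sweep(X, 2L, ctr$x_center), 2L, ctr$x_scale, "/")
  core <- nipals_pls1(Xc, y - ctr$y_center, n_lv)
  # regression vector in centered/scaled space: B = W (P'W)^-1 q
  R <- solve(crossprod(core$P, core$W), core$q)
  b_scaled <- as.numeric(core$W %*% R)
  b <- b_scaled / ctr$x_scale
  model <- list(
    coefficients = stats::setNames(b, colnames(X)),
    intercept = ctr$y_center - sum(ctr$x_center * b),
    weights = core$W, loadings = core$P, y_loadings = core$q,
    ssy = core$ssy,
    x_center = ctr$x_center, x_scale = ctr$x_scale, y_center = ctr$y_center,
    n_lv = n_lv, covariate_cols = covariate_cols,
    predictor_names = colnames(X)
  )
  class(model) <- "pls_model"
  model
}

#' @export
coef.pls_model <- function(object, ...) object$coefficients

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the same columns as the training design.
#' @param n_lv optionally predict with fewer components than fitted.
#' @param ... unused.
#' @return numeric vector of predictions. Negative salinity predictions are
#'   reported as-is; the count is attached as attribute `n_negative`.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_center)) {
    stop("newdata has ", ncol(X), " columns; model expects ", length(object$x_center))
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > object$n_lv) stop("n_lv must be in 1..", object$n_lv)
  Xc <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
  core <- list(W = object$weights, P = object$loadings, q = object$y_loadings)
  path <- pls_predict_path(core, Xc)
  out <- object$y_center + path[, n_lv]
  attr(out, "n_negative") <- sum(out < 0)
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d latent variable(s), %d predictor(s)%s>\n",
              x$n_lv, length(x$coefficients),
              if (length(x$covariate_cols))
                paste0(", covariates: ", paste(x$covariate_cols, collapse = ", "))
              else ""))
  invisible(x)
}

# Seeded fold assignment shared by every cross-validation loop.
cv_folds <- function(n, folds, seed) {
  if (folds < 2L || folds > n) stop("folds must be in 2..n")
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Cross-validated RMSE over a range of component counts
#'
#' K-fold cross-validation of PLS1: for each fold, the model is fitted on
#' the remaining folds (centering/scaling recomputed from them alone) and
#' the held-out samples are predicted with every component count up to
#' `max_lv` in one NIPALS pass.
#'
#' @inheritParams fit_plsr
#' @param max_lv largest component count to evaluate; must satisfy
#'   `max_lv <= min(n - ceiling(n/folds), p)`.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return numeric vector `rmsecv[1..max_lv]` (same units as `y`).
#' @export
rmsecv_curve <- function(X, y, max_lv, folds = 5, seed = 1,
                         covariate_cols = character(0)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  max_lv <- as.integer(max_lv)
  fold_id <- cv_folds(n, folds, seed)
  cap <- min(n - max(tabulate(fold_id)), ncol(X))
  if (max_lv < 1 || max_lv > cap) {
    stop("max_lv = ", max_lv, " infeasible; must be in 1..", cap)
  }
  press <- numeric(max_lv)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ctr <- pls_center(X[tr, , drop = FALSE], y[tr], covariate_cols)
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, ctr$x_center), 2L, ctr$x_scale, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, ctr$x_center), 2L, ctr$x_scale, "/")
    ytr <- y[tr] - ctr$y_center
    a_max <- max_lv
    core <- tryCatch(nipals_pls1(Xtr, ytr, a_max), error = function(e) NULL)
    while (is.null(core) && a_max > 1L) {
      # rank exhausted in this fold: evaluate what is achievable and let
      # higher component counts inherit the saturated prediction
      a_max <- a_max - 1L
      core <- tryCatch(nipals_pls1(Xtr, ytr, a_max), error = function(e) NULL)
    }
    # a fold with no usable covariance (e.g. constant response) falls back
    # to the centered model: predict the training mean
    path <- if (is.null(core)) {
      matrix(0, nrow(Xte), max_lv)
    } else {
      pls_predict_path(core, Xte)
    }
    if (!is.null(core) && a_max < max_lv) {
      path <- cbind(path, matrix(path[, a_max], nrow(path), max_lv - a_max))
    }
    resid <- (y[!tr] - ctr$y_center) - path
    press <- press + colSums(resid^2)
  }
  sqrt(press / n)
}

#' Cross-validated RMSE for a fixed component count
#'
#' @inheritParams rmsecv_curve
#' @param n_lv component count to evaluate.
#' @return RMSE_CV (same units as `y`), deterministic given `seed`.
#' @export
rmsecv <- function(X, y, n_lv, folds = 5, seed = 1,
                   covariate_cols = character(0)) {
  curve <- rmsecv_curve(X, y, max_lv = n_lv, folds = folds, seed = seed,
                        covariate_cols = covariate_cols)
  curve[n_lv]
}

#' Choose the number of latent variables by cross-validation
#'
#' Scans 1..`max_lv` and returns the count minimizing RMSE_CV; exact ties go
#' to the smaller count (libPLS convention).
#'
#' @inheritParams rmsecv_curve
#' @return list with `n_lv`, `rmsecv` (the minimum) and `curve`.
#' @export
select_n_lv <- function(X, y, max_lv, folds = 5, seed = 1,
                        covariate_cols = character(0)) {
  curve <- rmsecv_curve(X, y, max_lv = max_lv, folds = folds, seed = seed,
                        covariate_cols = covariate_cols)
  n_lv <- which.min(curve)
  list(n_lv = n_lv, rmsecv = curve[n_lv], curve = curve)
}

# Feasible upper bound for the LV scan on a given calibration set.
max_feasible_lv <- function(n, p, folds, max_lv) {
  max(1L, min(max_lv, n - ceiling(n / folds), p))
}
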