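# Salinity calibration: layer targets, stage-stratified splitting, covariate
# augmentation and the experiment grid over preprocessing x selector x
# covariate set x soil layer.

covariate_column_map <- c(H = "H_cm", AGB = "AGB_g", SWC = "SWC_frac")

#' Layer-averaged salinity targets
#'
#' S1 is the 0-20 cm EC, S2 the mean of the 0-20 and 20-40 cm ECs (i.e. the
#' 0-40 cm average), S3 the mean of all three layers (0-60 cm average), all
#' in dS/m.
#'
#' @param samples data.frame with columns `ec_0_20`, `ec_20_40`, `ec_40_60`.
#' @return data.frame with columns `S1`, `S2`, `S3`.
#' @examples
#' layer_targets(data.frame(ec_0_20 = 2.89, ec_20_40 = 3.23, ec_40_60 = 3.10))
#' @export
layer_targets <- function(samples) {
  need <- c("ec_0_20", "ec_20_40", "ec_40_60")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) stop("missing layer EC column(s): ",
                                 paste(missing_cols, collapse = ", "))
  ec <- as.matrix(samples[, need])
  if (anyNA(ec)) stop("missing layer EC value(s)")
  data.frame(S1 = ec[, 1],
             S2 = (ec[, 1] + ec[, 2]) / 2,
             S3 = rowMeans(ec))
}

#' Stage-stratified calibration/validation split
#'
#' Draws a fixed number of records per growth stage into the calibration set
#' and leaves the rest for validation (with 28 records per stage and 20 drawn,
#' the classic 100/40 layout over 5 stages). Reproducible given the seed.
#'
#' @param samples data.frame with a `stage_das` column.
#' @param per_stage_n calibration records per stage (default 20).
#' @param seed integer seed.
#' @return list with integer index vectors `calibration` and `validation`
#'   (disjoint, union = all rows).
#' @export
split_dataset <- function(samples, per_stage_n = 20, seed = 1) {
  stages <- sort(unique(samples$stage_das))
  cal <- integer(0)
  with_seed(seed, {
    for (s in stages) {
      idx <- which(samples$stage_das == s)
      if (length(idx) < per_stage_n) {
        stop("stage ", s, " has ", length(idx), " records; ",
             per_stage_n, " required for calibration")
      }
      cal <- c(cal, sample(idx, per_stage_n))
    }
  })
  cal <- sort(cal)
  list(calibration = cal,
       validation = setdiff(seq_len(nrow(samples)), cal))
}

#' Append growth-parameter covariates to a spectral design matrix
#'
#' Adds the requested growth parameters (by their short names `H`, `AGB`,
#' `SWC`) as ordinary columns after the spectral features. The covariate
#' columns are *not* scaled here; model fitting autoscales them using
#' training statistics only (see [fit_plsr()]).
#'
#' @param X_spec numeric matrix of spectral features (samples x bands).
#' @param samples data.frame carrying `H_cm`, `AGB_g`, `SWC_frac`.
#' @param covariates character subset of `c("H", "AGB", "SWC")`; empty for
#'   spectra-only.
#' @return the augmented matrix with attribute `covariate_cols` naming the
#'   appended columns.
#' @export
augment_with_covariates <- function(X_spec, samples, covariates = character(0)) {
  X_spec <- as.matrix(X_spec)
  if (length(covariates) == 0L) {
    attr(X_spec, "covariate_cols") <- character(0)
    return(X_spec)
  }
  bad <- setdiff(covariates, names(covariate_column_map))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  cols <- covariate_column_map[covariates]
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols)) stop("missing covariate column(s): ",
                                 paste(missing_cols, collapse = ", "))
  cov <- as.matrix(samples[, cols, drop = FALSE])
  if (anyNA(cov)) stop("missing covariate value(s)")
  colnames(cov) <- covariates
  out <- cbind(X_spec, cov)
  attr(out, "covariate_cols") <- covariates
  out
}

#' Calibrate and evaluate one PLSR model
#'
#' Chooses the number of latent variables by cross-validated RMSE on the
#' calibration rows, fits the model there, and evaluates both partitions.
#'
#' @param X design matrix (spectral features, possibly augmented via
#'   [augment_with_covariates()]).
#' @param y salinity target (dS/m).
#' @param calibration,validation row index vectors from [split_dataset()].
#' @param max_lv largest component count scanned (default 10).
#' @param folds,seed cross-validation settings.
#' @return list with the fitted `model`, chosen `n_lv`, and a one-row
#'   `report` data.frame (`LV`, `R2_C`, `RMSE_C`, `R2_V`, `RMSE_V`, `LCCC`).
#' @export
calibrate_plsr <- function(X, y, calibration, validation, max_lv = 10,
                           folds = 5, seed = 1) {
  X <- as.matrix(X)
  covariate_cols <- attr(X, "covariate_cols") %||% character(0)
  Xc <- X[calibration, , drop = FALSE]
  yc <- y[calibration]
  cap <- max_feasible_lv(nrow(Xc), ncol(Xc), folds, max_lv)
  sel <- select_n_lv(Xc, yc, max_lv = cap, folds = folds, seed = seed,
                     covariate_cols = covariate_cols)
  model <- fit_plsr(Xc, yc, n_lv = sel$n_lv, covariate_cols = covariate_cols)
  pred_c <- predict(model, Xc)
  pred_v <- predict(model, X[validation, , drop = FALSE])
  yv <- y[validation]
  report <- data.frame(
    LV = sel$n_lv,
    R2_C = r_squared(yc, pred_c), RMSE_C = rmse(yc, pred_c),
    R2_V = r_squared(yv, pred_v), RMSE_V = rmse(yv, pred_v),
    LCCC = lccc(yv, pred_v)
  )
  list(model = model, n_lv = sel$n_lv, rmsecv = sel$rmsecv, report = report,
       predictions = list(calibration = pred_c, validation = pred_v))
}

#' Control parameters for the experiment grid
#'
#' @param max_lv largest PLS component count (default 10).
#' @param folds cross-validation folds (default 5).
#' @param per_stage_n calibration records per stage (default 20).
#' @param cars list of [cars_select()] arguments.
#' @param rfa list of [random_frog_select()] arguments (defaults are reduced
#'   relative to [random_frog_select()] so a full grid stays desk-scale;
#'   raise `n_restarts` for protocol-faithful runs).
#' @param vip list of [vip_select()] arguments.
#' @return a named list.
#' @export
grid_control <- function(max_lv = 10, folds = 5, per_stage_n = 20,
                         cars = list(n_runs = 50, mc_ratio = 0.8, score_lv = 2),
                         rfa = list(n_iter = 200, burn_in = 20, n_restarts = 3,
                                    score_lv = 2),
                         vip = list(threshold = 1)) {
  list(max_lv = max_lv, folds = folds, per_stage_n = per_stage_n,
       cars = cars, rfa = rfa, vip = vip)
}

run_selector <- function(method, X, y, control, seed) {
  switch(method,
    full = NULL,
    VIP = do.call(vip_select, c(list(X = X, y = y, folds = control$folds,
                                     seed = seed), control$vip)),
    CARS = do.call(cars_select, c(list(X = X, y = y, folds = control$folds,
                                       max_lv = control$max_lv, seed = seed),
                                  control$cars)),
    RFA = do.call(random_frog_select,
                  c(list(X = X, y = y, folds = control$folds,
                         max_lv = control$max_lv, seed = seed), control$rfa)),
    stop("unknown selector: ", method)
  )
}

covariate_label <- function(covariates) {
  if (length(covariates) == 0L) "none" else paste(covariates, collapse = "+")
}

#' Run the full experiment grid
#'
#' Reproduces the study design as a grid over preprocessing ({R, FDR}),
#' wavelength selector ({full, VIP, CARS, RFA}), covariate set and soil layer
#' ({S1, S2, S3}): for every cell the spectra are preprocessed, wavelengths
#' are selected on the calibration partition only, the design is augmented
#' with covariates, the component count is chosen by cross-validated RMSE,
#' and the model is evaluated on both partitions.
#'
#' @param dataset a salinity dataset as returned by [generate_dataset()] or
#'   [read_dataset()]: a list with `samples` and `spectra` (raw, full grid).
#' @param preprocessings subset of `c("R", "FDR")` (trimmed+smoothed
#'   reflectance, and its first derivative).
#' @param selectors subset of `c("full", "VIP", "CARS", "RFA")`.
#' @param covariate_sets list of character vectors drawn from
#'   `c("H", "AGB", "SWC")`; `list(character(0))` for spectra-only.
#' @param layers subset of `c("S1", "S2", "S3")`.
#' @param seed master seed; split and selector seeds are derived from it.
#' @param control a [grid_control()] list.
#' @return data.frame with one row per cell: `layer`, `preprocessing`,
#'   `selector`, `covariates`, `n_features`, then the evaluation block
#'   `LV`, `R2_C`, `RMSE_C`, `R2_V`, `RMSE_V`, `LCCC`.
#' @export
run_experiment_grid <- function(dataset,
                                preprocessings = c("R", "FDR"),
                                selectors = c("full", "VIP", "CARS", "RFA"),
                                covariate_sets = list(character(0), "H",
                                                      c("H", "SWC"),
                                                      c("H", "AGB", "SWC")),
                                layers = c("S1", "S2", "S3"),
                                seed = 1,
                                control = grid_control()) {
  stopifnot(all(preprocessings %in% c("R", "FDR")),
            all(selectors %in% c("full", "VIP", "CARS", "RFA")),
            all(layers %in% c("S1", "S2", "S3")))
  samples <- dataset$samples
  targets <- layer_targets(samples)
  split <- split_dataset(samples, per_stage_n = control$per_stage_n,
                         seed = derive_seed(seed, "split"))
  reps <- list()
  for (prep in preprocessings) {
    reps[[prep]] <- preprocess_spectra(dataset$spectra,
                                       derivative = (prep == "FDR"))$values
  }
  rows <- list()
  for (prep in preprocessings) {
    Xfull <- reps[[prep]]
    for (layer in layers) {
      y <- targets[[layer]]
      for (method in selectors) {
        sel_seed <- derive_seed(seed, paste("select", prep, layer, method))
        sel <- run_selector(method, Xfull[split$calibration, , drop = FALSE],
                            y[split$calibration], control, sel_seed)
        cols <- if (is.null(sel)) seq_len(ncol(Xfull)) else sel$selected
        Xsel <- Xfull[, cols, drop = FALSE]
        for (cov in covariate_sets) {
          X <- augment_with_covariates(Xsel, samples, cov)
          fit <- calibrate_plsr(X, y, split$calibration, split$validation,
                                max_lv = control$max_lv, folds = control$folds,
                                seed = derive_seed(seed, paste("lv", prep, layer,
                                                               method,
                                                               covariate_label(cov))))
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(layer = layer, preprocessing = prep, selector = method,
                       covariates = covariate_label(cov),
                       n_features = length(cols)),
            fit$report)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
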