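test_that("layer targets are cumulative depth averages", {
  t1 <- layer_targets(data.frame(ec_0_20 = 2, ec_20_40 = 2, ec_40_60 = 2))
  expect_equal(unlist(t1), c(S1 = 2, S2 = 2, S3 = 2))
  t2 <- layer_targets(data.frame(ec_0_20 = 2.89, ec_20_40 = 3.23,
                                 ec_40_60 = 3.10))
  expect_equal(t2$S1, 2.89)
  expect_equal(t2$S2, 3.06)
  expect_equal(t2$S3, 3.073333, tolerance = 1e-6)
  expect_error(layer_targets(data.frame(ec_0_20 = 2.44)), "missing layer EC")
  expect_error(layer_targets(data.frame(ec_0_20 = 2, ec_20_40 = NA,
                                        ec_40_60 = 2)), "missing layer EC value")
})

test_that("stage-stratified splitting yields the 100/40 layout", {
  samples <- data.frame(stage_das = rep(c(76, 111, 124, 142, 162), each = 28))
  sp <- split_dataset(samples, per_stage_n = 20, seed = 4)
  expect_length(sp$calibration, 100)
  expect_length(sp$validation, 40)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), seq_len(140))
  for (s in unique(samples$stage_das)) {
    expect_equal(sum(samples$stage_das[sp$calibration] == s), 20)
  }
  expect_identical(split_dataset(samples, seed = 4), sp)
  expect_false(identical(split_dataset(samples, seed = 5), sp))
  expect_error(split_dataset(samples[1:30, , drop = FALSE],
                             per_stage_n = 20), "records")
})

test_that("validation draws are unbiased across treatments", {
  samples <- data.frame(stage_das = rep(c(76, 111, 124, 142, 162), each = 28),
                        treatment = rep(rep(c("T1", "T2", "T3", "T4"),
                                            each = 7), times = 5))
  counts <- sapply(1:50, function(s) {
    sp <- split_dataset(samples, seed = s)
    table(samples$treatment[sp$validation])
  })
  # each treatment holds 35 of 140 records, so 10 of 40 validation slots
  expect_true(all(abs(rowMeans(counts) - 10) <
                    3 * sqrt(10 * 0.75) / sqrt(50)))
})

test_that("covariate augmentation appends named columns without scaling", {
  samples <- data.frame(H_cm = c(50, 60, 70), AGB_g = c(80, 90, 100),
                        SWC_frac = c(0.7, 0.68, 0.66))
  X <- matrix(stats::rnorm(9), 3, 3)
  same <- augment_with_covariates(X, samples, character(0))
  expect_equal(unname(same[, ]), unname(X))
  aug <- augment_with_covariates(X, samples, c("H", "SWC"))
  expect_equal(ncol(aug), 5)
  expect_equal(attr(aug, "covariate_cols"), c("H", "SWC"))
  expect_equal(unname(aug[, "H"]), samples$H_cm)
  expect_error(augment_with_covariates(X, samples, "LAI"), "unknown")
  samples$H_cm[2] <- NA
  expect_error(augment_with_covariates(X, samples, "H"), "missing covariate")
})

test_that("a covariate equal to the target is a leakage alarm probe", {
  with_seed(1, {
    Xs <- matrix(stats::rnorm(60 * 10, sd = 0.01), 60, 10)
    y <- runif(60, 2, 4)
  })
  X <- cbind(Xs, leak = y)
  attr(X, "covariate_cols") <- "leak"
  fit <- calibrate_plsr(X, y, calibration = 1:40, validation = 41:60, seed = 2)
  expect_gte(fit$report$R2_V, 0.999)
})

test_that("calibration statistics never see the validation partition", {
  ds <- thin_dataset(generate_dataset(synthetic_config(), seed = 3), every = 20)
  y <- layer_targets(ds$samples)$S2
  fdr <- preprocess_spectra(ds$spectra, derivative = TRUE)$values
  sp <- split_dataset(ds$samples, seed = 5)
  sel1 <- cars_select(fdr[sp$calibration, ], y[sp$calibration],
                      n_runs = 15, seed = 6)
  fit1 <- calibrate_plsr(fdr[, sel1$selected, drop = FALSE], y,
                         sp$calibration, sp$validation, seed = 7)
  y2 <- y
  with_seed(8, y2[sp$validation] <- sample(y2[sp$validation]))
  sel2 <- cars_select(fdr[sp$calibration, ], y2[sp$calibration],
                      n_runs = 15, seed = 6)
  fit2 <- calibrate_plsr(fdr[, sel2$selected, drop = FALSE], y2,
                         sp$calibration, sp$validation, seed = 7)
  expect_identical(sel1$selected, sel2$selected)
  expect_equal(fit1$report$LV, fit2$report$LV)
  expect_equal(fit1$report$R2_C, fit2$report$R2_C, tolerance = 1e-12)
  expect_equal(fit1$report$RMSE_C, fit2$report$RMSE_C, tolerance = 1e-12)
})

test_that("a single grid cell returns one finite, well-formed row", {
  ds <- thin_dataset(generate_dataset(synthetic_config(), seed = 4), every = 20)
  res <- run_experiment_grid(ds, preprocessings = "R", selectors = "full",
                             covariate_sets = list(character(0)),
                             layers = "S1", seed = 9)
  expect_equal(nrow(res), 1)
  expect_true(all(is.finite(unlist(res[, c("LV", "R2_C", "RMSE_C", "R2_V",
                                           "RMSE_V", "LCCC")]))))
  expect_error(run_experiment_grid(ds, selectors = "lasso"), "selectors")
})

test_that("the full experiment grid has 96 cells with the reporting schema", {
  ds <- thin_dataset(generate_dataset(synthetic_config(), seed = 5), every = 12)
  control <- grid_control(cars = list(n_runs = 12, mc_ratio = 0.8,
                                      score_lv = 2),
                          rfa = list(n_iter = 40, burn_in = 5, n_restarts = 1,
                                     score_lv = 2))
  res <- run_experiment_grid(ds, seed = 10, control = control)
  expect_equal(nrow(res), 2 * 4 * 4 * 3)
  metric_block <- c("LV", "R2_C", "RMSE_C", "R2_V", "RMSE_V", "LCCC")
  expect_true(all(metric_block %in% names(res)))
  expect_equal(names(res)[(ncol(res) - 5):ncol(res)], metric_block)
  expect_equal(sort(unique(res$layer)), c("S1", "S2", "S3"))
  expect_setequal(unique(res$selector), c("CARS", "full", "RFA", "VIP"))
  expect_equal(sort(unique(res$covariates)),
               sort(c("none", "H", "H+SWC", "H+AGB+SWC")))
  # determinism of the whole grid under the master seed
  res2 <- run_experiment_grid(ds, seed = 10, control = control)
  expect_identical(res, res2)
  # feature selection shrinks the grid in every selected cell
  shrunk <- res[res$selector != "full", ]
  expect_true(all(shrunk$n_features < ncol(ds$spectra$values)))
})
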