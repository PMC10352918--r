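test_that("VIP scores satisfy the normalization identity", {
  with_seed(1, {
    for (i in 1:5) {
      n <- sample(20:60, 1); p <- sample(5:40, 1)
      X <- matrix(stats::rnorm(n * p), n, p)
      y <- stats::rnorm(n)
      A <- sample(1:4, 1)
      v <- vip_scores(fit_plsr(X, y, n_lv = A))
      expect_equal(sum(v^2) / p, 1, tolerance = 1e-10)
    }
  })
})

test_that("exchangeable predictors get equal VIP scores", {
  with_seed(2, {
    a <- stats::rnorm(25); b <- stats::rnorm(25)
  })
  # duplicating rows with swapped columns makes the sample exactly
  # symmetric under a column swap
  X <- rbind(cbind(a, b), cbind(b, a))
  colnames(X) <- c("x1", "x2")
  y <- X[, 1] + X[, 2]
  v <- vip_scores(fit_plsr(X, y, n_lv = 1))
  expect_equal(unname(v[1]), unname(v[2]), tolerance = 1e-10)
})

test_that("single-component VIP matches its closed form", {
  with_seed(3, {
    X <- matrix(stats::rnorm(50 * 3), 50, 3)
    y <- X[, 1] + 0.01 * stats::rnorm(50)
  })
  m <- fit_plsr(X, y, n_lv = 1)
  v <- vip_scores(m)
  Xc <- scale(X, scale = FALSE)
  w <- drop(crossprod(Xc, y - mean(y)))
  w <- w / sqrt(sum(w^2))
  expect_equal(unname(v), sqrt(3 * w^2), tolerance = 1e-8)
  expect_gt(v[1], 1)
})

test_that("vip_select applies the >1 rule and reports a valid result", {
  with_seed(4, {
    X <- matrix(stats::rnorm(60 * 20), 60, 20)
    colnames(X) <- as.character(401:420)
    y <- X[, 5] + 0.5 * X[, 12] + stats::rnorm(60, 0, 0.2)
  })
  sel <- vip_select(X, y, seed = 1)
  expect_s3_class(sel, "selection_result")
  expect_true(all(selected_wavelengths(sel) %in% 401:420))
  expect_setequal(sel$selected, which(sel$scores > 1))
  expect_true(all(c(5, 12) %in% sel$selected))
  expect_error(vip_select(X, y, threshold = -1), "positive")
})

test_that("the CARS decay schedule hits its closed-form endpoints", {
  for (p in c(10, 500, 1723)) {
    sched <- cars_schedule(p, 50)
    expect_equal(sched$a, (p / 2)^(1 / 49), tolerance = 1e-12)
    expect_equal(sched$k, log(p / 2) / 49, tolerance = 1e-12)
    expect_equal(round(sched$ratio[1] * p), p)
    expect_equal(round(sched$ratio[50] * p), 2)
    expect_true(all(diff(sched$ratio) < 0))
  }
  expect_error(cars_schedule(1, 50), "at least 2")
})

test_that("CARS keeps an exactly informative variable and tracks bookkeeping", {
  with_seed(5, X <- matrix(stats::rnorm(80), 40, 2))
  colnames(X) <- c("500", "900")
  y <- 5 * X[, 1]
  sel <- cars_select(X, y, n_runs = 10, seed = 2)
  expect_true(1 %in% sel$selected)
  expect_lt(sel$best_rmsecv, 1e-6)
  expect_equal(sel$best_rmsecv, min(sel$rmsecv_trace))
  # refitting on the selected subset with the recorded settings reproduces
  # the stored RMSE_CV (and can never beat it)
  cap <- min(sel$params$score_lv,
             salspec:::max_feasible_lv(40, length(sel$selected), 5, 10))
  refit <- min(rmsecv_curve(X[, sel$selected, drop = FALSE], y, max_lv = cap,
                            folds = 5, seed = sel$seed))
  expect_equal(refit, sel$best_rmsecv, tolerance = 1e-12)
  expect_error(cars_select(X[, 1, drop = FALSE], y), "at least 2")
})

test_that("CARS retains the schedule's variable count at the final run", {
  b <- make_band_benchmark(1, n = 60, p = 200, k = 5)
  sel <- cars_select(b$X, b$y, n_runs = 30, seed = 3)
  # retention frequencies are recorded for every band and the last run
  # keeps exactly two variables by the decay schedule
  expect_true(all(sel$scores >= 0 & sel$scores <= 1))
  expect_gte(length(sel$selected), 2)
  trace <- sel$rmsecv_trace
  expect_true(all(trace >= 0))
})

test_that("a degenerate constant response falls back to uniform weights", {
  with_seed(6, X <- matrix(stats::rnorm(100), 20, 5))
  colnames(X) <- as.character(1:5)
  expect_warning(sel <- cars_select(X, rep(2, 20), n_runs = 5, seed = 1),
                 "uniform")
  expect_s3_class(sel, "selection_result")
})

test_that("random frog tracks its minimum and finds the informative variable", {
  with_seed(7, {
    X <- matrix(stats::rnorm(60 * 20), 60, 20)
    colnames(X) <- as.character(1:20)
    y <- X[, 7] + stats::rnorm(60, 0, 0.1)
  })
  sel <- random_frog_select(X, y, n_iter = 200, burn_in = 20, n_restarts = 2,
                            seed = 9)
  expect_equal(sel$best_rmsecv, min(sel$rmsecv_trace))
  expect_true(all(sel$scores >= 0 & sel$scores <= 1))
  expect_equal(which.max(sel$scores), 7)
  expect_true(7 %in% sel$selected)
  expect_error(random_frog_select(X, y, n_iter = 0), "positive")
  expect_error(random_frog_select(X[, 1, drop = FALSE], y), "at least 2")
})

test_that("duplicated informative predictors get symmetric probabilities", {
  diffs <- sapply(1:20, function(s) {
    with_seed(s, {
      sig <- stats::rnorm(40)
      X <- cbind(a = sig, b = sig)
      y <- sig + stats::rnorm(40, 0, 0.2)
    })
    sel <- random_frog_select(X, y, n_iter = 50, burn_in = 5, n_restarts = 1,
                              seed = s)
    abs(sel$scores[1] - sel$scores[2])
  })
  expect_true(all(diffs <= 0.15))
})

test_that("all selectors shrink the paper-scale wavelength grid", {
  ds <- generate_dataset(synthetic_config(), seed = 11)
  fdr <- preprocess_spectra(ds$spectra, derivative = TRUE)
  y <- layer_targets(ds$samples)$S2
  X <- fdr$values
  p <- ncol(X)
  expect_equal(p, 1723)
  v <- vip_select(X, y, seed = 1)
  expect_lt(length(v$selected), p)
  cc <- cars_select(X, y, seed = 1)
  expect_lt(length(cc$selected), p)
  rf <- random_frog_select(X, y, n_iter = 60, burn_in = 10, n_restarts = 1,
                           seed = 1)
  expect_lt(length(rf$selected), p)
  # serialized form round-trips through CSV + JSON sidecar
  path <- file.path(tempdir(), "sel.csv")
  write_selection_result(cc, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), p)
  expect_equal(which(df$selected_flag == 1), cc$selected)
  meta <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(meta$method, "CARS")
  expect_equal(meta$n_selected, length(cc$selected))
})

test_that("with pure-noise responses VIP selection is unstable across seeds", {
  p <- 200
  sel_mat <- sapply(1:4, function(s) {
    with_seed(s, {
      X <- matrix(stats::rnorm(60 * p), 60, p)
      y <- stats::rnorm(60)
    })
    scores <- vip_scores(fit_plsr(X, y, n_lv = 2))
    scores
  })
  fractions <- colMeans(sel_mat > 1)
  expect_true(all(fractions > 0.1 & fractions < 0.7))
  # scores carry no reproducible band structure between independent draws
  cors <- stats::cor(sel_mat)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.3)
})
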