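# Fixtures built in code: no data files.

with_seed <- salspec:::with_seed

# Full-grid raw spectrum fixture (smooth vegetation-like curve).
full_grid_spectrum <- function(n = 1) {
  wl <- 350:2500
  base <- 0.05 + 0.4 / (1 + exp(-(wl - 715) / 16)) * exp(-(wl - 1100)^2 / (2 * 800^2))
  vals <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  spectra(vals, wl, kind = "raw")
}

# Regression benchmark with exactly known informative columns: iid standard
# normal predictors, response = sum of the informative columns + noise.
make_band_benchmark <- function(seed, n = 100, p = 500, k = 10, snr = 10) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- as.character(seq_len(p))
    info <- round(seq(25, p - 25, length.out = k))
    sig <- rowSums(X[, info, drop = FALSE])
    y <- sig + stats::rnorm(n, 0, stats::sd(sig) / snr)
    list(X = X, y = y, info = info)
  })
}

# Independent textbook NIPALS PLS1 oracle: explicit regression vector,
# prediction through the coefficient form (a different code path from the
# package's score-propagation predictor).
oracle_nipals <- function(X, y, n_lv) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- matrix(0, ncol(X), n_lv); q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, p); f <- f - t * q[a]
    W[, a] <- w; P[, a] <- p
  }
  B <- W %*% solve(t(P) %*% W, q)
  list(predict = function(Xn) ym + drop(sweep(as.matrix(Xn), 2, xm) %*% B),
       B = drop(B))
}

# Reduce a dataset's spectral resolution for fast grid tests.
thin_dataset <- function(dataset, every = 12) {
  sp <- dataset$spectra
  keep <- seq(1, length(sp$wavelengths), by = every)
  dataset$spectra <- suppressWarnings(
    spectra(sp$values[, keep, drop = FALSE], sp$wavelengths[keep],
            kind = sp$kind))
  dataset
}
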