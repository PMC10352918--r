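# Spectral preprocessing: noise-band trimming, Savitzky-Golay smoothing and
# first-derivative reflectance (FDR).

#' Default trim windows for canopy spectra
#'
#' Closed wavelength intervals deleted before analysis: the instrument-noise
#' margins 350-399 and 2401-2500 nm and the atmospheric water-vapour bands
#' 1361-1489 and 1811-1959 nm. On the full 350-2500 nm grid at 1 nm this
#' leaves 1723 bands in three contiguous segments.
#'
#' @return list of numeric `c(lo, hi)` intervals (nm).
#' @export
default_trim_windows <- function() {
  list(c(350, 399), c(2401, 2500), c(1361, 1489), c(1811, 1959))
}

normalize_windows <- function(windows) {
  if (length(windows) == 0L) return(list())
  windows <- lapply(windows, function(w) {
    w <- as.numeric(w)
    if (length(w) != 2L || !all(is.finite(w)) || w[1] > w[2]) {
      stop("each trim window must be a finite c(lo, hi) with lo <= hi")
    }
    w
  })
  # merge overlapping intervals so membership tests are well defined
  windows <- windows[order(vapply(windows, `[`, 0, 1))]
  out <- list(windows[[1]])
  for (w in windows[-1]) {
    last <- out[[length(out)]]
    if (w[1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], w[2]))
    } else {
      out[[length(out) + 1L]] <- w
    }
  }
  out
}

#' Remove wavelength windows from spectra
#'
#' Deletes all bands falling inside any of the given closed intervals,
#' preserving the order of the remaining bands. Used to drop instrument-noise
#' margins and water-vapour absorption regions before modeling.
#'
#' @param x a [spectra] object (raw or smoothed).
#' @param windows list of `c(lo, hi)` intervals in nm; defaults to
#'   [default_trim_windows()].
#' @return a [spectra] object on the trimmed grid.
#' @examples
#' sp <- spectra(runif(2151, 0, 1), 350:2500)
#' trimmed <- trim_bands(sp)
#' length(trimmed$wavelengths)  # 1723
#' @export
trim_bands <- function(x, windows = default_trim_windows()) {
  stopifnot(inherits(x, "spectra"))
  if (x$kind == "fdr") stop("trim_bands() applies to raw or smoothed spectra")
  windows <- normalize_windows(windows)
  keep <- rep(TRUE, length(x$wavelengths))
  for (w in windows) keep <- keep & !(x$wavelengths >= w[1] & x$wavelengths <= w[2])
  if (!any(keep)) stop("empty spectrum: all wavelengths removed by trim windows")
  subset_spectra(x, which(keep))
}

#' Savitzky-Golay smoothing
#'
#' Smooths each spectrum with a Savitzky-Golay filter (local least-squares
#' polynomial fit), applied independently to each contiguous grid segment so
#' the filter never bridges a trimmed gap. Segment edges use the one-sided
#' polynomial fit of the boundary window, which keeps the filter exact on
#' polynomials up to `polyorder` everywhere.
#'
#' @param x a [spectra] object (`raw` or `smoothed`).
#' @param window odd filter length in grid points (13 points = 13 nm on the
#'   native 1 nm grid).
#' @param polyorder polynomial order of the local fit (< `window`).
#' @return a [spectra] object with `kind = "smoothed"`.
#' @export
sg_smooth <- function(x, window = 13, polyorder = 2) {
  stopifnot(inherits(x, "spectra"))
  check_sg_args(window, polyorder)
  vals <- apply_per_segment(x, function(m, wl) {
    t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window))
  }, min_len = window, what = "smoothing window")
  spectra_unchecked(vals, x$wavelengths, "smoothed")
}

#' First-derivative reflectance
#'
#' Differentiates each spectrum with respect to wavelength (units nm^-1),
#' per contiguous segment. The default uses the Savitzky-Golay derivative
#' filter with the same window and polynomial order as the smoother, which is
#' exact on polynomials up to `polyorder`; a finite central difference is
#' offered as an alternative.
#'
#' @param x a [spectra] object (smoothed input recommended; raw accepted).
#' @param method `"sg"` (Savitzky-Golay derivative, default) or `"diff"`
#'   (central differences, one-sided at segment edges).
#' @param window,polyorder Savitzky-Golay settings, as in [sg_smooth()].
#' @return a [spectra] object with `kind = "fdr"`.
#' @export
first_derivative <- function(x, method = c("sg", "diff"), window = 13, polyorder = 2) {
  stopifnot(inherits(x, "spectra"))
  method <- match.arg(method)
  if (x$kind == "fdr") stop("input is already a derivative spectrum")
  step <- grid_step(x$wavelengths)
  if (method == "sg") {
    check_sg_args(window, polyorder)
    min_len <- max(window, 3L)
    vals <- apply_per_segment(x, function(m, wl) {
      t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window, m = 1, ts = step))
    }, min_len = min_len, what = "derivative window")
  } else {
    vals <- apply_per_segment(x, function(m, wl) {
      t(apply(m, 1L, central_diff, h = step))
    }, min_len = 3L, what = "central difference")
  }
  spectra_unchecked(vals, x$wavelengths, "fdr")
}

central_diff <- function(v, h) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / h
  d[n] <- (v[n] - v[n - 1]) / h
  if (n > 2L) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  d
}

check_sg_args <- function(window, polyorder) {
  if (window %% 2 != 1) stop("Savitzky-Golay window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than the window")
  invisible(TRUE)
}

apply_per_segment <- function(x, fn, min_len, what) {
  segs <- spectral_segments(x$wavelengths)
  out <- x$values
  for (idx in segs) {
    if (length(idx) < min_len) {
      stop("contiguous segment of length ", length(idx),
           " is shorter than the ", what, " (", min_len, " points)")
    }
    res <- fn(x$values[, idx, drop = FALSE], x$wavelengths[idx])
    if (nrow(x$values) == 1L) res <- matrix(res, nrow = 1L)
    out[, idx] <- res
  }
  out
}

#' Standard preprocessing chain
#'
#' Trims noise bands, smooths per segment, and optionally differentiates:
#' the two analysis-ready representations are trimmed+smoothed reflectance
#' (`derivative = FALSE`, "R") and first-derivative reflectance
#' (`derivative = TRUE`, "FDR").
#'
#' @inheritParams sg_smooth
#' @param windows trim windows, see [trim_bands()].
#' @param derivative logical; return FDR instead of smoothed reflectance.
#' @param derivative_of either `"smoothed"` (default) or `"raw"`; which
#'   representation the derivative filter is applied to.
#' @return a [spectra] object.
#' @export
preprocess_spectra <- function(x, windows = default_trim_windows(),
                               window = 13, polyorder = 2,
                               derivative = FALSE,
                               derivative_of = c("smoothed", "raw")) {
  derivative_of <- match.arg(derivative_of)
  trimmed <- trim_bands(x, windows)
  smoothed <- sg_smooth(trimmed, window = window, polyorder = polyorder)
  if (!derivative) return(smoothed)
  base <- if (derivative_of == "smoothed") smoothed else trimmed
  first_derivative(base, method = "sg", window = window, polyorder = polyorder)
}

#' Band-wise Pearson correlation with a scalar target
#'
#' Correlates every wavelength's values across samples with a per-sample
#' target (e.g. layer-averaged soil salinity), returning the full correlation
#' curve and the band with the largest absolute correlation. Zero-variance
#' bands get `NA` and are excluded from the argmax.
#'
#' @param x a [spectra] object with at least 3 samples.
#' @param target numeric vector, one value per sample.
#' @return data.frame with columns `wavelength` and `r`, with attributes
#'   `best_wavelength`, `best_r` and `n`.
#' @export
bandwise_correlation <- function(x, target) {
  stopifnot(inherits(x, "spectra"))
  n <- nrow(x$values)
  if (n < 3L) stop("at least 3 samples are required for band-wise correlation")
  if (length(target) != n) stop("target length must match the number of samples")
  v <- x$values
  sds <- apply(v, 2L, stats::sd)
  r <- rep(NA_real_, ncol(v))
  ok <- sds > 0 & stats::sd(target) > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(v[, ok, drop = FALSE], target))
  out <- data.frame(wavelength = x$wavelengths, r = r)
  if (any(!is.na(r))) {
    best <- which.max(abs(r))
    attr(out, "best_wavelength") <- x$wavelengths[best]
    attr(out, "best_r") <- r[best]
  } else {
    attr(out, "best_wavelength") <- NA_real_
    attr(out, "best_r") <- NA_real_
  }
  attr(out, "n") <- n
  out
}

#' Spectral region bounds
#'
#' Conventional canopy-spectrum regions: visible 400-780 nm, short-wave
#' infrared 780-1100 nm, long-wave infrared 1100-2400 nm.
#'
#' @param region one of `"vis"`, `"swir"`, `"lwir"`.
#' @return numeric `c(lo, hi)` in nm.
#' @export
spectral_region <- function(region = c("vis", "swir", "lwir")) {
  switch(match.arg(region),
         vis = c(400, 780), swir = c(780, 1100), lwir = c(1100, 2400))
}

#' Per-sample mean reflectance over a spectral region
#' @param x a [spectra] object.
#' @param region as in [spectral_region()].
#' @return numeric vector, one mean per sample.
#' @export
region_means <- function(x, region = c("vis", "swir", "lwir")) {
  b <- spectral_region(region)
  idx <- x$wavelengths >= b[1] & x$wavelengths <= b[2]
  if (!any(idx)) stop("no bands fall in the requested region")
  rowMeans(x$values[, idx, drop = FALSE])
}
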