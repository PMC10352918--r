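# Spectra container: a set of reflectance spectra on a shared wavelength grid.

#' Construct a spectra object
#'
#' Bundles one or more reflectance spectra sampled on a common, strictly
#' increasing wavelength grid (nm). Raw and smoothed reflectance must be
#' finite and non-negative; values above 1 (calibration-panel artifacts in
#' field canopy data) are tolerated up to 1.5 with a warning and rejected
#' above. First-derivative reflectance (`kind = "fdr"`, units nm^-1) may take
#' any sign.
#'
#' @param values numeric vector (one spectrum) or matrix with one row per
#'   sample and one column per wavelength.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing. The grid may contain gaps (e.g. after trimming noise bands);
#'   contiguous segments are recovered with [spectral_segments()].
#' @param kind one of `"raw"`, `"smoothed"`, `"fdr"`.
#' @return an object of class `spectra`: a list with elements `wavelengths`,
#'   `values` (samples x wavelengths matrix) and `kind`.
#' @examples
#' sp <- spectra(runif(2151, 0.05, 0.6), 350:2500, kind = "raw")
#' sp
#' @export
spectra <- function(values, wavelengths, kind = c("raw", "smoothed", "fdr")) {
  kind <- match.arg(kind)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) == 0L) stop("empty spectrum: no wavelengths supplied")
  if (ncol(values) != length(wavelengths)) {
    stop("number of value columns (", ncol(values),
         ") does not match the wavelength grid (", length(wavelengths), ")")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  if (!all(is.finite(values))) stop("spectral values must be finite")
  if (kind != "fdr") {
    if (any(values < 0)) stop("raw/smoothed reflectance must be non-negative")
    if (any(values > 1.5)) {
      stop("reflectance above 1.5 found; values this large indicate a ",
           "calibration failure rather than a panel artifact")
    }
    if (any(values > 1)) {
      warning("reflectance above 1 found (tolerated up to 1.5; ",
              "typically a calibration-panel artifact)")
    }
  }
  colnames(values) <- as.character(wavelengths)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectra")
}

#' @export
print.spectra <- function(x, ...) {
  seg <- spectral_segments(x$wavelengths)
  cat(sprintf("<spectra: %d sample(s), %d bands (%s), %d contiguous segment(s), %g-%g nm>\n",
              nrow(x$values), length(x$wavelengths), x$kind, length(seg),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra <- function(x) dim(x$values)

# Grid step: smallest spacing on the grid (1 nm for the native instrument grid).
grid_step <- function(wavelengths) {
  if (length(wavelengths) < 2L) return(1)
  min(diff(wavelengths))
}

#' Contiguous segments of a wavelength grid
#'
#' A trimmed grid consists of runs of equally spaced wavelengths separated by
#' gaps. Per-segment processing (smoothing, derivatives) must never mix
#' values across a gap.
#'
#' @param wavelengths strictly increasing numeric vector (nm).
#' @return list of integer index vectors, one per contiguous segment.
#' @examples
#' spectral_segments(c(400:402, 410:413))
#' @export
spectral_segments <- function(wavelengths) {
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  n <- length(wavelengths)
  if (n <= 1L) return(list(seq_len(n)))
  step <- grid_step(wavelengths)
  breaks <- which(diff(wavelengths) > step * 1.5)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

# Subset a spectra object by wavelength index, preserving class and metadata.
subset_spectra <- function(x, idx) {
  spectra_unchecked(x$values[, idx, drop = FALSE], x$wavelengths[idx], x$kind)
}

# Fast internal constructor that skips value validation (used after
# operations that cannot invalidate an already-validated object).
spectra_unchecked <- function(values, wavelengths, kind) {
  colnames(values) <- as.character(wavelengths)
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectra")
}

as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra")) x$values else as.matrix(x)
}
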