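# CSV interfaces: wide/long spectra tables and the sample table.

#' Read spectra from CSV
#'
#' Wide format: first column `sample_id`, remaining columns named by the
#' wavelength in nm (validated strictly increasing). Long format: columns
#' `sample_id`, `wavelength_nm`, `reflectance`. `format = "auto"` detects
#' which is present.
#'
#' @param path CSV file.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param kind spectrum kind to stamp on the result (see [spectra()]).
#' @return a [spectra] object with sample ids as row names.
#' @export
read_spectra_csv <- function(path, format = c("auto", "wide", "long"),
                             kind = "raw") {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("sample_id", "wavelength_nm", "reflectance") %in% names(df)))
      "long" else "wide"
  }
  if (format == "long") {
    wl <- sort(unique(df$wavelength_nm))
    ids <- unique(df$sample_id)
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, as.character(wl)))
    m[cbind(match(df$sample_id, ids), match(df$wavelength_nm, wl))] <- df$reflectance
    if (anyNA(m)) stop("long spectra table is not complete on a common grid")
    out <- spectra(m, wl, kind = kind)
  } else {
    if (names(df)[1] != "sample_id") stop("wide spectra CSV must start with a sample_id column")
    wl <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(wl)) stop("wide spectra CSV columns must be named by wavelength (nm)")
    if (any(diff(wl) <= 0)) stop("wavelength header must be strictly increasing")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    out <- spectra(m, wl, kind = kind)
  }
  out
}

#' Write spectra to a wide CSV
#'
#' @param x a [spectra] object.
#' @param path output file.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sample_csv_columns <- c("sample_id", "treatment", "stage_das", "H_cm",
                        "AGB_g", "SWC_frac", "ec_0_20", "ec_20_40", "ec_40_60")

#' Read the sample table CSV
#'
#' Expects the columns `sample_id`, `treatment`, `stage_das`, `H_cm`,
#' `AGB_g`, `SWC_frac`, `ec_0_20`, `ec_20_40`, `ec_40_60`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(sample_csv_columns, names(df))
  if (length(missing_cols)) stop("sample table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  df
}

#' Write a dataset to a directory
#'
#' Emits `samples.csv` (sample table) and `spectra.csv` (wide spectra) in a
#' form [read_dataset()] round-trips.
#'
#' @param dataset a `salinity_dataset` (see [generate_dataset()]) or any
#'   list with `samples` and `spectra`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$samples[, sample_csv_columns],
                   file.path(dir, "samples.csv"), row.names = FALSE)
  write_spectra_csv(dataset$spectra, file.path(dir, "spectra.csv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding `samples.csv` and `spectra.csv`.
#' @return a `salinity_dataset` (without latent generator internals).
#' @export
read_dataset <- function(dir) {
  samples <- read_samples_csv(file.path(dir, "samples.csv"))
  spectra <- read_spectra_csv(file.path(dir, "spectra.csv"), format = "wide")
  if (!identical(rownames(spectra$values), as.character(samples$sample_id))) {
    m <- match(samples$sample_id, rownames(spectra$values))
    if (anyNA(m)) stop("sample ids in spectra.csv and samples.csv disagree")
    spectra$values <- spectra$values[m, , drop = FALSE]
  }
  structure(list(samples = samples, spectra = spectra, latent = NULL,
                 config = NULL, seed = NULL),
            class = "salinity_dataset")
}
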