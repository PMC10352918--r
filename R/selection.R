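# Common container for wavelength-selection results.

new_selection_result <- function(method, wavelengths, scores, selected,
                                 rmsecv_trace, best_rmsecv, n_lv, seed, params) {
  stopifnot(length(scores) == length(wavelengths),
            all(selected %in% seq_along(wavelengths)), length(selected) >= 1,
            all(rmsecv_trace >= 0 | is.na(rmsecv_trace)), best_rmsecv >= 0)
  structure(list(
    method = method,
    wavelengths = wavelengths,
    scores = scores,
    selected = sort(unique(as.integer(selected))),
    rmsecv_trace = rmsecv_trace,
    best_rmsecv = best_rmsecv,
    n_lv = n_lv,
    seed = seed,
    params = params
  ), class = "selection_result")
}

#' Wavelengths picked by a selection result
#' @param x a `selection_result`.
#' @return numeric vector of selected wavelengths (nm).
#' @export
selected_wavelengths <- function(x) {
  stopifnot(inherits(x, "selection_result"))
  x$wavelengths[x$selected]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<%s selection: %d of %d bands, best RMSE_CV = %.4g (%d LV)>\n",
              x$method, length(x$selected), length(x$wavelengths),
              x$best_rmsecv, x$n_lv))
  invisible(x)
}

#' Serialize a selection result to CSV (+ JSON sidecar)
#'
#' Writes `wavelength, score, selected_flag` rows, and a JSON sidecar with
#' the method, parameters, seed and best RMSE_CV so runs are auditable.
#'
#' @param x a `selection_result`.
#' @param path output CSV path; the sidecar gets extension `.json`.
#' @export
write_selection_result <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  df <- data.frame(wavelength = x$wavelengths, score = x$scores,
                   selected_flag = as.integer(seq_along(x$wavelengths) %in% x$selected))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(method = x$method, params = x$params, seed = x$seed,
               n_lv = x$n_lv, best_rmsecv = x$best_rmsecv,
               n_selected = length(x$selected))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
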