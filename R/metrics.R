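# Model evaluation metrics and the percent-change arithmetic used when
# summarizing salinity dynamics and correlation curves.

check_lengths <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have the same length")
  if (!all(is.finite(y)) || !all(is.finite(yhat))) stop("inputs must be finite")
}

#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SST`, with SST taken about the mean of the measured values.
#' Can be negative on a validation partition when predictions are worse than
#' the mean.
#'
#' @param y measured values.
#' @param yhat predicted values.
#' @return unitless scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 2L) stop("at least 2 observations required")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined for a constant measured vector")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return scalar in the units of `y` (dS/m for salinity targets).
#' @export
rmse <- function(y, yhat) {
  check_lengths(y, yhat)
  if (length(y) < 1L) stop("at least 1 observation required")
  sqrt(mean((y - yhat)^2))
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{LCCC = \frac{2\rho\sigma_y\sigma_{\hat y}}
#'   {\sigma_y^2 + \sigma_{\hat y}^2 + (\mu_y - \mu_{\hat y})^2}}
#' measuring agreement with the 1:1 line: it equals Pearson's correlation
#' scaled down by a bias-correction factor, so `|LCCC| <= |rho|` and
#' `LCCC = 1` only when predictions match measurements exactly.
#'
#' @inheritParams r_squared
#' @param variance `"population"` (1/n, the standard Lin definition, default)
#'   or `"sample"` (1/(n-1)); the choice only matters through the relative
#'   weight of the squared mean difference.
#' @return unitless scalar in `[-1, 1]`.
#' @export
lccc <- function(y, yhat, variance = c("population", "sample")) {
  check_lengths(y, yhat)
  variance <- match.arg(variance)
  n <- length(y)
  if (n < 2L) stop("at least 2 observations required")
  denom_n <- if (variance == "population") n else n - 1L
  my <- mean(y); myh <- mean(yhat)
  vy <- sum((y - my)^2) / denom_n
  vyh <- sum((yhat - myh)^2) / denom_n
  if (vy == 0 || vyh == 0) stop("LCCC undefined for constant input")
  cyh <- sum((y - my) * (yhat - myh)) / denom_n
  2 * cyh / (vy + vyh + (my - myh)^2)
}

#' Percent change between two scalars
#'
#' `100 * (new - baseline) / baseline`. In `mode = "decrease"` a drop is
#' reported as a positive magnitude (`100 * (baseline - new) / baseline`),
#' matching how salinity declines between growth stages are quoted.
#'
#' @param baseline reference value (non-zero).
#' @param new comparison value.
#' @param mode `"change"` (signed) or `"decrease"` (positive magnitude of a
#'   drop).
#' @param digits decimal places for half-up rounding; `NULL` for no rounding.
#' @return percent value.
#' @examples
#' percent_change(0.264, 0.399)                     # +51.14 %
#' percent_change(2.39, 2.30, mode = "decrease")    # 3.77 %
#' @export
percent_change <- function(baseline, new, mode = c("change", "decrease"),
                           digits = 2) {
  mode <- match.arg(mode)
  if (!is.finite(baseline) || baseline == 0) stop("baseline must be finite and non-zero")
  pct <- 100 * (new - baseline) / baseline
  if (mode == "decrease") pct <- -pct
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  pct
}

#' Range of per-treatment percent decreases in an EC table
#'
#' Given a table of layer-averaged soil salinity means by treatment and
#' sampling date, computes each treatment's percent decrease between two
#' dates and returns the min/max across treatments (half-up, 2 d.p.).
#'
#' @param ec_table data.frame with columns `layer`, `das`, `treatment`,
#'   `ec_mean` (see [field_ec_table()]).
#' @param layer layer label present in the table (e.g. `"S1"`).
#' @param das_from,das_to the two sampling dates (days after sowing).
#' @return named numeric `c(min, max)` in percent.
#' @export
percent_decrease_range <- function(ec_table, layer, das_from, das_to) {
  sub <- ec_table[ec_table$layer == layer & ec_table$das %in% c(das_from, das_to), ]
  treatments <- sort(unique(ec_table$treatment))
  dec <- vapply(treatments, function(tr) {
    from <- sub$ec_mean[sub$treatment == tr & sub$das == das_from]
    to <- sub$ec_mean[sub$treatment == tr & sub$das == das_to]
    if (length(from) != 1L || length(to) != 1L) {
      stop("missing cell for treatment ", tr, " in layer ", layer)
    }
    percent_change(from, to, mode = "decrease", digits = NULL)
  }, numeric(1))
  round_half_up(c(min = min(dec), max = max(dec)), 2)
}

#' Correlation between growth parameters and layer-averaged salinity
#'
#' Pearson correlations between plant height, aboveground biomass and shoot
#' water content and the layer targets S1/S2/S3, either pooled over all
#' records or per growth stage. Constant columns yield `NA`.
#'
#' @param samples data.frame with columns `H_cm`, `AGB_g`, `SWC_frac`,
#'   `ec_0_20`, `ec_20_40`, `ec_40_60` and (for `by_stage`) `stage_das`.
#' @param by_stage if `TRUE`, return one correlation matrix per stage.
#' @return a 3x3 matrix (growth parameter x layer), or a named list of them.
#' @export
growth_salinity_correlation <- function(samples, by_stage = FALSE) {
  if (by_stage) {
    stages <- sort(unique(samples$stage_das))
    out <- lapply(stages, function(s) {
      growth_salinity_correlation(samples[samples$stage_das == s, , drop = FALSE])
    })
    names(out) <- as.character(stages)
    return(out)
  }
  if (nrow(samples) < 3L) stop("at least 3 records required per correlation cell")
  growth <- as.matrix(samples[, c("H_cm", "AGB_g", "SWC_frac")])
  targets <- as.matrix(layer_targets(samples))
  r <- matrix(NA_real_, 3L, 3L,
              dimnames = list(c("H", "AGB", "SWC"), c("S1", "S2", "S3")))
  for (i in 1:3) for (j in 1:3) {
    if (stats::sd(growth[, i]) > 0 && stats::sd(targets[, j]) > 0) {
      r[i, j] <- stats::cor(growth[, i], targets[, j])
    }
  }
  r
}

#' Evaluate predictions on a partition
#'
#' Convenience bundle of the three model metrics.
#'
#' @inheritParams r_squared
#' @param partition label stored alongside the metrics.
#' @return data.frame with `partition`, `n`, `r2`, `rmse`, `lccc` and the
#'   count of negative predictions (`n_negative`; negative salinity
#'   predictions are reported as-is, not clipped).
#' @export
eval_report <- function(y, yhat, partition = "validation") {
  data.frame(partition = partition, n = length(y),
             r2 = r_squared(y, yhat), rmse = rmse(y, yhat),
             lccc = lccc(y, yhat), n_negative = sum(yhat < 0))
}
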