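# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded operations (fold assignment, Monte-Carlo draws) never perturb the
#' global random stream. A `NULL` seed leaves the RNG untouched.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Round half away from zero, the convention used for reported percents.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a stage seed from a master seed
#'
#' Stages of the pipeline (simulation, splitting, each selector) draw their
#' own seed from the master seed and a stage tag, so a stage can be re-run in
#' isolation and still line up with a full run.
#'
#' @param seed integer master seed.
#' @param tag character stage label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 1009 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
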