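#' Log-spaced concentration series
#'
#' Generates `n` concentrations equally spaced on the log10 scale between
#' `lo` and `hi` (inclusive), the standard layout for a decade-spanning
#' calibration series.
#'
#' @param lo,hi positive range bounds (ng/mL).
#' @param n number of points, at least 2.
#' @return numeric vector of length `n`, strictly increasing.
#' @export
#' @examples
#' log_spaced_concentrations(0.05, 500, 8)
log_spaced_concentrations <- function(lo, hi, n) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo > 0, hi > lo, n >= 2)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Width of a linear detection range
#'
#' The conventional figure of merit for sensor comparison: the ratio of the
#' upper to the lower bound of the linear range (dimensionless fold-width).
#'
#' @param lo,hi lower and upper detection bounds, same units, both positive.
#' @return `hi / lo`.
#' @export
linear_range_width <- function(lo, hi) {
  stopifnot(lo > 0, hi > lo)
  hi / lo
}

# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
# seed = NULL runs the code as-is (caller accepts irreproducibility).
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# stop() with a condition class so callers (and the CLI) can map errors
# to exit codes without string matching.
abort <- function(msg, class = "achesense_error") {
  stop(structure(
    class = c(class, "achesense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
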