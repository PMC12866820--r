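#' Fit the log-linear concentration-response calibration
#'
#' Ordinary least squares of the response on log10(concentration),
#' \eqn{y = a \log_{10}(c) + b} — the standard quantification model for a
#' decade-spanning colorimetric series. Blanks (c = 0) must be excluded
#' beforehand (log undefined); they serve only the LOD estimate.
#'
#' @param table data frame with columns `concentration_ng_per_ml` and
#'   `response` (a column named for a specific index, e.g.
#'   `G_over_RplusB`, is accepted via `response_col`).
#' @param response_col name of the response column.
#' @param algorithm_id label carried into the fit (for ranking tables).
#' @return object of class `calibration_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `n`, `conc_range`, `algorithm_id`, plus
#'   `slope_se` and `df` for interval construction. A response constant in
#'   c (SS_tot = 0) reports `r_squared = 0` so rankings stay total.
#' @export
#' @examples
#' tab <- simulate_responses(assay_sim_truth(noise_sd = 0))
#' fit_log_linear(tab)
fit_log_linear <- function(table, response_col = "response",
                           algorithm_id = response_col) {
  stopifnot(is.data.frame(table), "concentration_ng_per_ml" %in% names(table),
            response_col %in% names(table))
  cc <- table$concentration_ng_per_ml
  y <- table[[response_col]]
  if (any(!is.finite(cc)) || any(cc <= 0))
    abort("all concentrations must be positive (exclude blanks before fitting)")
  if (any(!is.finite(y))) abort("responses must be finite")
  if (length(cc) < 2) abort("at least 2 points required")
  if (length(unique(cc)) < 2) abort("all concentrations identical: slope undefined")
  x <- log10(cc)
  m <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(m)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  sm <- suppressWarnings(summary(m))  # noiseless data: "perfect fit" warning
  coefs <- stats::coef(m)
  if (ss_tot == 0) coefs <- c(mean(y), 0)  # exact zero slope, not lm roundoff
  structure(
    list(slope = unname(coefs[2]),
         intercept = unname(coefs[1]),
         r_squared = r2,
         n = length(cc),
         conc_range = range(cc),
         algorithm_id = algorithm_id,
         slope_se = sm$coefficients[2, 2],
         df = m$df.residual),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Log-linear calibration [%s]\n", x$algorithm_id))
  cat(sprintf("  y = %.4f log10(c) + %.4f   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  linear range: %g - %g ng/mL\n", x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Invert the calibration: response to concentration
#'
#' \eqn{c = 10^{(y - b)/a}}. Predictions outside the fitted concentration
#' range are flagged as extrapolations.
#'
#' @param fit a [fit_log_linear()] result with nonzero slope.
#' @param y response value(s).
#' @return data frame with `response`, `concentration_ng_per_ml`,
#'   `extrapolated`.
#' @export
predict_concentration <- function(fit, y) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) abort("zero slope: concentration not identifiable")
  cc <- 10^((y - fit$intercept) / fit$slope)
  data.frame(response = y, concentration_ng_per_ml = cc,
             extrapolated = cc < fit$conc_range[1] | cc > fit$conc_range[2])
}

#' k-sigma limit of detection
#'
#' The blank-based detection limit convention: the critical response is
#' the blank mean displaced by `k` blank standard deviations in the
#' direction of the slope, and the LOD is that response inverted through
#' the calibration line:
#' \deqn{y_{crit} = \bar{y}_{blank} + sign(a) \cdot k \cdot s_{blank},
#'       \quad LOD = 10^{(y_{crit} - b)/a}}
#'
#' @param fit a [fit_log_linear()] result, nonzero slope.
#' @param blanks numeric vector of at least 3 blank-replicate responses.
#' @param k sigma multiplier (default 3, the usual convention).
#' @return object of class `lod_estimate`: `lod`, `blank_mean`,
#'   `blank_sd`, `k`, `y_crit`.
#' @export
lod_ksigma <- function(fit, blanks, k = 3) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (length(blanks) < 3) abort("at least 3 blank replicates required")
  if (fit$slope == 0) abort("zero slope: LOD undefined")
  m <- mean(blanks); s <- stats::sd(blanks)
  y_crit <- m + sign(fit$slope) * k * s
  structure(
    list(lod = 10^((y_crit - fit$intercept) / fit$slope),
         blank_mean = m, blank_sd = s, k = k, y_crit = y_crit),
    class = "lod_estimate"
  )
}

#' Inhibition efficiency (the Ellman-assay readout)
#'
#' \deqn{IE\% = \frac{A - A_1}{A - A_0} \times 100}
#' where A is the uninhibited absorbance at 412 nm, A0 the blank baseline
#' and A1 the absorbance after incubation with the inhibitor. Invariant
#' under any common affine rescaling of the three absorbances.
#'
#' @param A,A0,A1 absorbances (vectors recycle); `A != A0` required.
#' @return inhibition efficiency in percent.
#' @export
#' @examples
#' inhibition_efficiency(1.0, 0.2, 0.6)  # 50
inhibition_efficiency <- function(A, A0, A1) {
  if (any(A == A0)) abort("A equals A0: zero dynamic range")
  (A - A1) / (A - A0) * 100
}

#' Rank color-index algorithms by detection performance
#'
#' Fits the log-linear calibration per algorithm, estimates each LOD from
#' its blank replicates, and ranks by ascending LOD (ties broken by
#' descending R-squared, then by name). Algorithms with zero slope get a
#' non-finite LOD and sort last.
#'
#' @param tables named list of response tables (shared concentration
#'   grid), each with columns `concentration_ng_per_ml`, `response`.
#' @param blanks named list of blank-replicate vectors (same names).
#' @param k sigma multiplier passed to [lod_ksigma()].
#' @return data frame: `algorithm`, `slope`, `intercept`, `r_squared`,
#'   `lod`, sorted best-first.
#' @export
compare_algorithms <- function(tables, blanks, k = 3) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)),
            all(names(tables) %in% names(blanks)))
  grids <- lapply(tables, function(t) t$concentration_ng_per_ml)
  if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])), logical(1))))
    abort("concentration grids differ between algorithms")
  rows <- lapply(names(tables), function(nm) {
    fit <- fit_log_linear(tables[[nm]], algorithm_id = nm)
    lod <- if (fit$slope == 0) Inf else lod_ksigma(fit, blanks[[nm]], k)$lod
    data.frame(algorithm = nm, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, lod = lod)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lod, -out$r_squared, out$algorithm), ]
  rownames(out) <- NULL
  out
}

#' Write a calibration fit (with optional LOD) to JSON
#'
#' @param fit a `calibration_fit`.
#' @param path output path.
#' @param lod optional `lod_estimate` to include.
#' @export
write_fit_json <- function(fit, path, lod = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  obj <- list(slope = fit$slope, intercept = fit$intercept,
              r_squared = fit$r_squared, n = fit$n,
              conc_range = fit$conc_range, algorithm = fit$algorithm_id)
  if (!is.null(lod)) obj$lod <- lod$lod
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
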