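#' Ground truth for a simulated colorimetric response series
#'
#' Bundles the parameters of the log-linear concentration-response model
#' \eqn{y = a \log_{10}(c) + b} together with the concentration grid, the
#' additive noise level and the RNG seed. The defaults are the study
#' conditions of the assay this package models: the G/(R+B) calibration
#' line slope 0.823 and intercept 0.745 over 8 log-spaced paraoxon
#' concentrations spanning 0.05-500 ng/mL.
#'
#' @param slope response change per decade of concentration.
#' @param intercept response at 1 ng/mL.
#' @param noise_sd standard deviation of additive Gaussian response noise
#'   (response units, >= 0). Replicate scatter of smartphone colorimetric
#'   readings is typically a few percent of the dynamic range; 0.05 is used
#'   as the default.
#' @param concentrations strictly positive, strictly increasing vector of
#'   analyte concentrations in ng/mL.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return an object of class `assay_sim_truth`.
#' @export
assay_sim_truth <- function(slope = 0.823, intercept = 0.745,
                            noise_sd = 0.05,
                            concentrations = log_spaced_concentrations(0.05, 500, 8),
                            seed = 1L) {
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    abort("concentrations must be finite and strictly positive (log10 undefined otherwise)")
  if (is.unsorted(concentrations, strictly = TRUE))
    abort("concentrations must be strictly increasing")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort("noise_sd must be >= 0")
  structure(
    list(slope = slope, intercept = intercept, noise_sd = noise_sd,
         concentrations = as.numeric(concentrations), seed = as.integer(seed)),
    class = "assay_sim_truth"
  )
}

#' Simulate a concentration-response table
#'
#' Draws responses from the log-linear model
#' \eqn{y_i = a \log_{10}(c_i) + b + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}. The response is treated as an
#' abstract color-index reading (difference-map convention), so negative
#' values at low concentrations are legitimate and are not clipped.
#'
#' @param truth an [assay_sim_truth()] object.
#' @return data frame with columns `concentration_ng_per_ml`, `response`.
#' @export
#' @examples
#' simulate_responses(assay_sim_truth(noise_sd = 0))
simulate_responses <- function(truth) {
  stopifnot(inherits(truth, "assay_sim_truth"))
  cc <- truth$concentrations
  mu <- truth$slope * log10(cc) + truth$intercept
  eps <- local_seed(truth$seed, stats::rnorm(length(cc), 0, truth$noise_sd))
  data.frame(concentration_ng_per_ml = cc, response = mu + eps)
}

#' Invertible affine response-to-RGB channel encoding
#'
#' Maps a scalar response y to an 8-bit RGB triple with fixed red and blue
#' channels so that the G/(R+B) color index recovers y exactly (up to
#' 8-bit quantization): `G = round((gain * y + offset) * (R + B))`. This is
#' a documented rendering convention for synthetic assay patches, not a
#' spectral model of the TNB chromophore.
#'
#' @param y_range numeric length-2, the response range that must be
#'   encodable; the affine map places it inside the index interval
#'   `[0.1, 1.2]` (G stays within 0-255 for R = B = 100).
#' @return object of class `channel_encoding` with fields `gain`, `offset`,
#'   `R`, `B`.
#' @export
channel_encoding <- function(y_range) {
  stopifnot(length(y_range) == 2, all(is.finite(y_range)))
  lo <- min(y_range); hi <- max(y_range)
  span <- hi - lo
  if (span == 0) span <- 1  # constant response: any gain works
  gain <- (1.2 - 0.1) / span
  structure(list(gain = gain, offset = 0.1 - gain * lo, R = 100, B = 100),
            class = "channel_encoding")
}

encode_rgb <- function(enc, y) {
  stopifnot(inherits(enc, "channel_encoding"))
  g <- round((enc$gain * y + enc$offset) * (enc$R + enc$B))
  bad <- which(g < 0 | g > 255)
  if (length(bad))
    abort(sprintf("response in row %d (y = %.4g) falls outside the encodable range",
                  bad[1], y[bad[1]]))
  cbind(R = rep(enc$R, length(y)), G = g, B = rep(enc$B, length(y)))
}

#' Decode a response from an encoded RGB triple
#'
#' Inverts [channel_encoding()] through the G/(R+B) index.
#'
#' @param enc a `channel_encoding`.
#' @param triple RGB triple (named or positional R, G, B on the 0-255 scale).
#' @return the decoded response value.
#' @export
decode_response <- function(enc, triple) {
  stopifnot(inherits(enc, "channel_encoding"))
  idx <- compute_index(rgb_triple(triple[[1]], triple[[2]], triple[[3]]),
                       "G_over_RplusB")
  (idx - enc$offset) / enc$gain
}

#' Render a response table as solid-color assay patch images
#'
#' Writes one 8-bit RGB PNG per row, colored by the invertible channel
#' encoding, plus a `manifest.csv` linking filename to concentration —
#' emulating the fixed-geometry smartphone photographs of assay wells.
#'
#' @param responses data frame from [simulate_responses()].
#' @param dir output directory (created if needed).
#' @param patch_size patch side length in pixels.
#' @param encoding a [channel_encoding()]; default derived from the response
#'   range of `responses`.
#' @return invisibly, a list with the manifest data frame (`filename`,
#'   `concentration_ng_per_ml`), the encoding, and the manifest path.
#' @export
simulate_assay_images <- function(responses, dir, patch_size = 32,
                                  encoding = channel_encoding(range(responses$response))) {
  stopifnot(is.data.frame(responses),
            all(c("concentration_ng_per_ml", "response") %in% names(responses)),
            patch_size >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rgb <- encode_rgb(encoding, responses$response)
  fns <- sprintf("patch_%03d.png", seq_len(nrow(responses)))
  for (i in seq_len(nrow(responses))) {
    img <- array(rep(rgb[i, ] / 255, each = patch_size^2),
                 dim = c(patch_size, patch_size, 3))
    png::writePNG(img, file.path(dir, fns[i]))
  }
  manifest <- data.frame(filename = fns,
                         concentration_ng_per_ml = responses$concentration_ng_per_ml)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(list(manifest = manifest, encoding = encoding, manifest_path = mpath))
}

#' Simulate Ellman-assay absorbance triples under dose-dependent inhibition
#'
#' For each concentration c the inhibited absorbance follows a Hill
#' logistic between the uninhibited signal A and the blank baseline A0:
#' \deqn{A_1(c) = A_0 + (A - A_0) / (1 + (c/IC_{50})^{h}) + \epsilon}
#' so that the noiseless inhibition efficiency
#' \eqn{IE\% = (A - A_1)/(A - A_0) \times 100} equals the logistic
#' inhibition fraction (50% at c = IC50). The paper's assay gives no
#' functional form for the dose-response; the Hill model with IC50 = 5
#' ng/mL and slope 1 spans the 0.05-500 ng/mL working range.
#'
#' @param c_list concentrations in ng/mL (0 allowed: no inhibitor).
#' @param IC50 half-inhibition concentration, ng/mL, > 0.
#' @param hill Hill slope (dimensionless, > 0).
#' @param A uninhibited absorbance at 412 nm; must exceed `A0`.
#' @param A0 blank baseline absorbance.
#' @param noise_sd additive Gaussian noise on A1 (absorbance units).
#' @param seed integer RNG seed.
#' @return data frame with columns `c_ng_per_ml`, `A`, `A0`, `A1`.
#' @export
simulate_absorbance <- function(c_list, IC50 = 5, hill = 1,
                                A = 1.0, A0 = 0.1, noise_sd = 0, seed = 1L) {
  if (A <= A0) abort("A must exceed A0 (degenerate dynamic range)")
  if (IC50 <= 0) abort("IC50 must be positive")
  stopifnot(all(c_list >= 0), hill > 0, noise_sd >= 0)
  frac <- ifelse(c_list == 0, 0, 1 / (1 + (c_list / IC50)^(-hill)))
  a1 <- A0 + (A - A0) * (1 - frac)
  a1 <- a1 + local_seed(seed, stats::rnorm(length(c_list), 0, noise_sd))
  data.frame(c_ng_per_ml = c_list, A = A, A0 = A0, A1 = a1)
}

#' Default substrate grid for Michaelis-Menten simulation
#'
#' Ten points log-spaced from 0.2 Km to 20 Km; spanning well below and
#' well above half-saturation keeps both Km and Vmax identifiable.
#'
#' @param Km half-saturation constant, mmol/L.
#' @param n number of grid points.
#' @return substrate concentrations in mmol/L.
#' @export
default_substrate_grid <- function(Km, n = 10) {
  stopifnot(Km > 0, n >= 2)
  10^seq(log10(0.2 * Km), log10(20 * Km), length.out = n)
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' \eqn{v_i = V_{max} S_i / (K_m + S_i) + \epsilon_i}.
#'
#' @param Km half-saturation constant, mmol/L (> 0).
#' @param Vmax maximal rate (> 0, arbitrary rate units).
#' @param S_grid substrate concentrations, mmol/L, all positive.
#' @param noise_sd additive Gaussian rate noise.
#' @param seed integer RNG seed.
#' @param label sample name carried through to the fit.
#' @return data frame of class `kinetics_dataset` with columns
#'   `substrate_mmol_per_L`, `rate` and attribute `label`.
#' @export
simulate_mm_kinetics <- function(Km, Vmax = 1, S_grid = default_substrate_grid(Km),
                                 noise_sd = 0, seed = 1L, label = "sample") {
  if (length(S_grid) == 0) abort("S_grid must be nonempty")
  stopifnot(Km > 0, Vmax > 0, all(S_grid > 0), noise_sd >= 0)
  v <- mm_rate(S_grid, Km, Vmax) +
    local_seed(seed, stats::rnorm(length(S_grid), 0, noise_sd))
  d <- data.frame(substrate_mmol_per_L = as.numeric(S_grid), rate = v)
  attr(d, "label") <- label
  class(d) <- c("kinetics_dataset", class(d))
  d
}

#' Configuration for a clustered particle point field
#'
#' Describes a 2-D field of `n_particles` clusters of junction points.
#' Within a particle, points sit on a square lattice with spacing
#' `intra_spacing`; particle centroids sit on a coarse grid at least
#' `inter_particle_distance` apart, which must exceed 3x the intra
#' spacing so that spurious inter-particle Delaunay edges are separable
#' from genuine intra-particle ones.
#'
#' @param n_particles number of particles (>= 1).
#' @param points_per_particle junction points per particle (>= 1).
#' @param intra_spacing lattice spacing within a particle, px.
#' @param inter_particle_distance centroid-to-centroid spacing, px.
#' @param jitter_sd Gaussian positional jitter per coordinate, px.
#' @param seed integer RNG seed.
#' @return object of class `particle_field_config`.
#' @export
particle_field_config <- function(n_particles = 4, points_per_particle = 16,
                                  intra_spacing = 5, inter_particle_distance = 100,
                                  jitter_sd = 0, seed = 1L) {
  if (n_particles < 1 || points_per_particle < 1)
    abort("counts must be >= 1")
  if (intra_spacing <= 0 || inter_particle_distance <= 0 || jitter_sd < 0)
    abort("spacings must be positive and jitter_sd >= 0")
  if (inter_particle_distance / intra_spacing <= 3)
    abort("inter_particle_distance must exceed 3x intra_spacing")
  structure(
    list(n_particles = as.integer(n_particles),
         points_per_particle = as.integer(points_per_particle),
         intra_spacing = intra_spacing,
         inter_particle_distance = inter_particle_distance,
         jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "particle_field_config"
  )
}

#' Simulate a clustered 2-D junction-point field
#'
#' Generates the failure mode that motivates confidence-threshold edge
#' pruning: tight intra-particle point lattices joined by long spurious
#' inter-particle Delaunay edges. Particle labels are recorded as ground
#' truth so pruning can be validated edge by edge.
#'
#' @param config a [particle_field_config()].
#' @return data frame with columns `x_px`, `y_px`, `particle_id`.
#' @export
simulate_particle_pointset <- function(config) {
  stopifnot(inherits(config, "particle_field_config"))
  k <- config$points_per_particle
  side <- ceiling(sqrt(k))
  # intra-particle square lattice, centered on the particle centroid
  gx <- (seq_len(side) - (side + 1) / 2) * config$intra_spacing
  lattice <- expand.grid(x = gx, y = gx)[seq_len(k), , drop = FALSE]
  ncol_grid <- ceiling(sqrt(config$n_particles))
  cx <- ((seq_len(config$n_particles) - 1) %% ncol_grid) * config$inter_particle_distance
  cy <- ((seq_len(config$n_particles) - 1) %/% ncol_grid) * config$inter_particle_distance
  pts <- local_seed(config$seed, {
    do.call(rbind, lapply(seq_len(config$n_particles), function(p) {
      jx <- stats::rnorm(k, 0, config$jitter_sd)
      jy <- stats::rnorm(k, 0, config$jitter_sd)
      data.frame(x_px = cx[p] + lattice$x + jx,
                 y_px = cy[p] + lattice$y + jy,
                 particle_id = p)
    }))
  })
  rownames(pts) <- NULL
  pts
}
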