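#' A single color observation
#'
#' One RGB triple on the 0-255 scale, typically the per-channel arithmetic
#' mean over an image region of interest. Fractional values are allowed
#' (means are never rounded before index computation, to avoid quantization
#' bias in calibration).
#'
#' @param R,G,B channel intensities in [0, 255].
#' @return named numeric vector of class `rgb_triple`.
#' @export
rgb_triple <- function(R, G, B) {
  v <- c(R = as.numeric(R), G = as.numeric(G), B = as.numeric(B))
  if (any(!is.finite(v)) || any(v < 0) || any(v > 255))
    abort("RGB channels must be finite and within [0, 255]")
  structure(v, class = "rgb_triple")
}

#' Read an assay image as an 8-bit RGB array
#'
#' Reads a PNG or TIFF and returns an H x W x 3 numeric array on the
#' 0-255 scale. 16-bit samples are mapped to 8-bit by integer division by
#' 257 (65535 -> 255). An alpha channel is dropped; single-channel
#' (grayscale) input is an error, since the color indices need all three
#' channels.
#'
#' @param path path to a PNG or TIFF file.
#' @return H x W x 3 numeric array, values in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- 8L  # readPNG rescales to [0,1]; detect 16-bit by step size
    if (length(dim(raw)) == 3 && any(abs(raw * 255 - round(raw * 255)) > 1e-9))
      bits <- 16L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    abort(sprintf("unsupported image format: .%s (PNG/TIFF expected)", ext))
  }
  if (length(dim(raw)) < 3 || dim(raw)[3] < 3)
    abort("single-channel image: three-channel RGB input required")
  raw <- raw[, , 1:3, drop = FALSE]  # drop alpha if present
  if (bits >= 16L) {
    v <- round(raw * 65535) %/% 257
  } else {
    v <- round(raw * 255)
  }
  array(as.numeric(v), dim = dim(raw))
}

# validate a 0-based half-open ROI c(x0, y0, x1, y1) against image dims
check_roi <- function(image, roi) {
  stopifnot(length(dim(image)) == 3)
  if (length(roi) != 4) abort("roi must be c(x0, y0, x1, y1)")
  h <- dim(image)[1]; w <- dim(image)[2]
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x0 >= x1 || y0 >= y1) abort("roi has zero or negative area")
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h)
    abort(sprintf("roi [%g,%g)x[%g,%g) outside %dx%d image", x0, x1, y0, y1, w, h))
  list(rows = (y0 + 1):y1, cols = (x0 + 1):x1)
}

#' Mean RGB over a rectangular region of interest
#'
#' ROI rectangles are 0-based and half-open, `[x0, x1) x [y0, y1)`, in
#' pixel coordinates (x = column, y = row).
#'
#' @param image H x W x 3 array from [read_image()].
#' @param roi numeric `c(x0, y0, x1, y1)`.
#' @return an [rgb_triple()] of per-channel arithmetic means (fractional).
#' @export
extract_roi_mean_rgb <- function(image, roi) {
  sel <- check_roi(image, roi)
  sub <- image[sel$rows, sel$cols, , drop = FALSE]
  rgb_triple(mean(sub[, , 1]), mean(sub[, , 2]), mean(sub[, , 3]))
}

# catalog of color-index algorithms: each maps channel arrays/scalars to a
# scalar (or per-pixel matrix). Ratio denominators of exactly zero yield NA
# here; scalar entry points turn that into a hard error.
index_formulas <- list(
  R             = function(R, G, B) R,
  G             = function(R, G, B) G,
  B             = function(R, G, B) B,
  R_plus_G_plus_B = function(R, G, B) R + G + B,
  G_over_RplusB = function(R, G, B) ifelse(R + B == 0, NA_real_, G / (R + B)),
  R_over_GplusB = function(R, G, B) ifelse(G + B == 0, NA_real_, R / (G + B)),
  B_over_RplusG = function(R, G, B) ifelse(R + G == 0, NA_real_, B / (R + G)),
  gray          = function(R, G, B) 0.299 * R + 0.587 * G + 0.114 * B,
  H             = function(R, G, B) hsv_channel(R, G, B, 1L),
  S             = function(R, G, B) hsv_channel(R, G, B, 2L),
  V             = function(R, G, B) hsv_channel(R, G, B, 3L)
)

hsv_channel <- function(R, G, B, which) {
  hsv <- grDevices::rgb2hsv(rbind(c(R), c(G), c(B)), maxColorValue = 255)
  out <- hsv[which, ]
  if (which == 1L) out <- out * 360  # hue in degrees [0, 360)
  if (length(R) > 1 || is.matrix(R)) dim(out) <- dim(R)
  out
}

#' Names of the available color-index algorithms
#' @return character vector of algorithm ids.
#' @export
index_catalog <- function() names(index_formulas)

#' Compute a color index from an RGB triple
#'
#' Applies one of the cataloged color-index algorithms (single channels,
#' channel sums and ratios, BT.601 grayscale, HSV components) to a triple.
#' Grayscale uses the BT.601 luma weights (0.299, 0.587, 0.114). Ratio
#' indices with an exactly zero denominator raise an error: a zero R+B
#' patch indicates broken acquisition, and silently padding the
#' denominator would distort calibration.
#'
#' @param t an [rgb_triple()] (or coercible length-3 vector).
#' @param alg algorithm id, one of [index_catalog()].
#' @return scalar index value.
#' @export
#' @examples
#' compute_index(rgb_triple(100, 100, 100), "G_over_RplusB")  # 0.5
compute_index <- function(t, alg) {
  if (!inherits(t, "rgb_triple")) t <- rgb_triple(t[[1]], t[[2]], t[[3]])
  f <- index_formulas[[alg]]
  if (is.null(f)) abort(sprintf("unknown algorithm id: %s", alg))
  v <- f(t[["R"]], t[["G"]], t[["B"]])
  if (is.na(v)) abort(sprintf("zero denominator for index %s on triple (%g, %g, %g)",
                              alg, t[["R"]], t[["G"]], t[["B"]]))
  unname(v)
}

#' Convert an RGB triple to HSV
#'
#' Standard hexcone conversion. Hue is reported in degrees [0, 360);
#' saturation and value in [0, 1]. Achromatic input (R = G = B) has S = 0
#' and H defined as 0.
#'
#' @param t an [rgb_triple()].
#' @return named numeric `c(H, S, V)`.
#' @export
rgb_to_hsv_triple <- function(t) {
  if (!inherits(t, "rgb_triple")) t <- rgb_triple(t[[1]], t[[2]], t[[3]])
  hsv <- grDevices::rgb2hsv(t[["R"]], t[["G"]], t[["B"]], maxColorValue = 255)
  c(H = hsv[1] * 360, S = hsv[2], V = hsv[3])
}

#' Per-pixel color-index (difference) map with pseudo-color rendering
#'
#' Evaluates a cataloged index at every pixel, optionally subtracting the
#' index of a reference triple (a color difference map), and renders the
#' finite values through a linear viridis colormap. Pixels whose index is
#' undefined (zero ratio denominator) are masked (NA in `values`, black in
#' the rendering).
#'
#' @param image H x W x 3 array from [read_image()].
#' @param alg algorithm id from [index_catalog()].
#' @param reference optional [rgb_triple()]; its index is subtracted
#'   pixelwise.
#' @return list with `values` (H x W numeric matrix, NA where masked) and
#'   `rendered` (H x W x 3 array in [0, 1], writable with [png::writePNG()]).
#' @export
pseudo_color_map <- function(image, alg, reference = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  f <- index_formulas[[alg]]
  if (is.null(f)) abort(sprintf("unknown algorithm id: %s", alg))
  vals <- f(image[, , 1], image[, , 2], image[, , 3])
  vals <- matrix(vals, nrow = dim(image)[1])
  if (!is.null(reference))
    vals <- vals - compute_index(reference, alg)
  vals[!is.finite(vals)] <- NA_real_
  if (all(is.na(vals))) abort("all pixels masked: index undefined everywhere")
  rng <- range(vals, na.rm = TRUE)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))) / 255
  idx <- if (diff(rng) == 0) rep(1L, length(vals)) else
    pmin(256L, 1L + as.integer(floor((vals - rng[1]) / diff(rng) * 255.999)))
  rendered <- array(0, dim = c(dim(vals), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(vals), ncol(vals))
    plane[ok] <- pal[idx[ok], ch]
    rendered[, , ch] <- plane
  }
  list(values = vals, rendered = rendered)
}

#' Extract color indices from a set of assay images
#'
#' Reads every image in a manifest, takes the ROI-mean RGB, and computes
#' the requested color indices — the digitization step linking smartphone
#' photographs to calibratable responses. Indices are computed on the
#' ROI-mean channels (not averaged per-pixel indices), which is robust to
#' pixel noise.
#'
#' @param dir directory containing the images.
#' @param manifest data frame with `filename`, `concentration_ng_per_ml`
#'   (or path to such a CSV).
#' @param roi `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param algorithms character vector of ids from [index_catalog()].
#' @return data frame: `filename`, `concentration_ng_per_ml`, `R`, `G`,
#'   `B`, then one column per requested index.
#' @export
extract_indices <- function(dir, manifest, roi,
                            algorithms = "G_over_RplusB") {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("filename", "concentration_ng_per_ml") %in% names(manifest)))
  bad <- setdiff(algorithms, index_catalog())
  if (length(bad)) abort(sprintf("unknown algorithm id: %s", bad[1]))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(file.path(dir, manifest$filename[i]))
    t <- extract_roi_mean_rgb(img, roi)
    idx <- vapply(algorithms, function(a) compute_index(t, a), numeric(1))
    cbind(data.frame(filename = manifest$filename[i],
                     concentration_ng_per_ml = manifest$concentration_ng_per_ml[i],
                     R = t[["R"]], G = t[["G"]], B = t[["B"]]),
          as.data.frame(as.list(idx)))
  })
  do.call(rbind, rows)
}
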