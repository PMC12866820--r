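#' A 2-D junction-point set
#'
#' Validated container for the point coordinates feeding the spacing
#' statistic. Duplicate coordinates are rejected outright: they would
#' create zero-length Delaunay edges and poison the normal fit used for
#' pruning.
#'
#' @param x,y pixel coordinates (0-based convention), equal length >= 3.
#' @param particle_id optional integer ground-truth labels.
#' @param source optional image/sample identifier.
#' @return object of class `point_set` (a data frame `x_px`, `y_px`
#'   and optionally `particle_id`).
#' @export
point_set <- function(x, y, particle_id = NULL, source = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3) abort("at least 3 points required for triangulation")
  if (anyDuplicated(cbind(x, y))) abort("duplicate coordinates not allowed")
  d <- data.frame(x_px = as.numeric(x), y_px = as.numeric(y))
  if (!is.null(particle_id)) d$particle_id <- particle_id
  attr(d, "source") <- source
  class(d) <- c("point_set", class(d))
  d
}

as_point_set <- function(ps) {
  if (inherits(ps, "point_set")) return(ps)
  stopifnot(is.data.frame(ps), all(c("x_px", "y_px") %in% names(ps)))
  point_set(ps$x_px, ps$y_px, ps$particle_id)
}

#' Read a point set from CSV
#'
#' Expects columns `x_px`, `y_px` and optionally `particle_id`.
#'
#' @param path CSV path.
#' @return a [point_set()].
#' @export
read_point_set_csv <- function(path) {
  as_point_set(utils::read.csv(path))
}

#' Delaunay triangulation of a point set
#'
#' Triangulates the points so that no input point lies inside any
#' triangle's circumcircle, yielding the non-overlapping triangular mesh
#' whose edge lengths serve as inter-point distances. Cocircular
#' degeneracies (e.g. the four corners of a square) admit either diagonal.
#'
#' @param ps a [point_set()] (or data frame with `x_px`, `y_px`).
#' @return object of class `edge_set`: a list with `edges` (data frame
#'   `i`, `j`, `length`, `pruned`), `triangles` (matrix of vertex-index
#'   triples) and the originating `points`.
#' @export
delaunay_triangulate <- function(ps) {
  ps <- as_point_set(ps)
  x <- ps$x_px; y <- ps$y_px
  # collinearity guard: all cross products relative to the first segment zero
  cross <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  if (all(abs(cross) < 1e-9 * max(1, diff(range(x)), diff(range(y)))))
    abort("all points collinear: triangulation undefined")
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tri <- tryCatch(deldir::triMat(dd), error = function(e) NULL)
  if (is.null(tri) || nrow(dd$delsgs) == 0)
    abort("all points collinear: triangulation undefined")
  if (!is.matrix(tri)) tri <- matrix(tri, nrow = 1)  # single triangle
  i <- pmin(dd$delsgs$ind1, dd$delsgs$ind2)
  j <- pmax(dd$delsgs$ind1, dd$delsgs$ind2)
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  structure(
    list(edges = data.frame(i = i, j = j,
                            length = sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2),
                            pruned = FALSE),
         triangles = tri,
         points = ps,
         threshold = NA_real_),
    class = "edge_set"
  )
}

#' Edge lengths of a triangulation
#'
#' @param es an `edge_set` from [delaunay_triangulate()].
#' @return numeric vector, one Euclidean length per unique edge.
#' @export
edge_lengths <- function(es) {
  stopifnot(inherits(es, "edge_set"))
  if (nrow(es$edges) == 0) abort("empty edge set")
  es$edges$length
}

#' Prune spurious long edges by a normal confidence threshold
#'
#' When a field contains many discrete particles, Delaunay triangulation
#' bridges them with erroneous long inter-particle edges. This single-pass
#' correction fits a normal distribution to all edge lengths (sample mean,
#' n-1 sd) and flags as pruned every edge longer than the upper bound of
#' the central 95% interval of that fitted normal,
#' \eqn{\mu + z_{0.975}\,\sigma} (z = 1.959964). The threshold is computed
#' once on all edges and applied once; no iteration.
#'
#' `method = "mean_ci"` instead uses the confidence interval of the mean,
#' \eqn{\mu + z\,\sigma/\sqrt{n}}. This alternative reading shrinks with
#' the number of edges and on large meshes prunes far more than the
#' spurious connections, so the quantile reading is the default.
#'
#' @param es an `edge_set` with at least 2 edges.
#' @param confidence central coverage of the fitted normal (default 0.95).
#' @param method `"quantile"` (default) or `"mean_ci"`.
#' @return the `edge_set` with `pruned` flags set and `threshold` recorded.
#' @export
prune_edges_ci <- function(es, confidence = 0.95,
                           method = c("quantile", "mean_ci")) {
  stopifnot(inherits(es, "edge_set"), confidence > 0, confidence < 1)
  method <- match.arg(method)
  len <- es$edges$length
  if (length(len) < 2) abort("at least 2 edges required to estimate spread")
  mu <- mean(len)
  sigma <- stats::sd(len)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  thr <- if (method == "quantile") mu + z * sigma else mu + z * sigma / sqrt(length(len))
  es$edges$pruned <- len > thr
  es$threshold <- thr
  es
}

#' Mean point spacing of the kept edges
#'
#' The porosity statistic: the arithmetic mean length of the edges that
#' survive pruning. Shorter mean spacing is read as a denser junction
#' field, i.e. higher framework porosity.
#'
#' @param es a (typically pruned) `edge_set` with at least one kept edge.
#' @return object of class `spacing_stat`: `mean_spacing`,
#'   `n_edges_kept`, `n_edges_pruned`, `threshold`.
#' @export
mean_point_spacing <- function(es) {
  stopifnot(inherits(es, "edge_set"))
  kept <- es$edges$length[!es$edges$pruned]
  # single-pass upper pruning with >= 2 edges always keeps the minimum edge
  if (length(kept) == 0) abort("all edges pruned: spacing undefined")
  structure(
    list(mean_spacing = mean(kept),
         n_edges_kept = length(kept),
         n_edges_pruned = sum(es$edges$pruned),
         threshold = es$threshold),
    class = "spacing_stat"
  )
}

#' @export
print.spacing_stat <- function(x, ...) {
  cat(sprintf("Mean point spacing: %.4f px (%d edges kept, %d pruned, threshold %.4f px)\n",
              x$mean_spacing, x$n_edges_kept, x$n_edges_pruned, x$threshold))
  invisible(x)
}

#' Detect junction points as local intensity maxima
#'
#' Converts the image to BT.601 grayscale and reports pixels that are
#' strict 8-neighborhood maxima with intensity at least `threshold_rel`
#' times the global maximum, greedily enforcing a minimum pairwise
#' separation (brightest first). This is a deliberately simple surrogate
#' for the manual/ImageJ junction marking used on SEM micrographs.
#'
#' @param image H x W x 3 array (or H x W matrix) of intensities.
#' @param min_distance minimum separation between reported points, px.
#' @param threshold_rel minimum intensity relative to the global maximum,
#'   in (0, 1].
#' @return a [point_set()] of detected (x, y) pixel coordinates (0-based).
#' @export
detect_junction_points <- function(image, min_distance = 10, threshold_rel = 0.3) {
  g <- if (length(dim(image)) == 3)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else as.matrix(image)
  h <- nrow(g); w <- ncol(g)
  if (h < 3 || w < 3) abort("image too small for maxima detection")
  core <- g[2:(h - 1), 2:(w - 1)]
  nb <- array(NA_real_, dim = c(h - 2, w - 2, 8))
  k <- 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    k <- k + 1
    nb[, , k] <- g[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
  }
  is_max <- core > apply(nb, c(1, 2), max)
  is_max <- is_max & core >= threshold_rel * max(g)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0)
    abort("fewer than 3 junction points detected; lower threshold_rel or min_distance")
  ord <- order(core[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, ]
    if (nrow(keep) == 0 ||
        all((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 >= min_distance^2))
      keep <- rbind(keep, p)
  }
  if (nrow(keep) < 3)
    abort("fewer than 3 junction points detected; lower threshold_rel or min_distance")
  # arr.ind row/col are 1-based into the (h-2)x(w-2) core; convert to
  # 0-based full-image pixel coordinates (x = column, y = row)
  point_set(x = keep[, 2], y = keep[, 1])
}

#' Write a triangulation's edges to CSV
#'
#' Columns `i`, `j` (1-based point indices), `length_px`, `pruned`.
#'
#' @param es an `edge_set`.
#' @param path CSV path.
#' @export
write_edges_csv <- function(es, path) {
  stopifnot(inherits(es, "edge_set"))
  out <- es$edges
  names(out) <- c("i", "j", "length_px", "pruned")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a spacing statistic to JSON
#'
#' @param stat a `spacing_stat`.
#' @param path output path.
#' @export
write_spacing_json <- function(stat, path) {
  stopifnot(inherits(stat, "spacing_stat"))
  jsonlite::write_json(
    list(mean_spacing = stat$mean_spacing, threshold = stat$threshold,
         n_kept = stat$n_edges_kept, n_pruned = stat$n_edges_pruned),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
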