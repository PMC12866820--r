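# Independent brute-force oracles used across the suite.

# Circumcenter and squared circumradius of a point triple; NULL if collinear.
circumcircle <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
              p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((sum(p1^2)) * (p2[2] - p3[2]) + (sum(p2^2)) * (p3[2] - p1[2]) +
           (sum(p3^2)) * (p1[2] - p2[2])) / d
  uy <- ((sum(p1^2)) * (p3[1] - p2[1]) + (sum(p2^2)) * (p1[1] - p3[1]) +
           (sum(p3^2)) * (p2[1] - p1[1])) / d
  list(center = c(ux, uy), r2 = sum((p1 - c(ux, uy))^2))
}

# O(n^4) Delaunay construction: every triple whose open circumcircle
# contains no other input point is a Delaunay triangle; return its edges
# as a sorted two-column matrix of index pairs.
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcircle(c(x[i], y[i]), c(x[j], y[j]), c(x[k], y[k]))
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - cc$center[1])^2 + (y[others] - cc$center[2])^2
    if (all(d2 > cc$r2 * (1 - 1e-9)))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Naive per-pixel loop ROI mean (0-based half-open rectangle).
brute_roi_mean <- function(image, roi) {
  acc <- c(0, 0, 0); npx <- 0
  for (yy in (roi[2] + 1):roi[4]) for (xx in (roi[1] + 1):roi[3]) {
    acc <- acc + image[yy, xx, ]
    npx <- npx + 1
  }
  acc / npx
}

# Planted-spot micrograph: Gaussian bumps at given (x, y) centers (0-based).
make_spot_image <- function(centers, h = 80, w = 80, sigma = 2) {
  g <- matrix(0, h, w)
  for (r in seq_len(nrow(centers))) {
    cx <- centers[r, 1]; cy <- centers[r, 2]
    for (yy in 1:h) for (xx in 1:w)
      g[yy, xx] <- g[yy, xx] +
        exp(-(((xx - 1) - cx)^2 + ((yy - 1) - cy)^2) / (2 * sigma^2))
  }
  array(rep(g / max(g) * 255, 3), dim = c(h, w, 3))
}

# Minimal edge_set wrapper around a bare length vector, for exercising the
# pruning arithmetic independently of any triangulation.
edge_set_from_lengths <- function(len) {
  structure(list(edges = data.frame(i = seq_along(len), j = seq_along(len) + 1L,
                                    length = len, pruned = FALSE),
                 triangles = NULL, points = NULL, threshold = NA_real_),
            class = "edge_set")
}

# Classify triangulation edges as inter-particle using ground-truth labels.
is_inter_edge <- function(es, labels) {
  labels[es$edges$i] != labels[es$edges$j]
}
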