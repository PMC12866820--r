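test_that("small triangulations have the expected mesh structure", {
  tri <- delaunay_triangulate(point_set(c(0, 4, 2), c(0, 0, 3)))
  expect_equal(nrow(tri$edges), 3)
  expect_equal(nrow(tri$triangles), 1)

  sq <- delaunay_triangulate(point_set(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  expect_equal(nrow(sq$edges), 5)  # 4 sides + one diagonal (cocircular tie)
  expect_equal(sort(edge_lengths(sq)), c(1, 1, 1, 1, sqrt(2)))

  expect_error(delaunay_triangulate(point_set(c(0, 1, 2), c(0, 1, 2))),
               "collinear")
  expect_error(point_set(c(0, 1), c(0, 1)), "3 points")
  expect_error(point_set(c(0, 0, 1), c(2, 2, 3)), "duplicate")
})

test_that("triangulation agrees with the brute-force empty-circumcircle oracle", {
  for (seed in c(2, 9, 31)) {
    set.seed(seed)
    n <- sample(6:12, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    es <- delaunay_triangulate(point_set(x, y))
    got <- as.matrix(es$edges[, c("i", "j")])
    dimnames(got) <- NULL
    expect_equal(got, brute_delaunay_edges(x, y),
                 label = sprintf("oracle equivalence, seed %d", seed))
  }
})

test_that("edge lengths match the pairwise-distance oracle", {
  set.seed(4)
  x <- runif(10); y <- runif(10)
  es <- delaunay_triangulate(point_set(x, y))
  oracle <- sqrt((x[es$edges$i] - x[es$edges$j])^2 +
                   (y[es$edges$i] - y[es$edges$j])^2)
  expect_equal(edge_lengths(es), oracle)
})

test_that("normal-CI pruning removes only the spurious long edge", {
  es <- edge_set_from_lengths(c(rep(1, 20), 10))
  pr <- prune_edges_ci(es)
  # direct computation: mu = 30/21, sd = sqrt(sum((l-mu)^2)/20)
  mu <- 30 / 21
  sigma <- sqrt(sum((c(rep(1, 20), 10) - mu)^2) / 20)
  expect_equal(pr$threshold, mu + qnorm(0.975) * sigma)
  expect_equal(pr$threshold, 5.2779, tolerance = 1e-4)
  expect_equal(which(pr$edges$pruned), 21L)

  same <- prune_edges_ci(edge_set_from_lengths(rep(2.5, 6)))
  expect_equal(same$threshold, 2.5)       # sigma = 0
  expect_false(any(same$edges$pruned))    # strict > keeps everything

  tight <- prune_edges_ci(edge_set_from_lengths(c(rep(1, 20), 10)),
                          method = "mean_ci")
  expect_lt(tight$threshold, pr$threshold)  # CI-of-mean variant shrinks
  expect_error(prune_edges_ci(edge_set_from_lengths(1)), "2 edges")
})

test_that("pruning separates inter-particle from intra-particle edges", {
  cfg <- particle_field_config(n_particles = 4, points_per_particle = 25,
                               intra_spacing = 5, inter_particle_distance = 200,
                               jitter_sd = 0, seed = 12)
  ps <- simulate_particle_pointset(cfg)
  es <- prune_edges_ci(delaunay_triangulate(ps))
  inter <- is_inter_edge(es, ps$particle_id)
  expect_true(all(es$edges$pruned[inter]))    # 100% recall of spurious edges
  expect_false(any(es$edges$pruned[!inter]))  # 0% false-prune of genuine edges

  stat <- mean_point_spacing(es)
  expect_equal(stat$n_edges_kept + stat$n_edges_pruned, nrow(es$edges))
  expect_lte(stat$mean_spacing, stat$threshold)
})

test_that("the spacing statistic is scale-equivariant and rigid-motion invariant", {
  set.seed(8)
  x <- runif(25, 0, 50); y <- runif(25, 0, 50)
  base <- mean_point_spacing(prune_edges_ci(delaunay_triangulate(point_set(x, y))))

  k <- 3.7
  scaled <- mean_point_spacing(
    prune_edges_ci(delaunay_triangulate(point_set(k * x, k * y))))
  expect_equal(scaled$mean_spacing, k * base$mean_spacing)
  expect_equal(scaled$threshold, k * base$threshold)

  th <- 0.6
  xr <- cos(th) * x - sin(th) * y + 12
  yr <- sin(th) * x + cos(th) * y - 5
  rot <- mean_point_spacing(
    prune_edges_ci(delaunay_triangulate(point_set(xr, yr))))
  expect_equal(rot$mean_spacing, base$mean_spacing, tolerance = 1e-9)
  expect_equal(rot$threshold, base$threshold, tolerance = 1e-9)
})

test_that("mean spacing reproduces closed-form values and tracks density", {
  eq <- delaunay_triangulate(point_set(c(0, 2, 1), c(0, 0, sqrt(3))))
  expect_equal(mean_point_spacing(prune_edges_ci(eq))$mean_spacing, 2)

  sq <- delaunay_triangulate(point_set(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  sq$threshold <- Inf  # unpruned mean of the 5 edges
  expect_equal(mean_point_spacing(sq)$mean_spacing, (4 + sqrt(2)) / 5)

  spacing_at <- function(s) {
    cfg <- particle_field_config(n_particles = 1, points_per_particle = 9,
                                 intra_spacing = s,
                                 inter_particle_distance = 10 * s, seed = 2)
    ps <- simulate_particle_pointset(cfg)
    mean_point_spacing(prune_edges_ci(delaunay_triangulate(ps)))$mean_spacing
  }
  expect_equal(spacing_at(2.5), spacing_at(5) / 2)  # denser field, shorter spacing
})

test_that("junction detection recovers planted spot centers", {
  centers <- cbind(x = c(15, 60, 30, 70, 45), y = c(20, 15, 55, 60, 35))
  img <- make_spot_image(centers)
  ps <- detect_junction_points(img, min_distance = 8, threshold_rel = 0.3)
  expect_equal(nrow(ps), 5)
  for (r in seq_len(5)) {
    d <- sqrt((ps$x_px - centers[r, 1])^2 + (ps$y_px - centers[r, 2])^2)
    expect_lt(min(d), 1.01)  # within 1 px of the planted center
  }
  uniform <- array(0.5, dim = c(20, 20, 3))
  expect_error(detect_junction_points(uniform), "fewer than 3")
})

test_that("point sets and spacing stats roundtrip through CSV/JSON", {
  cfg <- particle_field_config(seed = 3)
  ps <- simulate_particle_pointset(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ps, csv, row.names = FALSE)
  back <- read_point_set_csv(csv)
  expect_equal(back$x_px, ps$x_px)
  expect_equal(back$particle_id, ps$particle_id)

  es <- prune_edges_ci(delaunay_triangulate(back))
  ej <- withr::local_tempfile(fileext = ".csv")
  sj <- withr::local_tempfile(fileext = ".json")
  write_edges_csv(es, ej)
  write_spacing_json(mean_point_spacing(es), sj)
  edges <- utils::read.csv(ej)
  expect_equal(nrow(edges), nrow(es$edges))
  stats <- jsonlite::read_json(sj)
  expect_equal(stats$n_kept + stats$n_pruned, nrow(es$edges))
})
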