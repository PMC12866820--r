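solid_png <- function(rgb, h = 10, w = 10) {
  path <- withr::local_tempfile(fileext = ".png", .local_envir = parent.frame())
  png::writePNG(array(rep(rgb / 255, each = h * w), dim = c(h, w, 3)), path)
  path
}

test_that("read_image returns 0-255 RGB and rejects grayscale", {
  img <- read_image(solid_png(c(100, 150, 200)))
  expect_equal(dim(img), c(10, 10, 3))
  expect_true(all(img[, , 1] == 100 & img[, , 2] == 150 & img[, , 3] == 200))

  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), gray)
  expect_error(read_image(gray), "single-channel")
  expect_error(read_image("no_such_file.png"), "not found")
})

test_that("16-bit TIFF maps to 8-bit by integer division by 257", {
  v16 <- c(0L, 257L, 30000L, 65535L)
  path <- withr::local_tempfile(fileext = ".tif")
  arr <- array(rep(v16 / 65535, 3), dim = c(2, 2, 3))
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  img <- read_image(path)
  expect_equal(as.vector(img[, , 1]), v16 %/% 257L)  # direct oracle
  expect_equal(max(img), 255)
})

test_that("ROI mean matches the naive per-pixel loop", {
  img <- read_image(solid_png(c(10, 20, 30)))
  expect_equal(unclass(extract_roi_mean_rgb(img, c(2, 3, 7, 9))),
               c(R = 10, G = 20, B = 30))

  half <- array(0, dim = c(4, 4, 3))
  half[, 3:4, ] <- 200 / 255
  hp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(half, hp)
  expect_equal(unclass(extract_roi_mean_rgb(read_image(hp), c(0, 0, 4, 4))),
               c(R = 100, G = 100, B = 100))

  set.seed(11)
  rnd <- array(sample(0:255, 12 * 9 * 3, replace = TRUE) / 255,
               dim = c(9, 12, 3))
  rp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rnd, rp)
  rimg <- read_image(rp)
  roi <- c(1, 2, 10, 8)
  expect_equal(unname(unclass(extract_roi_mean_rgb(rimg, roi))),
               brute_roi_mean(rimg, roi))

  expect_error(extract_roi_mean_rgb(rimg, c(0, 0, 20, 5)), "outside")
  expect_error(extract_roi_mean_rgb(rimg, c(3, 3, 3, 5)), "area")
})

test_that("color-index catalog matches its documented formulas", {
  expect_setequal(
    c("R", "G", "B", "R_plus_G_plus_B", "G_over_RplusB", "R_over_GplusB",
      "B_over_RplusG", "gray", "H", "S", "V"),
    index_catalog())
  t1 <- rgb_triple(100, 100, 100)
  expect_equal(compute_index(t1, "G_over_RplusB"), 0.5)
  expect_equal(compute_index(rgb_triple(50, 200, 150), "G_over_RplusB"), 1.0)
  expect_equal(compute_index(t1, "gray"), 100)  # BT.601 weights sum to 1
  expect_equal(compute_index(t1, "R_plus_G_plus_B"), 300)
  expect_equal(compute_index(rgb_triple(30, 60, 90), "gray"),
               0.299 * 30 + 0.587 * 60 + 0.114 * 90)
  expect_error(compute_index(rgb_triple(0, 50, 0), "G_over_RplusB"),
               "zero denominator")
  expect_error(compute_index(t1, "not_an_index"), "unknown algorithm")
  expect_error(rgb_triple(300, 0, 0), "255")
})

test_that("HSV conversion follows the hexcone model and roundtrips", {
  expect_equal(unname(rgb_to_hsv_triple(rgb_triple(255, 0, 0))), c(0, 1, 1))
  expect_equal(unname(rgb_to_hsv_triple(rgb_triple(0, 255, 0))), c(120, 1, 1))
  expect_equal(unname(rgb_to_hsv_triple(rgb_triple(100, 100, 100))),
               c(0, 0, 100 / 255))

  grid <- expand.grid(R = c(0, 40, 128, 255), G = c(0, 90, 200),
                      B = c(15, 128, 255))
  for (r in seq_len(nrow(grid))) {
    hsv <- rgb_to_hsv_triple(rgb_triple(grid$R[r], grid$G[r], grid$B[r]))
    back <- grDevices::col2rgb(grDevices::hsv(hsv[1] / 360, hsv[2], hsv[3]))
    expect_true(all(abs(back - unlist(grid[r, ])) <= 1),
                label = sprintf("hsv roundtrip at (%d,%d,%d)",
                                grid$R[r], grid$G[r], grid$B[r]))
  }
})

test_that("indices depend only on the ROI mean and scale as documented", {
  set.seed(5)
  img <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  perm <- sample(64)
  shuffled <- img
  for (ch in 1:3) shuffled[, , ch] <- matrix(img[, , ch][perm], 8, 8)
  roi <- c(0, 0, 8, 8)
  for (alg in index_catalog())
    expect_equal(compute_index(extract_roi_mean_rgb(img, roi), alg),
                 compute_index(extract_roi_mean_rgb(shuffled, roi), alg),
                 label = paste("pixel-permutation invariance of", alg))

  t0 <- rgb_triple(60, 120, 40)
  for (k in c(0.25, 0.5, 2)) {
    tk <- rgb_triple(60 * k, 120 * k, 40 * k)
    expect_equal(compute_index(tk, "G_over_RplusB"),
                 compute_index(t0, "G_over_RplusB"))
  }
})

test_that("pseudo-color maps evaluate the index per pixel", {
  solid <- array(rep(c(80, 160, 120) / 1, each = 16), dim = c(4, 4, 3))
  m <- pseudo_color_map(solid, "G_over_RplusB",
                        reference = rgb_triple(80, 160, 120))
  expect_true(all(m$values == 0))

  two <- solid; two[1:2, , 2] <- 200
  m2 <- pseudo_color_map(two, "G_over_RplusB")
  expect_length(unique(as.vector(m2$values)), 2)

  grad <- array(0, dim = c(3, 5, 3))
  grad[, , 1] <- 50; grad[, , 3] <- 30
  grad[, , 2] <- matrix(rep(seq(10, 250, length.out = 5), each = 3), 3, 5)
  mg <- pseudo_color_map(grad, "G_over_RplusB")
  expect_equal(mg$values, grad[, , 2] / 80)  # per-pixel formula oracle
  expect_equal(dim(mg$rendered), c(3, 5, 3))
  expect_true(all(mg$rendered >= 0 & mg$rendered <= 1))

  black <- array(0, dim = c(2, 2, 3))
  expect_error(pseudo_color_map(black, "G_over_RplusB"), "masked")
})

test_that("extract_indices digitizes a manifest of patch images", {
  tab <- simulate_responses(assay_sim_truth(noise_sd = 0))
  dir <- withr::local_tempdir()
  sim <- simulate_assay_images(tab, dir)
  out <- extract_indices(dir, sim$manifest, c(4, 4, 28, 28),
                         algorithms = c("G_over_RplusB", "gray"))
  expect_equal(nrow(out), 8)
  expect_true(all(c("R", "G", "B", "G_over_RplusB", "gray") %in% names(out)))
  expect_equal(out$G_over_RplusB, out$G / (out$R + out$B))
  expect_error(extract_indices(dir, sim$manifest, c(0, 0, 8, 8),
                               algorithms = "nope"), "unknown algorithm")
})
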