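# rasterized disk mask built directly from pixel-center geometry
disk_mask <- function(r, pad = 6L) {
  n <- 2L * (r + pad)
  cx <- n / 2; cy <- n / 2
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n)        # col centers
  ys <- matrix(rep(n - seq_len(n) + 0.5, times = n), n)   # row centers, y-up
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 < r^2), n)
}

test_that("binarize recovers a perfectly separable mask exactly", {
  mask <- disk_mask(40)
  img <- 255 - 255 * mask  # dark disk on white
  b <- binarize(img)
  expect_identical(b$mask, mask)
})

test_that("binarize fails on a constant image without threshold", {
  expect_error(binarize(matrix(128, 50, 50)), "segmentation failure")
  # but an explicit threshold works on a two-level image
  img <- matrix(200, 50, 50); img[20:30, 20:30] <- 50
  expect_equal(sum(binarize(img, threshold = 100)$mask), 11 * 11)
})

test_that("binarize tolerates gaussian noise at 99% pixel agreement", {
  fx <- generate_seed_image(fixture_spec("cardioid", resolution = 300,
                                         rng_seed = 3))
  truth <- binarize(fx$image)$mask
  set.seed(17)
  noisy <- fx$image + matrix(stats::rnorm(length(fx$image), 0, 10),
                             nrow(fx$image))
  got <- binarize(noisy)$mask
  expect_gte(mean(got == truth), 0.99)
})

test_that("a rasterized disk measures like a circle", {
  sils <- extract_silhouettes(disk_mask(100))
  expect_length(sils, 1L)
  s <- sils[[1]]
  expect_lt(abs(s$area - pi * 100^2) / (pi * 100^2), 0.01)
  expect_lt(abs(s$perimeter - 2 * pi * 100) / (2 * pi * 100), 0.02)
  expect_lt(abs(s$pixel_area - s$area) / s$area, 0.015)
  e <- fit_ellipse(s)
  expect_lt(abs(e$major_axis - e$minor_axis) / e$major_axis, 1e-3)
})

test_that("disjoint blobs are returned one silhouette each, in order", {
  # 5 x 5 grid of disks
  cellpx <- 48L
  cell <- disk_mask(16, pad = 8L)
  big <- matrix(0L, 5L * cellpx, 5L * cellpx)
  for (i in 0:4) for (j in 0:4)
    big[i * cellpx + seq_len(cellpx), j * cellpx + seq_len(cellpx)] <- cell
  sils <- extract_silhouettes(big)
  expect_length(sils, 25L)
  cx <- vapply(sils, function(s) s$centroid[1], 0)
  expect_true(!is.unsorted(cx))
  # determinism: identical input gives identical values
  again <- extract_silhouettes(big)
  expect_identical(lapply(sils, function(s) s$outline),
                   lapply(again, function(s) s$outline))
})

test_that("interior holes are filled before measurement", {
  ring <- disk_mask(60)
  hole <- disk_mask(25, pad = 41L)   # same canvas size, concentric
  mask <- ring * (1L - hole)
  s <- extract_silhouettes(mask)[[1]]
  expect_lt(abs(s$area - pi * 60^2) / (pi * 60^2), 0.01)
})

test_that("min_area_px filters specks and errors when nothing remains", {
  mask <- disk_mask(30)
  mask[2, 2] <- 1L  # a 1-px speck
  expect_length(extract_silhouettes(mask, min_area_px = 50), 1L)
  expect_error(extract_silhouettes(disk_mask(3), min_area_px = 1e5),
               "no component")
})

test_that("moment ellipse recovers axes and orientation of a raster ellipse", {
  ellipse_mask <- function(a, b, ang, n = 220L) {
    cx <- n / 2; cy <- n / 2
    xs <- matrix(rep(seq_len(n) - 0.5, each = n), n) - cx
    ys <- matrix(rep(n - seq_len(n) + 0.5, times = n), n) - cy
    u <- cos(ang) * xs + sin(ang) * ys
    v <- -sin(ang) * xs + cos(ang) * ys
    matrix(as.integer(u^2 / a^2 + v^2 / b^2 < 1), n)
  }
  s <- extract_silhouettes(ellipse_mask(80, 40, 0))[[1]]
  e <- fit_ellipse(s)
  expect_lt(abs(e$major_axis - 160) / 160, 0.01)
  expect_lt(abs(e$minor_axis - 80) / 80, 0.01)
  s30 <- extract_silhouettes(ellipse_mask(80, 40, pi / 6))[[1]]
  e30 <- fit_ellipse(s30)
  expect_lt(abs(e30$orientation - pi / 6), pi / 180)
  # aspect ratio of a 3:1 ellipse within 1%
  s3 <- extract_silhouettes(ellipse_mask(90, 30, 0.4))[[1]]
  expect_lt(abs(aspect_ratio(fit_ellipse(s3)) - 3) / 3, 0.01)
})

test_that("silhouette invariants hold on synthetic model rasters", {
  for (seed in 1:4) {
    fx <- generate_seed_image(fixture_spec(
      c("cardioid", "cardioid_x_phi", "ellipse", "ovoid")[seed],
      resolution = 500, rng_seed = seed, radial_noise_sigma = 0.02))
    s <- extract_silhouettes(binarize(fx$image))[[1]]
    truth_area <- poly_area(fx$ground_truth)
    expect_lt(abs(s$area - truth_area) / truth_area, 0.01)
    expect_lt(abs(s$pixel_area - s$area) / s$area, 0.015)
    expect_lte(s$convex_perimeter, s$perimeter + 1e-9)
    expect_gte(s$major_axis, s$minor_axis)
    hull <- convex_hull(s$outline)
    expect_true(polyclip::pointinpolygon(
      list(x = s$centroid[1], y = s$centroid[2]),
      list(x = hull$x, y = hull$y)) == 1)
  }
})

test_that("pixel size scales all silhouette lengths", {
  mask <- disk_mask(50)
  s1 <- extract_silhouettes(mask)[[1]]
  b <- structure(list(mask = mask, pixel_size = 0.02), class = "binary_image")
  s2 <- extract_silhouettes(b)[[1]]
  expect_equal(s2$area, s1$area * 0.02^2, tolerance = 1e-9)
  expect_equal(s2$perimeter, s1$perimeter * 0.02, tolerance = 1e-9)
  expect_equal(s2$bbox_length, s1$bbox_length * 0.02, tolerance = 1e-9)
})
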