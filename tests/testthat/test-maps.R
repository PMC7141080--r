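test_that("Gaussian accumulation conserves unit mass and is linear", {
  m <- uncertainty_map(800, 600, factor = 2, kernel = "gaussian")
  m1 <- accumulate_samples(m, rbind(c(400, 300)), sigma_px = 20)
  expect_equal(sum(m1$grid), 1, tolerance = 1e-6)
  expect_equal(m1$n_samples, 1L)

  # two identical samples exactly double the grid
  m2 <- accumulate_samples(m1, rbind(c(400, 300)), sigma_px = 20)
  expect_equal(m2$grid, 2 * m1$grid, tolerance = 1e-12)

  # mass totals n_samples away from the borders
  pts <- cbind(runif(10, 200, 600), runif(10, 200, 400))
  mn <- accumulate_samples(m, pts, sigma_px = 20)
  expect_equal(sum(mn$grid), 10, tolerance = 1e-3)
  expect_true(all(mn$grid >= 0))
})

test_that("pupil-polygon kernels follow the disk distance-transform profile", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  R <- 60
  poly <- cbind(300 + R * cos(th), 200 + R * sin(th))
  m <- uncertainty_map(600, 400, factor = 1, kernel = "pupil-polygon")
  m <- accumulate_samples(m, list(poly))
  expect_equal(m$n_samples, 1L)
  # kernel value at radius rho is 1 - rho/R, peak 1 at the centre
  expect_equal(max(m$grid), 1, tolerance = 0.05)
  for (rho in c(0, 15, 30, 45)) {
    got <- m$grid[200 + 1, 300 + rho + 1]
    expect_lt(abs(got - (1 - rho / R)), 1.5 / R + 0.02)
  }
  # degenerate polygons are skipped and counted
  m2 <- accumulate_samples(m, list(cbind(c(0, 1, 2), c(0, 0, 0))))
  expect_equal(m2$n_skipped, 1L)
  expect_equal(m2$n_samples, 1L)
})

test_that("larger projected pupils spread mass over larger support", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  small <- cbind(150 + 20 * cos(th), 150 + 20 * sin(th))
  big <- cbind(450 + 60 * cos(th), 150 + 60 * sin(th))
  m <- uncertainty_map(600, 300, factor = 1, kernel = "pupil-polygon")
  m <- accumulate_samples(m, list(small, big))
  half <- ncol(m$grid) %/% 2
  support_small <- sum(m$grid[, 1:half] > 0)
  support_big <- sum(m$grid[, (half + 1):ncol(m$grid)] > 0)
  expect_gt(support_big, 5 * support_small)
  expect_gt(sum(m$grid[, (half + 1):ncol(m$grid)]), sum(m$grid[, 1:half]))
})

test_that("bump rendering shades gradients and flattens constants", {
  expect_equal(bump_render(matrix(3, 20, 30)), matrix(127.5, 20, 30))
  # a linear ramp has a constant gradient: uniform non-mid output
  ramp <- matrix(rep(seq(0, 1, length.out = 40), times = 30), nrow = 30, byrow = TRUE)
  br <- bump_render(ramp, z_scale = 1)
  interior <- br[2:29, 2:39]
  expect_lt(diff(range(interior)), 1e-9)
  # a hemisphere bump matches the direct Lambert cosine at probe pixels
  n <- 81; R <- 30
  xs <- matrix(rep(-40:40, each = n), n); ys <- t(xs)
  r2 <- xs^2 + ys^2
  hemi <- matrix(0, n, n)
  hemi[r2 <= R^2] <- sqrt(R^2 - r2[r2 <= R^2])
  az <- 315 * pi / 180; el <- 45 * pi / 180
  l <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  br2 <- bump_render(hemi, 315, 45, z_scale = 1)
  shade_direct <- function(ix, iy) {
    gx <- (hemi[iy, ix + 1] - hemi[iy, ix - 1]) / 2
    gy <- (hemi[iy + 1, ix] - hemi[iy - 1, ix]) / 2
    max((-gx * l[1] - gy * l[2] + l[3]) / sqrt(gx^2 + gy^2 + 1), 0)
  }
  probes <- list(c(41, 41), c(50, 41), c(41, 52), c(35, 35), c(48, 49))
  direct <- vapply(probes, function(p) shade_direct(p[1], p[2]), 0)
  got <- vapply(probes, function(p) br2[p[2], p[1]], 0)
  # compare after the same min-max scaling the renderer applies
  all_shades <- matrix(0, n, n)
  for (ix in 2:(n - 1)) for (iy in 2:(n - 1)) all_shades[iy, ix] <- shade_direct(ix, iy)
  lo <- min(all_shades[2:(n - 1), 2:(n - 1)]); hi <- max(all_shades[2:(n - 1), 2:(n - 1)])
  expect_equal(got, (direct - lo) / (hi - lo) * 255, tolerance = 0.02)
})

test_that("the IDW error map interpolates residual norms", {
  # all-zero residuals give the zero map
  f0 <- correction_field(data.frame(timestamp_ms = 0:2, x = c(0, 50, 90),
                                    y = c(0, 40, 80), dx = 0, dy = 0))
  expect_equal(max(error_map(f0, 100, 100, factor = 4)$grid), 0)

  # a single node with vector (3,4) gives the constant map 5
  f1 <- correction_field(data.frame(timestamp_ms = 0, x = 50, y = 50, dx = 3, dy = 4))
  em1 <- error_map(f1, 120, 80, factor = 4)
  expect_equal(range(em1$grid), c(5, 5))

  # two-node case against direct Shepard evaluation at random cells
  nodes <- data.frame(timestamp_ms = c(0, 9), x = c(20, 100), y = c(30, 70),
                      dx = c(2, -1), dy = c(0, 3))
  f2 <- correction_field(nodes, r = 2)
  em2 <- error_map(f2, 128, 96, factor = 4)
  set.seed(3)
  for (k in 1:10) {
    iy <- sample(nrow(em2$grid), 1); ix <- sample(ncol(em2$grid), 1)
    cx <- (ix - 1) * 4 + 1.5; cy <- (iy - 1) * 4 + 1.5
    expect_equal(em2$grid[iy, ix],
                 sqrt(sum(idw_oracle(nodes, c(cx, cy), 2)^2)), tolerance = 1e-9)
  }
  # continuity: adjacent cells differ by less than max |v_i|
  vmax <- max(sqrt(nodes$dx^2 + nodes$dy^2))
  expect_lt(max(abs(diff(em2$grid))), vmax)
  expect_lt(max(abs(t(diff(t(em2$grid))))), vmax)
})

test_that("projected contours stay simple inside the hull and fold outside", {
  # identity-like (affine) mapping: projection is congruent up to the affine map
  aff <- data.frame(pupil_u = runif(30, 100, 500), pupil_v = runif(30, 100, 400))
  aff$marker_x <- 10 + 2 * aff$pupil_u
  aff$marker_y <- 5 + 2 * aff$pupil_v
  fa <- gaze_fit(aff)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  contour <- cbind(300 + 40 * cos(th), 250 + 30 * sin(th))
  proj <- project_contour(fa, contour)
  expect_lt(max(abs(proj - cbind(10 + 2 * contour[, 1], 5 + 2 * contour[, 2]))), 1e-6)
  expect_false(attr(proj, "folded"))

  # mild quadratic, contour inside the calibration hull: simple polygon
  fit <- gaze_fit(quad_pairs(60))
  inside <- cbind(320 + 35 * cos(th), 240 + 25 * sin(th))
  pin <- project_contour(fit, inside)
  expect_false(attr(pin, "folded"))
  expect_false(attr(pin, "extrapolated"))

  # strong quadratic, contour far outside the hull: the projection folds.
  # The truth map is affine + a complex-square quadratic whose critical
  # point (u = 20) lies well outside the calibration region; a contour
  # enclosing it maps to a looped (self-intersecting) polygon.
  fmap <- function(u, v) {
    du <- u - 320; dv <- v - 240; s <- 0.005
    cbind(960 + 3 * du + s * (du^2 - dv^2), 540 + 3 * dv + s * 2 * du * dv)
  }
  set.seed(14)
  u <- runif(60, 150, 490); v <- runif(60, 110, 370)
  m <- fmap(u, v)
  fs <- gaze_fit(data.frame(pupil_u = u, pupil_v = v,
                            marker_x = m[, 1], marker_y = m[, 2]))
  far <- cbind(20 + 60 * cos(th), 240 + 60 * sin(th))
  pf <- project_contour(fs, far)
  expect_true(attr(pf, "extrapolated"))
  expect_true(attr(pf, "folded"))
})

test_that("maps write as paired PNG + text matrix and round-trip", {
  m <- uncertainty_map(64, 48, factor = 4, kernel = "gaussian")
  m <- accumulate_samples(m, rbind(c(32, 24), c(20, 30)), sigma_px = 6)
  p <- tempfile(fileext = ".png")
  paths <- write_map(m, p)
  expect_true(file.exists(paths["png"]))
  expect_true(file.exists(paths["txt"]))
  back <- read_map_text(paths["txt"])
  expect_lt(max(abs(back - m$grid)), 1e-6)

  # constant-zero grid renders all black
  z <- uncertainty_map(40, 40, factor = 4)
  pz <- tempfile(fileext = ".png")
  write_map(z, pz)
  expect_true(all(png::readPNG(pz) == 0))

  # a single nonzero cell renders as the single white pixel
  one <- z; one$grid[3, 7] <- 5
  po <- tempfile(fileext = ".png")
  write_map(one, po)
  img <- png::readPNG(po)
  expect_equal(img[3, 7], 1)
  expect_equal(sum(img > 0), 1)
})
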