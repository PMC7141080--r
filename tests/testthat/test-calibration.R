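test_that("pupil and marker streams pair by nearest timestamp", {
  pupils <- data.frame(timestamp_ms = c(0, 10, 20),
                       pupil_u = 1:3, pupil_v = 4:6)
  markers <- data.frame(timestamp_ms = c(0, 6, 13, 21),
                        marker_x = c(10, 20, 30, 40), marker_y = 0)
  got <- pair_streams(pupils, markers, max_dt_ms = 9)
  expect_equal(nrow(got), 3)
  # pupil at t=10 sits between markers at 6 and 13: nearest is 13
  expect_equal(got$marker_timestamp_ms[2], 13)
  expect_equal(got$marker_x[2], 30)

  # identical grids: all matched to their own timestamp
  m2 <- data.frame(timestamp_ms = pupils$timestamp_ms, marker_x = 7:9, marker_y = 0)
  all_m <- pair_streams(pupils, m2)
  expect_equal(all_m$marker_timestamp_ms, pupils$timestamp_ms)

  # a 100 ms offset exceeds the 9 ms gate: zero pairs
  m3 <- data.frame(timestamp_ms = pupils$timestamp_ms + 100, marker_x = 1, marker_y = 1)
  expect_message(none <- pair_streams(pupils, m3), "dropped 3")
  expect_equal(nrow(none), 0)

  # equidistant markers break toward the later sample
  m4 <- data.frame(timestamp_ms = c(5, 15), marker_x = c(100, 200), marker_y = 0)
  tie <- pair_streams(pupils[2, ], m4)
  expect_equal(tie$marker_timestamp_ms, 15)

  expect_warning(pair_streams(pupils[0, ], markers), "empty")
})

test_that("calibration/evaluation split is exact, seeded and bounded", {
  pairs <- quad_pairs(228)
  sp <- split_pairs(pairs, 0.5, seed = 3)
  expect_equal(nrow(sp$calibration), 114)
  expect_equal(nrow(sp$evaluation), 114)
  expect_equal(nrow(rbind(sp$calibration, sp$evaluation)), 228)
  expect_length(intersect(rownames(sp$calibration), rownames(sp$evaluation)), 0)

  sp2 <- split_pairs(pairs, 0.5, seed = 3)
  expect_identical(sp$calibration, sp2$calibration)

  ten <- quad_pairs(10)
  expect_silent(split_pairs(ten, 0.9, seed = 1))   # X = 9, Y = 1: allowed
  expect_error(split_pairs(ten, 0.4, seed = 1),    # X = 4 < 6
               class = "monogaze_insufficient")
})

test_that("the quadratic fit recovers a generating quadratic exactly", {
  truth <- quadratic_truth_model()
  pairs <- quad_pairs(60, truth)
  fit <- gaze_fit(pairs)
  # predictions reproduce the truth map everywhere in the domain
  grid <- expand.grid(pupil_u = seq(160, 480, 40), pupil_v = seq(120, 360, 40))
  pred <- predict(fit, grid)
  want <- monogaze:::eval_quad_map(truth, as.matrix(grid))
  expect_lt(max(abs(pred - want)), 1e-6)
  # raw-basis coefficients match the generating ones
  expect_equal(unname(coef(fit)[, "x"]), unname(truth$coeff_x), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[, "y"]), unname(truth$coeff_y), tolerance = 1e-6)
})

test_that("under-determined and degenerate geometries are refused", {
  expect_error(gaze_fit(quad_pairs(5)), class = "monogaze_insufficient")
  # pupils on a straight line cannot span the quadratic basis
  line <- data.frame(pupil_u = seq(100, 500, length.out = 20), pupil_v = 240,
                     marker_x = seq(100, 1800, length.out = 20), marker_y = 500)
  err <- tryCatch(gaze_fit(line), error = identity)
  expect_s3_class(err, "monogaze_degenerate_geometry")
  expect_match(conditionMessage(err), "basis term")
})

test_that("prediction honours training points, affine data and extrapolation flags", {
  pairs <- quad_pairs(40)
  fit <- gaze_fit(pairs)
  pred <- predict(fit, pairs[3, ])
  expect_equal(c(pred[1, 1], pred[1, 2]),
               c(x = pairs$marker_x[3], y = pairs$marker_y[3]),
               tolerance = 1e-8)

  # affine-generated data: quadratic coefficients vanish
  aff <- data.frame(pupil_u = runif(30, 100, 500), pupil_v = runif(30, 100, 400))
  aff$marker_x <- 50 + 3 * aff$pupil_u + 0.5 * aff$pupil_v
  aff$marker_y <- 20 + 0.2 * aff$pupil_u + 2.5 * aff$pupil_v
  fa <- gaze_fit(aff)
  expect_lt(max(abs(coef(fa)[c("u*v", "u^2", "v^2"), ])), 1e-8)
  expect_equal(unname(coef(fa)[1:3, "x"]), c(50, 3, 0.5), tolerance = 1e-8)

  # points outside the calibration pupil bounding box carry the flag
  out <- predict(fit, data.frame(pupil_u = c(300, 5000), pupil_v = c(240, 240)))
  expect_equal(attr(out, "extrapolated"), c(FALSE, TRUE))
})

test_that("reprojection residuals satisfy the least-squares identities", {
  s <- generate_session("pursuit-rect", duration_s = 2, seed = 5)
  fit <- gaze_fit(s$table)
  rs <- residuals(fit)
  expect_equal(nrow(rs), nrow(s$table))
  # with an intercept in the basis, residual components sum to zero
  expect_lt(abs(sum(rs$dx)), 1e-7)
  expect_lt(abs(sum(rs$dy)), 1e-7)
  # nodes sit at the marker centres with copied timestamps
  expect_equal(rs$x, s$table$marker_x)
  expect_equal(rs$timestamp_ms, s$table$timestamp_ms)
  # noiseless data: all residual vectors vanish
  rs0 <- residuals(gaze_fit(quad_pairs(30)))
  expect_lt(max(abs(c(rs0$dx, rs0$dy))), 1e-7)
})

test_that("fit is invariant to standardization and equivariant to marker offsets", {
  pairs <- quad_pairs(50)
  f1 <- gaze_fit(pairs, standardize = TRUE)
  f2 <- gaze_fit(pairs, standardize = FALSE)
  grid <- data.frame(pupil_u = runif(20, 160, 480), pupil_v = runif(20, 120, 360))
  expect_lt(max(abs(predict(f1, grid) - predict(f2, grid))), 1e-8)

  shifted <- pairs
  shifted$marker_x <- shifted$marker_x + 37
  shifted$marker_y <- shifted$marker_y - 12
  f3 <- gaze_fit(shifted)
  d <- predict(f3, grid) - predict(f1, grid)
  expect_equal(unname(colMeans(d)), c(37, -12), tolerance = 1e-8)
  expect_lt(max(abs(sweep(d, 2, c(37, -12)))), 1e-8)
})

test_that("fitted mappings round-trip through the plain-text model file", {
  fit <- gaze_fit(quad_pairs(40))
  p <- tempfile(fileext = ".txt")
  write_mapping(fit, p)
  back <- read_mapping(p)
  grid <- data.frame(pupil_u = runif(10, 160, 480), pupil_v = runif(10, 120, 360))
  expect_equal(predict(back, grid)[, 1:2], predict(fit, grid)[, 1:2],
               tolerance = 1e-12)
})
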