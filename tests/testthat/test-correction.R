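test_that("IDW interpolation follows the Shepard closed form", {
  one <- correction_field(data.frame(timestamp_ms = 0, x = 5, y = 5,
                                     dx = 2, dy = -1))
  expect_equal(unname(idw_vector(one, c(100, 200))), c(2, -1))

  # two equidistant nodes with opposite vectors cancel
  two <- correction_field(data.frame(timestamp_ms = c(0, 9), x = c(-10, 10),
                                     y = 0, dx = c(3, -3), dy = 0))
  expect_equal(unname(idw_vector(two, c(0, 7))), c(0, 0))

  # a query at a node returns that node's vector exactly (d = 0 rule)
  three <- correction_field(data.frame(
    timestamp_ms = c(0, 9, 18), x = c(0, 10, 0), y = c(0, 0, 10),
    dx = c(1, 0, 1), dy = c(0, 1, 1)))
  expect_equal(unname(idw_vector(three, c(10, 0))), c(0, 1))
  # coincident nodes average
  co <- correction_field(data.frame(timestamp_ms = c(0, 9), x = 1, y = 1,
                                    dx = c(2, 4), dy = c(0, 2)))
  expect_equal(unname(idw_vector(co, c(1, 1))), c(3, 1))

  # worked 3-node example against the independent direct summation
  got <- idw_vector(three, c(2, 2))
  expect_equal(unname(got), idw_oracle(three$nodes, c(2, 2), r = 2),
               tolerance = 1e-12)

  expect_error(idw_vector(three, c(0, 0), subset = integer(0)),
               class = "monogaze_no_nodes")
  expect_error(correction_field(three$nodes[0, ]), class = "monogaze_no_nodes")
})

test_that("IDW matches the brute-force oracle on random node sets", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    nodes <- random_nodes(sample(1:10, 1))
    r <- sample(c(1, 2, 3), 1)
    f <- correction_field(nodes, r = r)
    p <- c(runif(1, 0, 1920), runif(1, 0, 1080))
    worst <- max(worst, abs(unname(idw_vector(f, p)) - idw_oracle(nodes, p, r)))
  }
  expect_lt(worst, 1e-9)
})

test_that("the Modified-IDW window selects nodes around the nearest point", {
  nd <- data.frame(timestamp_ms = seq(0, 1000, by = 100),
                   x = seq(0, 1000, by = 100), y = 0, dx = 0, dy = 0)
  f <- correction_field(nd, window_ms = 200)
  sel <- select_window(f, c(499, 3))        # nearest node at t = 500
  expect_equal(nd$timestamp_ms[sel], c(300, 400, 500, 600, 700))
  expect_true(attr(sel, "nearest") %in% sel)

  # T covering the whole span selects every node
  f_all <- correction_field(nd, window_ms = 1e6)
  expect_equal(length(select_window(f_all, c(730, -5))), nrow(nd))

  # T = 0 keeps only nodes sharing Np's timestamp
  f0 <- correction_field(rbind(nd, nd[6, ]), window_ms = 0)
  expect_equal(unique(f0$nodes$timestamp_ms[select_window(f0, c(520, 0))]), 500)

  # spatial ties break toward the earlier timestamp
  tie <- correction_field(data.frame(timestamp_ms = c(100, 900),
                                     x = c(-5, 5), y = 0, dx = 0, dy = 0),
                          window_ms = 50)
  expect_equal(attr(select_window(tie, c(0, 0)), "nearest"), 1L)
})

test_that("midw equals idw once the window covers the session", {
  set.seed(77)
  nodes <- random_nodes(40)
  span <- diff(range(nodes$timestamp_ms))
  f <- correction_field(nodes, r = 2, window_ms = span + 1)
  pts <- cbind(runif(50, 0, 1920), runif(50, 0, 1080))
  expect_lt(max(abs(correct_gaze(f, pts, "midw") - correct_gaze(f, pts, "idw"))),
            1e-12)
})

test_that("corrections are convex combinations and respect exact nodes", {
  set.seed(5)
  nodes <- random_nodes(25)
  f <- correction_field(nodes, r = 2, window_ms = 200)
  for (i in 1:20) {
    p <- c(runif(1, 0, 1920), runif(1, 0, 1080))
    sel <- select_window(f, p)
    v <- idw_vector(f, p, sel)
    # each component lies within the selected vectors' range (convex hull
    # of the v_i in each coordinate)
    expect_gte(v[1], min(nodes$dx[sel]) - 1e-12)
    expect_lte(v[1], max(nodes$dx[sel]) + 1e-12)
    expect_gte(v[2], min(nodes$dy[sel]) - 1e-12)
    expect_lte(v[2], max(nodes$dy[sel]) + 1e-12)
  }
  # all-zero residuals leave any point unchanged
  zero <- correction_field(transform(nodes, dx = 0, dy = 0))
  p <- cbind(c(10, 500), c(20, 900))
  expect_equal(correct_gaze(zero, p, "idw"), correct_gaze(zero, p, "raw"))
  # correcting at a node applies that node's exact vector (d = 0 rule)
  at_node <- correct_gaze(f, rbind(c(nodes$x[7], nodes$y[7])), "idw")
  expect_equal(drop(at_node), c(x = nodes$x[7] + nodes$dx[7],
                                y = nodes$y[7] + nodes$dy[7]))
})

test_that("corrections reduce evaluation error on drifting noisy sessions", {
  # mirrors the reported ordering: raw >= idw and raw > midw
  ok_idw <- 0; ok_midw <- 0
  for (sd in c(1, 2, 3)) for (seed in 1:3) {
    s <- generate_session("head-rotation", duration_s = 4, noise_sd_px = sd,
                          seed = seed)
    ev <- evaluate_session(s, gaze_config(seed = seed + 10))
    mae <- setNames(ev$mae_px, ev$method)
    ok_idw <- ok_idw + (mae["raw"] >= mae["idw"])
    ok_midw <- ok_midw + (mae["raw"] > mae["midw"])
  }
  expect_gte(ok_idw + ok_midw, 16)   # >= 8/9 for each comparison jointly
  expect_gte(ok_midw, 8)
})
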