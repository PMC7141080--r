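# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force Shepard interpolation: a direct loop over the
# nodes, kept deliberately separate from the package's idw_vector().
idw_oracle <- function(nodes, p, r) {
  num <- c(0, 0); den <- 0
  for (i in seq_len(nrow(nodes))) {
    d <- sqrt((nodes$x[i] - p[1])^2 + (nodes$y[i] - p[2])^2)
    if (d == 0) next
    num <- num + c(nodes$dx[i], nodes$dy[i]) / d^r
    den <- den + 1 / d^r
  }
  num / den
}

# Random correction-field nodes for property tests.
random_nodes <- function(n, t_span = 1000) {
  data.frame(
    timestamp_ms = sort(runif(n, 0, t_span)),
    x = runif(n, 0, 1920), y = runif(n, 0, 1080),
    dx = rnorm(n, 0, 5), dy = rnorm(n, 0, 5)
  )
}

# Pairs generated exactly by a known quadratic map (no noise).
quad_pairs <- function(n = 40, map = quadratic_truth_model(), seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    u <- runif(n, 150, 490); v <- runif(n, 110, 370)
    m <- monogaze:::eval_quad_map(map, cbind(u, v))
    data.frame(timestamp_ms = seq_len(n) * 9, pupil_u = u, pupil_v = v,
               marker_x = m[, 1], marker_y = m[, 2])
  })
}

# A small session CSV on disk; returns the path (cleaned up by the caller's
# test via tempfile semantics).
write_session_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
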