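# Calibration: pairing the pupil and marker streams, splitting into
# calibration/evaluation sets, and fitting the bivariate second-order
# polynomial gaze mapping by SVD least squares.

#' Pair pupil and marker streams by nearest timestamp
#'
#' Each pupil sample is matched to the marker sample with the nearest
#' timestamp, provided the gap does not exceed `max_dt_ms` (default 9 ms,
#' about one frame at 114 Hz).  Equidistant markers break toward the later
#' sample.  Unmatched samples are dropped and counted.
#'
#' @param pupils `data.frame` with `timestamp_ms`, `pupil_u`, `pupil_v`
#'   (time-sorted), or a list of `pupil_sample` objects.
#' @param markers `data.frame` with `timestamp_ms`, `marker_x`, `marker_y`
#'   (time-sorted), or a list of `marker_sample` objects.
#' @param max_dt_ms maximum pairing gap in milliseconds.
#' @return `data.frame` of calibration pairs: `timestamp_ms` (the pupil
#'   timestamp), `pupil_u`, `pupil_v`, `marker_x`, `marker_y`,
#'   `marker_timestamp_ms`.
#' @export
pair_streams <- function(pupils, markers, max_dt_ms = 9) {
  if (is.list(pupils) && !is.data.frame(pupils) &&
      all(vapply(pupils, inherits, TRUE, "pupil_sample")))
    pupils <- data.frame(
      timestamp_ms = vapply(pupils, `[[`, 0, "timestamp_ms"),
      pupil_u = vapply(pupils, function(p) p$center[1], 0),
      pupil_v = vapply(pupils, function(p) p$center[2], 0))
  if (is.list(markers) && !is.data.frame(markers) &&
      all(vapply(markers, inherits, TRUE, "marker_sample")))
    markers <- data.frame(
      timestamp_ms = vapply(markers, `[[`, 0, "timestamp_ms"),
      marker_x = vapply(markers, function(m) m$center[1], 0),
      marker_y = vapply(markers, function(m) m$center[2], 0))
  empty <- data.frame(timestamp_ms = numeric(), pupil_u = numeric(),
                      pupil_v = numeric(), marker_x = numeric(),
                      marker_y = numeric(), marker_timestamp_ms = numeric())
  if (nrow(pupils) == 0 || nrow(markers) == 0) {
    warning("empty input stream: no pairs formed")
    return(empty)
  }
  mt <- markers$timestamp_ms
  pt <- pupils$timestamp_ms
  # index of the last marker at or before each pupil time
  lo <- findInterval(pt, mt)
  hi <- pmin(lo + 1L, length(mt))
  lo <- pmax(lo, 1L)
  dlo <- abs(pt - mt[lo]); dhi <- abs(mt[hi] - pt)
  # ties (dlo == dhi) break toward the later marker sample
  j <- ifelse(dhi <= dlo, hi, lo)
  dt <- abs(mt[j] - pt)
  keep <- dt <= max_dt_ms
  if (sum(!keep) > 0)
    message(sprintf("pairing dropped %d of %d pupil samples (no marker within %g ms)",
                    sum(!keep), length(pt), max_dt_ms))
  if (!any(keep)) return(empty)
  data.frame(
    timestamp_ms = pt[keep],
    pupil_u = pupils$pupil_u[keep], pupil_v = pupils$pupil_v[keep],
    marker_x = markers$marker_x[j[keep]], marker_y = markers$marker_y[j[keep]],
    marker_timestamp_ms = mt[j[keep]]
  )
}

#' Split calibration pairs into calibration and evaluation sets
#'
#' Uniform random split without replacement: `round(n * split_fraction)`
#' pairs form the calibration set X used to fit the mapping; the remainder Y
#' evaluates it.  At least 6 calibration pairs are required (the quadratic
#' has 6 coefficients per axis).
#'
#' @param pairs `data.frame` of calibration pairs (see [pair_streams()]).
#' @param split_fraction fraction assigned to calibration, in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return `list(calibration =, evaluation =)` of disjoint `data.frame`s
#'   whose union is `pairs`.
#' @export
split_pairs <- function(pairs, split_fraction = 0.5, seed = 1L) {
  n <- nrow(pairs)
  nx <- round(n * split_fraction)
  if (nx < 6)
    stop_monogaze("monogaze_insufficient",
                  sprintf("split yields %d calibration pairs; at least 6 required", nx))
  if (nx >= n)
    stop_monogaze("monogaze_insufficient", "split leaves no evaluation pairs")
  idx <- with_seed(seed, sample.int(n, nx))
  list(calibration = pairs[sort(idx), , drop = FALSE],
       evaluation = pairs[-sort(idx), , drop = FALSE])
}

# Expand coefficients fitted on standardized pupil coordinates
# us = (u - mu)/s into the raw-pixel quadratic basis (1, u, v, uv, u^2, v^2).
expand_std_coeff <- function(cs, mu, s) {
  A <- 1 / s[1]; B <- -mu[1] / s[1]
  C <- 1 / s[2]; D <- -mu[2] / s[2]
  c(cs[1] + cs[2] * B + cs[3] * D + cs[4] * B * D + cs[5] * B^2 + cs[6] * D^2,
    cs[2] * A + cs[4] * A * D + 2 * cs[5] * A * B,
    cs[3] * C + cs[4] * B * C + 2 * cs[6] * C * D,
    cs[4] * A * C,
    cs[5] * A^2,
    cs[6] * C^2)
}

#' Fit the quadratic gaze mapping
#'
#' Fits two bivariate second-order polynomial surfaces (basis
#' `1, u, v, uv, u^2, v^2`) taking pupil centres to world-camera marker
#' centres, by SVD least squares on standardized pupil coordinates
#' (zero mean, unit scale per axis — a conditioning measure; predictions are
#' invariant to it).
#'
#' @param pairs `data.frame` of at least 6 calibration pairs with columns
#'   `pupil_u`, `pupil_v`, `marker_x`, `marker_y` (optionally
#'   `timestamp_ms`).
#' @param standardize standardize pupil coordinates before the SVD solve
#'   (default `TRUE`).
#' @return an object of class `gaze_mapping` with components `coefficients`
#'   (6 x 2 matrix on the raw pixel basis), `coeff_std` (on the standardized
#'   basis), `norm_params`, `fitted`, `residual_set` (node positions,
#'   timestamps and correction vectors), `pupil_bbox`, `n`.
#' @seealso [predict.gaze_mapping()], [residuals.gaze_mapping()],
#'   [correction_field()].
#' @export
gaze_fit <- function(pairs, standardize = TRUE) {
  req <- c("pupil_u", "pupil_v", "marker_x", "marker_y")
  stopifnot(all(req %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 6)
    stop_monogaze("monogaze_insufficient",
                  sprintf("need at least 6 calibration pairs, got %d", n))
  u <- pairs$pupil_u; v <- pairs$pupil_v
  if (standardize) {
    mu <- c(mean(u), mean(v))
    s <- c(sd(u), sd(v))
    s[!is.finite(s) | s == 0] <- 1
  } else {
    mu <- c(0, 0); s <- c(1, 1)
  }
  D <- quad_design((u - mu[1]) / s[1], (v - mu[2]) / s[2])
  sv <- svd(D)
  tol <- max(dim(D)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < 6) {
    # name the deficient basis direction: the null-space right singular
    # vector's largest component
    null_v <- sv$v[, which.min(sv$d)]
    term <- QUAD_BASIS[which.max(abs(null_v))]
    stop_monogaze("monogaze_degenerate_geometry",
                  sprintf("degenerate calibration geometry: design matrix rank %d < 6 (deficient direction dominated by basis term '%s')",
                          rank, term))
  }
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))             # SVD pseudo-inverse
  cs_x <- drop(pinv %*% pairs$marker_x)
  cs_y <- drop(pinv %*% pairs$marker_y)
  fitted <- cbind(x = drop(D %*% cs_x), y = drop(D %*% cs_y))
  res <- cbind(dx = pairs$marker_x - fitted[, 1],
               dy = pairs$marker_y - fitted[, 2])
  ts <- if ("timestamp_ms" %in% names(pairs)) pairs$timestamp_ms else seq_len(n) - 1
  coefficients <- cbind(x = expand_std_coeff(cs_x, mu, s),
                        y = expand_std_coeff(cs_y, mu, s))
  rownames(coefficients) <- QUAD_BASIS
  structure(list(
    coefficients = coefficients,
    coeff_std = cbind(x = cs_x, y = cs_y),
    norm_params = list(mean = mu, scale = s),
    fitted = fitted,
    residual_set = data.frame(timestamp_ms = ts,
                              x = pairs$marker_x, y = pairs$marker_y,
                              dx = res[, "dx"], dy = res[, "dy"]),
    pupil_bbox = c(umin = min(u), umax = max(u), vmin = min(v), vmax = max(v)),
    training = pairs,
    n = n,
    call = match.call()
  ), class = "gaze_mapping")
}

#' Predict world-camera gaze positions from pupil centres
#'
#' Evaluates both fitted quadratic surfaces at the (standardized) pupil
#' points.  Extrapolation is permitted; points outside the calibration
#' pupil bounding box are flagged in the `"extrapolated"` attribute, since
#' quadratic mappings degrade (and can fold) outside the calibrated region.
#'
#' @param object a `gaze_mapping`.
#' @param newdata `data.frame` with `pupil_u`, `pupil_v`, or an n x 2
#'   matrix of pupil coordinates.  Defaults to the training pupils.
#' @param ... unused.
#' @return n x 2 matrix of world coordinates (`x`, `y`), with a logical
#'   `"extrapolated"` attribute per row.
#' @export
predict.gaze_mapping <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training
  uv <- if (is.data.frame(newdata)) cbind(newdata$pupil_u, newdata$pupil_v)
        else as.matrix(newdata)
  mu <- object$norm_params$mean; s <- object$norm_params$scale
  D <- quad_design((uv[, 1] - mu[1]) / s[1], (uv[, 2] - mu[2]) / s[2])
  out <- cbind(x = drop(D %*% object$coeff_std[, "x"]),
               y = drop(D %*% object$coeff_std[, "y"]))
  bb <- object$pupil_bbox
  attr(out, "extrapolated") <- uv[, 1] < bb["umin"] | uv[, 1] > bb["umax"] |
                               uv[, 2] < bb["vmin"] | uv[, 2] > bb["vmax"]
  out
}

#' Reprojection residuals of a fitted gaze mapping
#'
#' Returns the correction-vector set: for each calibration pair, the node
#' position (the marker centre), its timestamp, and the correction vector
#' `v_i = marker - reprojection` where the reprojection is the mapping's
#' estimate of the marker from the paired pupil centre.
#'
#' @param object a `gaze_mapping`.
#' @param ... unused.
#' @return `data.frame` with columns `timestamp_ms`, `x`, `y`, `dx`, `dy`.
#' @export
residuals.gaze_mapping <- function(object, ...) object$residual_set

#' @export
coef.gaze_mapping <- function(object, ...) object$coefficients

#' @export
print.gaze_mapping <- function(x, ...) {
  cat("Quadratic gaze mapping (basis 1, u, v, uv, u^2, v^2), fitted by SVD\n")
  cat(sprintf("  %d calibration pairs; RMS residual %.4g px\n", x$n,
              sqrt(mean(x$residual_set$dx^2 + x$residual_set$dy^2))))
  invisible(x)
}

#' @export
summary.gaze_mapping <- function(object, ...) {
  rn <- sqrt(object$residual_set$dx^2 + object$residual_set$dy^2)
  structure(list(
    coefficients = object$coefficients,
    norm_params = object$norm_params,
    n = object$n,
    residual_norm = c(mean = mean(rn), sd = sd(rn), max = max(rn)),
    pupil_bbox = object$pupil_bbox
  ), class = "summary.gaze_mapping")
}

#' @export
print.summary.gaze_mapping <- function(x, ...) {
  cat("Quadratic gaze mapping fitted by SVD least squares\n\n")
  cat(sprintf("Calibration pairs: %d\n", x$n))
  cat(sprintf("Reprojection residual norm: mean %.4g, sd %.4g, max %.4g px\n\n",
              x$residual_norm["mean"], x$residual_norm["sd"], x$residual_norm["max"]))
  cat("Coefficients (raw pixel basis):\n")
  print(x$coefficients)
  invisible(x)
}

#' Plot a fitted gaze mapping's residual field
#'
#' Draws the calibration nodes in world-camera coordinates with their
#' correction vectors `v_i` as arrows (scaled for visibility).
#'
#' @param x a `gaze_mapping`.
#' @param scale arrow magnification factor (default 5).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gaze_mapping <- function(x, scale = 5, ...) {
  rs <- x$residual_set
  plot(rs$x, rs$y, pch = 16, cex = 0.5, xlab = "world x (px)",
       ylab = "world y (px)", ylim = rev(range(rs$y)),
       main = "Calibration residual vectors", ...)
  nz <- (rs$dx^2 + rs$dy^2) > 0
  if (any(nz))
    arrows(rs$x[nz], rs$y[nz], rs$x[nz] + scale * rs$dx[nz],
           rs$y[nz] + scale * rs$dy[nz], length = 0.04, col = "red3")
  invisible(x)
}

#' Simulate marker responses from a fitted gaze mapping
#'
#' Simulates new marker observations at the training pupil positions:
#' fitted reprojections plus Gaussian noise with the per-axis residual
#' standard deviation (the parametric-bootstrap analogue of
#' `simulate.lm`).
#'
#' @param object a `gaze_mapping`.
#' @param nsim number of simulated response sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` `data.frame`s with columns `marker_x`,
#'   `marker_y`.
#' @export
simulate.gaze_mapping <- function(object, nsim = 1, seed = 1L, ...) {
  sdx <- sd(object$residual_set$dx); sdy <- sd(object$residual_set$dy)
  n <- object$n
  with_seed(seed, lapply(seq_len(nsim), function(i)
    data.frame(marker_x = object$fitted[, 1] + rnorm(n, 0, sdx),
               marker_y = object$fitted[, 2] + rnorm(n, 0, sdy))))
}

#' Write / read a fitted gaze mapping as plain text
#'
#' The model file stores the basis order, the standardization parameters
#' and the 12 coefficients as `key: value` lines.
#'
#' @param model a `gaze_mapping`.
#' @param path file path.
#' @return `write_mapping` returns `path` invisibly; `read_mapping` a
#'   `gaze_mapping` usable with [predict.gaze_mapping()].
#' @export
write_mapping <- function(model, path) {
  ln <- c(
    paste0("basis: ", paste(QUAD_BASIS, collapse = ", ")),
    paste0("mean: ", paste(format(model$norm_params$mean, digits = 17), collapse = " ")),
    paste0("scale: ", paste(format(model$norm_params$scale, digits = 17), collapse = " ")),
    paste0("coeff_x: ", paste(format(model$coeff_std[, "x"], digits = 17), collapse = " ")),
    paste0("coeff_y: ", paste(format(model$coeff_std[, "y"], digits = 17), collapse = " ")),
    paste0("pupil_bbox: ", paste(format(model$pupil_bbox, digits = 17), collapse = " "))
  )
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  ln <- readLines(path, warn = FALSE)
  getv <- function(key) {
    row <- grep(paste0("^", key, ":"), ln, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub("^[^:]+:", "", row)), "\\s+")[[1]])
  }
  mu <- getv("mean"); s <- getv("scale")
  cs <- cbind(x = getv("coeff_x"), y = getv("coeff_y"))
  bb <- getv("pupil_bbox")
  names(bb) <- c("umin", "umax", "vmin", "vmax")
  coefficients <- cbind(x = expand_std_coeff(cs[, "x"], mu, s),
                        y = expand_std_coeff(cs[, "y"], mu, s))
  rownames(coefficients) <- QUAD_BASIS
  structure(list(coefficients = coefficients, coeff_std = cs,
                 norm_params = list(mean = mu, scale = s),
                 pupil_bbox = bb, n = NA_integer_),
            class = "gaze_mapping")
}
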