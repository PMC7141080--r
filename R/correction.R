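# Gaze correction by Inverse Distance Weighting over the calibration
# residuals (Shepard interpolation of the correction vectors), and the
# time-windowed Modified IDW.

#' Build a correction field from calibration residuals
#'
#' A correction field holds the calibration nodes — marker-centre positions
#' with timestamps and correction vectors `v_i` (marker minus reprojection)
#' — together with the IDW power `r` and the Modified-IDW time window `T`.
#'
#' @param nodes a fitted `gaze_mapping` (its [residuals.gaze_mapping()] are
#'   used), or a `data.frame` with columns `timestamp_ms`, `x`, `y`, `dx`,
#'   `dy`.
#' @param r positive IDW power (default 2, the value found most
#'   appropriate for this pipeline).
#' @param window_ms Modified-IDW window length `T` in milliseconds
#'   (default 200): nodes recorded within `T` ms before or after the
#'   spatially nearest node are selected.
#' @return an object of class `correction_field`.
#' @export
correction_field <- function(nodes, r = 2, window_ms = 200) {
  if (inherits(nodes, "gaze_mapping")) nodes <- residuals(nodes)
  req <- c("timestamp_ms", "x", "y", "dx", "dy")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  if (nrow(nodes) < 1)
    stop_monogaze("monogaze_no_nodes", "correction field needs at least one node")
  if (!is.numeric(r) || r <= 0) stop_monogaze("monogaze_domain", "r must be positive")
  if (!is.numeric(window_ms) || window_ms < 0)
    stop_monogaze("monogaze_domain", "window_ms must be non-negative")
  structure(list(nodes = nodes[req], r = r, window_ms = window_ms),
            class = "correction_field")
}

#' @export
print.correction_field <- function(x, ...) {
  rn <- sqrt(x$nodes$dx^2 + x$nodes$dy^2)
  cat(sprintf("Correction field: %d nodes, r = %g, window T = %g ms\n",
              nrow(x$nodes), x$r, x$window_ms))
  cat(sprintf("  |v_i|: mean %.4g, max %.4g px\n", mean(rn), max(rn)))
  invisible(x)
}

#' Inverse-distance-weighted correction vector at a point
#'
#' Shepard interpolation of the node correction vectors:
#' `v_p = sum(v_i / d_i^r) / sum(1 / d_i^r)` with `d_i` the Euclidean
#' distance from `p` to node `i` in world-camera pixels.  If `p` coincides
#' with one or more nodes (`d_i = 0`, where the weight is undefined), the
#' mean of the coincident nodes' vectors is returned.
#'
#' @param field a `correction_field`.
#' @param p query point `c(x, y)` in world pixels.
#' @param subset optional integer indices of the nodes to use (e.g. from
#'   [select_window()]); default all nodes.
#' @return the correction vector `c(dx, dy)`.
#' @export
idw_vector <- function(field, p, subset = NULL) {
  nd <- field$nodes
  if (!is.null(subset)) nd <- nd[subset, , drop = FALSE]
  if (nrow(nd) == 0)
    stop_monogaze("monogaze_no_nodes", "empty node subset for IDW")
  d <- sqrt((nd$x - p[1])^2 + (nd$y - p[2])^2)
  hit <- d == 0
  if (any(hit))
    return(c(dx = mean(nd$dx[hit]), dy = mean(nd$dy[hit])))
  w <- 1 / d^field$r
  sw <- sum(w)
  c(dx = sum(nd$dx * w) / sw, dy = sum(nd$dy * w) / sw)
}

#' Select the Modified-IDW node window for a query point
#'
#' Finds the node `Np` spatially nearest to `p` (ties break toward the
#' earlier timestamp) and returns all nodes recorded within the field's
#' time window of it: `|t_Np - t_e| <= T`, a closed window on both sides.
#' `Np` itself is always selected.
#'
#' @param field a `correction_field`.
#' @param p query point `c(x, y)` in world pixels.
#' @return integer indices into `field$nodes`, with the index of `Np` as
#'   attribute `"nearest"`.
#' @export
select_window <- function(field, p) {
  nd <- field$nodes
  d <- sqrt((nd$x - p[1])^2 + (nd$y - p[2])^2)
  near <- which(d == min(d))
  if (length(near) > 1) near <- near[which.min(nd$timestamp_ms[near])]
  sel <- which(abs(nd$timestamp_ms - nd$timestamp_ms[near]) <= field$window_ms)
  attr(sel, "nearest") <- near
  sel
}

#' Correct raw gaze estimates
#'
#' Applies the chosen correction to each raw estimated gaze point:
#' `"raw"` returns the points unchanged, `"idw"` adds the IDW correction
#' vector interpolated over all calibration nodes, and `"midw"` (Modified
#' IDW) adds the vector interpolated only over the time window around the
#' spatially nearest node (see [select_window()]).  As the window length
#' grows beyond the session span, `"midw"` coincides with `"idw"`.
#'
#' @param field a `correction_field`.
#' @param points n x 2 matrix (or `data.frame`) of raw gaze points in world
#'   pixels.
#' @param method `"midw"`, `"idw"` or `"raw"`.
#' @return n x 2 matrix of corrected points.
#' @export
correct_gaze <- function(field, points, method = c("midw", "idw", "raw")) {
  method <- match.arg(method)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (method == "raw") {
    colnames(pts) <- c("x", "y")
    return(pts)
  }
  out <- t(vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    v <- if (method == "idw") idw_vector(field, p)
         else idw_vector(field, p, select_window(field, p))
    p + v
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}
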