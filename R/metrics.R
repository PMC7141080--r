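# Quantitative evaluation: per-point error norms, unit conversions
# (world pixels -> cm -> degrees of visual angle), error-reduction
# percentages, and the end-to-end session evaluation.

#' Euclidean error norms between estimated and actual gaze positions
#'
#' @param estimates,truths n x 2 matrices (or `data.frame`s) of world
#'   coordinates.
#' @return numeric vector of per-point Euclidean norms in pixels.
#' @export
error_norms <- function(estimates, truths) {
  e <- as.matrix(estimates); t <- as.matrix(truths)
  if (nrow(e) != nrow(t))
    stop_monogaze("monogaze_domain", "estimates and truths differ in length")
  row_norms(e[, 1:2, drop = FALSE] - t[, 1:2, drop = FALSE])
}

#' Convert a pixel error to centimetres on the target plane
#'
#' @param e_px error in world-camera pixels.
#' @param px_per_cm world-plane scale, pixels per centimetre (positive).
#' @return error in cm.
#' @export
px_to_cm <- function(e_px, px_per_cm) {
  if (!is.numeric(px_per_cm) || px_per_cm <= 0)
    stop_monogaze("monogaze_domain", "px_per_cm must be positive")
  e_px / px_per_cm
}

#' Convert a planar error to degrees of visual angle
#'
#' For an error of `e_cm` on a plane at `distance_cm` from the eye, the
#' subtended visual angle is `atan(e_cm / distance_cm)` in degrees.
#'
#' @param e_cm error in cm on the target plane.
#' @param distance_cm viewing distance in cm (default 75).
#' @return angle in degrees.
#' @export
cm_to_deg <- function(e_cm, distance_cm = 75) {
  if (!is.numeric(distance_cm) || distance_cm <= 0)
    stop_monogaze("monogaze_domain", "distance_cm must be positive")
  atan(e_cm / distance_cm) * 180 / pi
}

#' Error reduction of a correction method relative to a reference
#'
#' @param mae_ref reference mean error (positive).
#' @param mae_new corrected mean error.
#' @return reduction in percent: `100 * (mae_ref - mae_new) / mae_ref`.
#' @export
reduction_percent <- function(mae_ref, mae_new) {
  if (!is.numeric(mae_ref) || mae_ref <= 0)
    stop_monogaze("monogaze_domain", "reference MAE must be positive")
  100 * (mae_ref - mae_new) / mae_ref
}

#' Evaluate a calibration session end to end
#'
#' Runs the full pipeline on a session of paired pupil/marker samples:
#' random calibration/evaluation split, SVD fit of the quadratic mapping on
#' the calibration set, correction field from its reprojection residuals,
#' and evaluation-set error for the three estimates — raw, IDW-corrected,
#' and Modified-IDW-corrected.  Errors are Euclidean norms against the
#' actual marker positions, converted to cm (via `px_per_cm`) and to
#' degrees of visual angle (via `distance_cm`); the mean of the per-point
#' degree conversions is the Mean Angular Error.
#'
#' @param session a session `data.frame` (see [read_session()]) or a
#'   `gaze_session` from [generate_session()].
#' @param config a [gaze_config()] providing `split_fraction`, `seed`, `r`,
#'   `window_ms`, `px_per_cm`, `distance_cm`.
#' @param truth optional n x 2 matrix of actual gaze positions aligned with
#'   the session rows; defaults to the session's marker columns.
#' @return object of class `gaze_evaluation`: a `data.frame` with one row
#'   per method (`raw`, `idw`, `midw`) and columns `mae_px`, `mae_cm`,
#'   `sd_cm`, `mae_deg`, `sd_deg`, `n_eval`, `reduction_vs_raw_percent`.
#'   Per-point error norms are attached as attribute `"errors_px"`; the
#'   fitted mapping and correction field as `"model"` and `"field"`.
#' @export
evaluate_session <- function(session, config = gaze_config(), truth = NULL) {
  if (inherits(session, "gaze_session")) {
    if (is.null(truth)) truth <- as.matrix(session$truth[, c("x", "y")])
    session <- session$table
  }
  stopifnot(all(SESSION_COLS %in% names(session)))
  n <- nrow(session)
  if (n < 12)
    stop_monogaze("monogaze_insufficient",
                  sprintf("evaluation needs at least 12 pairs, got %d", n))
  if (is.null(truth)) truth <- as.matrix(session[, c("marker_x", "marker_y")])
  truth <- as.matrix(truth)[, 1:2, drop = FALSE]
  if (nrow(truth) != n)
    stop_monogaze("monogaze_domain", "truth must align row-for-row with the session")
  idx <- seq_len(n)
  session$.row <- idx
  sp <- split_pairs(session, config$split_fraction, config$seed)
  model <- gaze_fit(sp$calibration)
  field <- correction_field(model, r = config$r, window_ms = config$window_ms)
  ev <- sp$evaluation
  raw <- predict(model, ev)
  truth_ev <- truth[ev$.row, , drop = FALSE]
  est <- list(raw = raw[, 1:2, drop = FALSE],
              idw = correct_gaze(field, raw, "idw"),
              midw = correct_gaze(field, raw, "midw"))
  errs <- lapply(est, error_norms, truths = truth_ev)
  mk <- function(e_px) {
    e_cm <- px_to_cm(e_px, config$px_per_cm)
    e_deg <- cm_to_deg(e_cm, config$distance_cm)
    c(mae_px = mean(e_px), mae_cm = mean(e_cm), sd_cm = sd(e_cm),
      mae_deg = mean(e_deg), sd_deg = sd(e_deg))
  }
  stats <- t(vapply(errs, mk, numeric(5)))
  out <- data.frame(method = rownames(stats), stats, n_eval = nrow(ev),
                    row.names = NULL)
  raw_cm <- out$mae_cm[out$method == "raw"]
  out$reduction_vs_raw_percent <-
    if (raw_cm > 0) reduction_percent(raw_cm, out$mae_cm) else 0
  structure(out,
            errors_px = errs, model = model, field = field,
            class = c("gaze_evaluation", "data.frame"))
}

#' @export
print.gaze_evaluation <- function(x, ...) {
  cat(sprintf("Gaze evaluation on %d evaluation points:\n", x$n_eval[1]))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) round(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
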