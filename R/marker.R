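# Concentric-ring calibration-marker detection in the world camera.

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # 0-based (x, y)
}

#' Detect the concentric-ring calibration marker
#'
#' Searches the frame for the nested structure of the marker — a thick dark
#' ring containing a light ring which encloses a smaller filled dark disk —
#' by hole-filling each dark component and checking for dark content inside
#' its interior.  The centroids of the filled outer shape, the light ring
#' and the filled inner disk must agree within 10% of the outer radius; the
#' reported centre is the innermost-disk centroid (the central cross is
#' neutralized by hole filling) and the confidence is
#' `1 - max pairwise centroid distance / outer radius`.
#'
#' @param image numeric intensity matrix in `[0, 255]` (rows = v), minimum
#'   dimension 128 px, or a path to a PNG file.
#' @param timestamp_ms sample timestamp in milliseconds.
#' @param min_area minimum outer-component area in px^2 (default 60).
#' @param threshold dark/light intensity boundary (default 128).
#' @return object of class `marker_sample`: `timestamp_ms`, `center`
#'   (`c(x, y)` world px), `confidence` in `[0, 1]`, `outer_radius` px.
#' @export
detect_marker <- function(image, timestamp_ms = 0, min_area = 60,
                          threshold = 128) {
  if (is.character(image)) image <- read_gray_image(image)
  if (min(dim(image)) < 128)
    stop_monogaze("monogaze_domain", "world frame must be at least 128 px in each dimension")
  dark <- image < threshold
  lab <- EBImage::bwlabel(EBImage::Image(t(dark) * 1))
  nlab <- max(lab)
  if (nlab == 0) stop_monogaze("monogaze_no_marker", "no marker found: no dark components")
  areas <- tabulate(as.integer(lab[lab > 0]), nbins = nlab)
  cand <- list()
  for (id in which(areas >= min_area)) {
    comp <- lab == id
    fill <- EBImage::fillHull(comp)
    interior <- fill & !comp
    n_int <- sum(interior)
    if (n_int < min_area / 4) next
    int_m <- t(EBImage::imageData(interior)) > 0   # rows = v
    dark_m <- dark & int_m
    n_inner <- sum(dark_m)
    if (n_inner < 9) next                          # no inner dark disk
    if (sum(int_m & !dark_m) < 9) next             # no light ring between them
    inner_fill <- EBImage::fillHull(EBImage::Image(t(dark_m) * 1)) > 0
    inner_m <- t(EBImage::imageData(inner_fill)) > 0
    white_m <- int_m & !inner_m
    if (sum(white_m) < 9) next
    fill_m <- t(EBImage::imageData(fill)) > 0
    c_out <- mask_centroid(fill_m)
    c_white <- mask_centroid(white_m)
    c_in <- mask_centroid(inner_m)
    r_out <- sqrt(sum(fill_m) / pi)
    dmax <- max(
      sqrt(sum((c_out - c_white)^2)),
      sqrt(sum((c_out - c_in)^2)),
      sqrt(sum((c_white - c_in)^2))
    )
    if (dmax > 0.1 * r_out) next
    cand[[length(cand) + 1]] <- list(center = c_in, outer_radius = r_out,
                                     confidence = 1 - dmax / r_out)
  }
  if (length(cand) == 0)
    stop_monogaze("monogaze_no_marker", "no marker found: no nested ring/disk triple")
  confs <- vapply(cand, `[[`, 0, "confidence")
  if (sum(confs > 0.8) > 1)
    stop_monogaze("monogaze_ambiguous_marker",
                  sprintf("ambiguous marker: %d candidates above confidence 0.8",
                          sum(confs > 0.8)))
  best <- cand[[which.max(confs)]]
  structure(list(timestamp_ms = timestamp_ms, center = best$center,
                 confidence = best$confidence, outer_radius = best$outer_radius),
            class = "marker_sample")
}

#' @export
print.marker_sample <- function(x, ...) {
  cat(sprintf("Marker at (%.2f, %.2f) px, outer radius %.1f px, confidence %.3f\n",
              x$center[1], x$center[2], x$outer_radius, x$confidence))
  invisible(x)
}
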