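# Dark-pupil detection: histogram threshold, morphological cleanup, largest
# dark component, algebraic ellipse fit, and the distance-transform
# uncertainty field of the centre location.

# Direct algebraic least-squares ellipse fit (Halir & Flusser's numerically
# stable formulation of Fitzgibbon's method).  pts is an n x 2 matrix of
# contour points; returns list(center, axes = c(a, b) with a >= b, angle in
# degrees).
fit_ellipse <- function(pts) {
  if (nrow(pts) < 5)
    stop_monogaze("monogaze_degenerate", "ellipse fit needs >= 5 contour points")
  mu <- colMeans(pts)
  x <- pts[, 1] - mu[1]; y <- pts[, 2] - mu[2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)   # premultiplied by inv(C1)
  ev <- eigen(M)
  # keep real eigenvectors satisfying the ellipse constraint 4ac - b^2 > 0
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0)
    stop_monogaze("monogaze_degenerate", "contour does not admit an ellipse fit")
  a1 <- V[, k[1]]
  co <- c(a1, drop(Tm %*% a1))                  # A B C D E F on centred coords
  A <- co[1]; B <- co[2]; C <- co[3]; Dd <- co[4]; E <- co[5]; Ff <- co[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * Dd - B * E) / den
  cy <- (2 * A * E - B * Dd) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + Dd * cx + E * cy + Ff
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  lam <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / lam$values
  if (any(ax2 <= 0) || any(!is.finite(ax2)))
    stop_monogaze("monogaze_degenerate", "degenerate conic from contour")
  semi <- sqrt(ax2)                             # paired with lam$vectors columns
  major <- which.max(semi)
  angle <- atan2(lam$vectors[2, major], lam$vectors[1, major]) * 180 / pi
  angle <- ((angle + 90) %% 180) - 90           # fold to (-90, 90]
  list(center = c(cx + mu[1], cy + mu[2]),
       axes = c(max(semi), min(semi)), angle = angle)
}

#' Detect the dark pupil in an eye-camera frame
#'
#' Thresholds the frame at the lowest occupied histogram intensity plus a
#' fixed offset (the dark-pupil heuristic), applies a 5x5 morphological
#' closing to fill specular glint holes, keeps the largest dark connected
#' component, and fits an ellipse to its traced contour.  The reported
#' centre is the ellipse centre (robust to partial occlusion).
#'
#' @param image numeric intensity matrix in `[0, 255]` (rows = v), minimum
#'   dimension 64 px, or a path to a PNG file.
#' @param timestamp_ms sample timestamp in milliseconds.
#' @param min_area minimum component area in px^2 (default 100).
#' @param threshold_offset intensity added to the lowest histogram spike to
#'   form the threshold (default 15).
#' @param dark_max largest intensity the pupil mode may occupy; frames whose
#'   darkest occupied spike exceeds this contain no dark pupil (default 100).
#' @return an object of class `pupil_sample`: `timestamp_ms`, `center`
#'   (`c(u, v)` px), `contour` (m x 2 matrix of 0-based boundary pixels),
#'   `ellipse` (`center`, `axes` `(a, b)`, `angle` degrees), `area_px`.
#'   A component touching the frame border is still returned, with a
#'   `BorderClipped` warning.
#' @export
detect_pupil <- function(image, timestamp_ms = 0, min_area = 100,
                         threshold_offset = 15, dark_max = 100) {
  if (is.character(image)) image <- read_gray_image(image)
  if (min(dim(image)) < 64)
    stop_monogaze("monogaze_domain", "eye frame must be at least 64 px in each dimension")
  iv <- pmin(pmax(round(image), 0), 255)
  counts <- tabulate(iv + 1L, nbins = 256L)
  # lowest histogram spike: darkest intensity below which at least min_area
  # pixels accumulate
  cum <- cumsum(counts)
  spike <- which(cum >= min_area)[1] - 1L
  if (is.na(spike) || spike > dark_max)
    stop_monogaze("monogaze_no_pupil", "no dark pupil component found")
  thr <- spike + threshold_offset
  mask <- iv <= thr
  e <- EBImage::Image(t(mask) * 1)
  e <- EBImage::closing(e, EBImage::makeBrush(5, "box"))
  lab <- EBImage::bwlabel(e)
  if (max(lab) == 0)
    stop_monogaze("monogaze_no_pupil", "no dark pupil component found")
  areas <- tabulate(as.integer(lab[lab > 0]))
  if (max(areas) < min_area)
    stop_monogaze("monogaze_no_pupil",
                  sprintf("largest dark component (%d px^2) below min_area", max(areas)))
  id <- which.max(areas)
  comp <- lab == id
  cm <- t(EBImage::imageData(comp))             # back to rows = v
  if (any(cm[1, ]) || any(cm[nrow(cm), ]) || any(cm[, 1]) || any(cm[, ncol(cm)]))
    warning("BorderClipped: pupil component touches the frame border")
  oc <- EBImage::ocontour(EBImage::Image(t(cm) * 1))[[1]]  # 0-based (u, v)
  if (nrow(oc) < 5)
    stop_monogaze("monogaze_no_pupil", "pupil contour too short for an ellipse fit")
  ell <- fit_ellipse(oc)
  structure(list(
    timestamp_ms = timestamp_ms,
    center = ell$center,
    contour = oc,
    ellipse = ell,
    area_px = sum(cm),
    threshold = thr
  ), class = "pupil_sample")
}

#' @export
print.pupil_sample <- function(x, ...) {
  cat(sprintf("Pupil at (%.2f, %.2f) px, axes (%.2f, %.2f), angle %.1f deg, area %d px^2\n",
              x$center[1], x$center[2], x$ellipse$axes[1], x$ellipse$axes[2],
              x$ellipse$angle, x$area_px))
  invisible(x)
}

# Signed polygon area (shoelace); poly is an n x 2 matrix, not repeated.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Minimum Euclidean distance from points (px, py) to the closed polygon's
# edges; vectorized over points, looped over edges.
dist_to_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
      d2 <- (px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# Interior test + distance transform at arbitrary points for a closed
# polygon: returns list(inside, dt).  Shared by the uncertainty field and
# the pupil-shaped map kernels.
polygon_interior_dt <- function(poly, px, py) {
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), cbind(px, py))
  # points coinciding with polygon vertices count as inside (boundary)
  key <- paste(round(px, 6), round(py, 6))
  vkey <- paste(round(poly[, 1], 6), round(poly[, 2], 6))
  inside <- inside | key %in% vkey
  dt <- rep(NA_real_, length(px))
  dt[inside] <- dist_to_polygon(poly, px[inside], py[inside])
  list(inside = inside, dt = dt)
}

#' Uncertainty field of a pupil contour
#'
#' Computes, over the contour's bounding box, the per-pixel uncertainty of
#' the pupil centre location: `1 - DT/max(DT)` where `DT` is the Euclidean
#' distance transform to the contour.  The field is 0 at the deepest
#' interior point (most certain centre location), 1 on the contour, and
#' undefined (NA) outside the pupil.
#'
#' @param contour closed simple polygon, m x 2 matrix of `(u, v)` pixels.
#' @param center optional detected centre, stored for reference.
#' @return object of class `uncertainty_field`: `field` (matrix, rows = v,
#'   NA outside), `mask`, `origin` (`c(u0, v0)` of the bounding box), and
#'   `deepest` (the 0-based pixel attaining 0).
#' @export
compute_uncertainty_field <- function(contour, center = NULL) {
  contour <- as.matrix(contour)
  if (abs(polygon_area(contour)) < 4)
    stop_monogaze("monogaze_degenerate", "degenerate contour: area below 4 px^2")
  u0 <- floor(min(contour[, 1])); u1 <- ceiling(max(contour[, 1]))
  v0 <- floor(min(contour[, 2])); v1 <- ceiling(max(contour[, 2]))
  us <- u0:u1; vs <- v0:v1
  px <- rep(us, each = length(vs))
  py <- rep(vs, times = length(us))
  pin <- polygon_interior_dt(contour, px, py)
  dt <- matrix(pin$dt, nrow = length(vs), ncol = length(us))
  mask <- matrix(pin$inside, nrow = length(vs), ncol = length(us))
  mx <- max(dt, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop_monogaze("monogaze_degenerate", "contour has no interior pixels")
  field <- 1 - dt / mx
  deep <- which(dt == mx, arr.ind = TRUE)[1, ]
  structure(list(
    field = field, mask = mask, origin = c(u0, v0),
    deepest = c(us[deep[2]], vs[deep[1]]), center = center
  ), class = "uncertainty_field")
}

#' @export
print.uncertainty_field <- function(x, ...) {
  cat(sprintf("Pupil uncertainty field %dx%d at origin (%d, %d); deepest point (%d, %d)\n",
              ncol(x$field), nrow(x$field), x$origin[1], x$origin[2],
              x$deepest[1], x$deepest[2]))
  invisible(x)
}
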