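# Qualitative uncertainty visualization: kernel accumulation maps over the
# world-camera raster (isotropic Gaussian or pupil-shaped distance-transform
# kernels), bump-mapped relief rendering, and the IDW-interpolated error map.

#' Create an empty gaze-uncertainty map
#'
#' The map is a non-negative accumulation grid over the world-camera pixel
#' raster, downsampled by an integer factor for tractability.
#'
#' @param width,height world frame size in native pixels (default
#'   1920x1080).
#' @param factor integer downsampling factor (default 4).
#' @param kernel `"gaussian"` (unit-mass isotropic kernels at gaze points)
#'   or `"pupil-polygon"` (unnormalized distance-transform kernels inside
#'   projected pupil contours, so larger, more uncertain pupils spread more
#'   mass).
#' @return object of class `uncertainty_map` with fields `grid` (rows = y
#'   cells), `n_samples`, `n_skipped`, `kernel`, `width`, `height`,
#'   `factor`.
#' @export
uncertainty_map <- function(width = 1920, height = 1080, factor = 4,
                            kernel = c("gaussian", "pupil-polygon")) {
  kernel <- match.arg(kernel)
  rc <- raster_centers(width, height, factor)
  structure(list(
    grid = matrix(0, nrow = rc$ny, ncol = rc$nx),
    n_samples = 0L, n_skipped = 0L, kernel = kernel,
    width = width, height = height, factor = factor
  ), class = "uncertainty_map")
}

#' @export
print.uncertainty_map <- function(x, ...) {
  cat(sprintf("Uncertainty map %dx%d cells (factor %d, %s kernel): %d samples, total mass %.4g\n",
              ncol(x$grid), nrow(x$grid), x$factor, x$kernel, x$n_samples,
              sum(x$grid)))
  invisible(x)
}

#' Accumulate gaze samples into an uncertainty map
#'
#' For a `"gaussian"` map, each sample is a gaze point and deposits a
#' unit-mass isotropic Gaussian (sd `sigma_px` native pixels, truncated at
#' 4 sd and renormalized).  For a `"pupil-polygon"` map, each sample is a
#' projected pupil contour in world pixels and deposits its interior
#' distance-transform kernel — 1 at the deepest interior point, 0 at the
#' contour — with unnormalized mass, so the spread reflects the size,
#' shape and orientation of each pupil.  Degenerate polygons (area below
#' 4 px^2) are skipped and counted.
#'
#' @param map an [uncertainty_map()].
#' @param samples n x 2 matrix of gaze points (gaussian kernel) or a list
#'   of m x 2 contour matrices (pupil-polygon kernel).
#' @param sigma_px Gaussian kernel sd in native world pixels (default 20).
#' @return the updated map.
#' @export
accumulate_samples <- function(map, samples, sigma_px = 20) {
  stopifnot(inherits(map, "uncertainty_map"))
  rc <- raster_centers(map$width, map$height, map$factor)
  if (map$kernel == "gaussian") {
    pts <- as.matrix(samples)
    for (i in seq_len(nrow(pts))) {
      cx <- pts[i, 1]; cy <- pts[i, 2]
      jx <- which(abs(rc$x - cx) <= 4 * sigma_px)
      jy <- which(abs(rc$y - cy) <= 4 * sigma_px)
      if (length(jx) == 0 || length(jy) == 0) { map$n_skipped <- map$n_skipped + 1L; next }
      kx <- exp(-((rc$x[jx] - cx)^2) / (2 * sigma_px^2))
      ky <- exp(-((rc$y[jy] - cy)^2) / (2 * sigma_px^2))
      k <- outer(ky, kx)
      map$grid[jy, jx] <- map$grid[jy, jx] + k / sum(k)
      map$n_samples <- map$n_samples + 1L
    }
  } else {
    if (!is.list(samples)) samples <- list(samples)
    for (poly in samples) {
      poly <- as.matrix(poly)
      if (nrow(poly) < 3 || abs(polygon_area(poly)) < 4) {
        map$n_skipped <- map$n_skipped + 1L
        next
      }
      jx <- which(rc$x >= min(poly[, 1]) - map$factor &
                  rc$x <= max(poly[, 1]) + map$factor)
      jy <- which(rc$y >= min(poly[, 2]) - map$factor &
                  rc$y <= max(poly[, 2]) + map$factor)
      if (length(jx) == 0 || length(jy) == 0) { map$n_skipped <- map$n_skipped + 1L; next }
      px <- rep(rc$x[jx], each = length(jy))
      py <- rep(rc$y[jy], times = length(jx))
      pin <- polygon_interior_dt(poly, px, py)
      if (!any(pin$inside) || max(pin$dt, na.rm = TRUE) <= 0) {
        map$n_skipped <- map$n_skipped + 1L
        next
      }
      k <- matrix(0, nrow = length(jy), ncol = length(jx))
      k[pin$inside] <- pin$dt[pin$inside] / max(pin$dt, na.rm = TRUE)
      map$grid[jy, jx] <- map$grid[jy, jx] + k
      map$n_samples <- map$n_samples + 1L
    }
  }
  map
}

#' Project a pupil contour into the world camera
#'
#' Maps each contour vertex through the fitted gaze mapping.  Because the
#' mapping is quadratic, contours outside the calibrated region can fold
#' onto themselves; a self-intersecting projection is flagged as folded —
#' the signature of extrapolation failure.
#'
#' @param model a `gaze_mapping`.
#' @param contour m x 2 matrix of pupil-contour vertices (m >= 5), eye
#'   pixels.
#' @return m x 2 matrix of world coordinates with logical attributes
#'   `"folded"` (self-intersection after mapping) and `"extrapolated"`
#'   (any vertex outside the calibration pupil bounding box).
#' @export
project_contour <- function(model, contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 5)
    stop_monogaze("monogaze_degenerate", "contour needs at least 5 vertices")
  est <- predict(model, contour)
  out <- est[, 1:2, drop = FALSE]
  attr(out, "extrapolated") <- any(attr(est, "extrapolated"))
  attr(out, "folded") <- polygon_self_intersects(out)
  out
}

# Does the closed polygon intersect itself?  Checks proper crossings of all
# non-adjacent edge pairs.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  ax <- x; ay <- y; bx <- x[j]; by <- y[j]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    # candidate edges k: non-adjacent to edge i
    k <- (i + 2):n
    if (i == 1) k <- k[k != n]
    if (length(k) == 0) next
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[k], ay[k])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[k], by[k])
    d3 <- cross(ax[k], ay[k], bx[k], by[k], rep(ax[i], length(k)), rep(ay[i], length(k)))
    d4 <- cross(ax[k], ay[k], bx[k], by[k], rep(bx[i], length(k)), rep(by[i], length(k)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Bump-map rendering of an accumulation map
#'
#' Renders the map as a height field under Lambertian shading from a
#' directional light, emphasizing its gradients: surface normals come from
#' central-difference gradients, the shade is the clamped cosine between
#' normal and light direction, and the output is min-max scaled to
#' `[0, 255]`.  A constant map has zero gradients everywhere and renders
#' as uniform mid-gray.
#'
#' @param map an `uncertainty_map` (or a plain numeric matrix).
#' @param light_azimuth_deg light azimuth in degrees, measured from the +x
#'   axis (default 315).
#' @param light_elevation_deg light elevation above the map plane in
#'   degrees (default 45).
#' @param z_scale height exaggeration applied before shading (default
#'   normalizes the map to peak 1 and scales by 10 cells).
#' @return numeric intensity matrix in `[0, 255]`.
#' @export
bump_render <- function(map, light_azimuth_deg = 315, light_elevation_deg = 45,
                        z_scale = NULL) {
  g <- if (inherits(map, "uncertainty_map")) map$grid else as.matrix(map)
  if (!all(is.finite(g))) stop_monogaze("monogaze_domain", "map must be finite")
  rng <- max(g) - min(g)
  if (is.null(z_scale)) z_scale <- if (rng > 0) 10 / rng else 1
  h <- g * z_scale
  ny <- nrow(h); nx <- ncol(h)
  # central differences, replicated edges
  gx <- (h[, c(2:nx, nx)] - h[, c(1, 1:(nx - 1))]) / 2
  gy <- (h[c(2:ny, ny), ] - h[c(1, 1:(ny - 1)), ]) / 2
  nz <- 1 / sqrt(gx^2 + gy^2 + 1)
  az <- light_azimuth_deg * pi / 180
  el <- light_elevation_deg * pi / 180
  l <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  shade <- pmax((-gx * l[1] - gy * l[2] + l[3]) * nz, 0)
  srng <- max(shade) - min(shade)
  if (srng == 0) return(matrix(127.5, ny, nx))
  (shade - min(shade)) / srng * 255
}

#' IDW-interpolated error map over the world raster
#'
#' Estimates the gaze-estimation error magnitude at every raster location
#' by Inverse Distance Weighting of the calibration residual vectors: each
#' cell holds the norm of the interpolated correction vector, and a cell
#' coinciding with a node holds that node's `|v_i|` (the IDW `d = 0` rule).
#'
#' @param field a `correction_field`.
#' @param width,height raster extent in native world pixels.
#' @param factor integer downsampling factor (default 4).
#' @return object of class `error_map` with `grid` (rows = y cells, px
#'   units), `width`, `height`, `factor`.
#' @export
error_map <- function(field, width = 1920, height = 1080, factor = 4) {
  stopifnot(inherits(field, "correction_field"))
  nd <- field$nodes
  rc <- raster_centers(width, height, factor)
  grid <- matrix(0, nrow = rc$ny, ncol = rc$nx)
  # chunk over rows to bound the cells x nodes distance matrix
  for (iy in seq_len(rc$ny)) {
    dx <- outer(rc$x, nd$x, "-")
    dy <- rc$y[iy] - nd$y
    d <- sqrt(sweep(dx^2, 2, dy^2, "+"))
    w <- 1 / d^field$r
    hit <- d == 0
    w[hit] <- 0
    sw <- rowSums(w)
    vx <- (w %*% nd$dx) / sw
    vy <- (w %*% nd$dy) / sw
    val <- sqrt(vx^2 + vy^2)
    if (any(hit)) {
      hr <- which(rowSums(hit) > 0)
      for (i in hr) val[i] <- sqrt(mean(nd$dx[hit[i, ]])^2 + mean(nd$dy[hit[i, ]])^2)
    }
    grid[iy, ] <- val
  }
  structure(list(grid = grid, width = width, height = height, factor = factor,
                 r = field$r),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("IDW error map %dx%d cells (factor %d): |v| in [%.4g, %.4g] px\n",
              ncol(x$grid), nrow(x$grid), x$factor, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Plot an accumulation or error map
#'
#' @param x an `uncertainty_map` or `error_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.uncertainty_map <- function(x, ...) {
  image(t(x$grid)[, rev(seq_len(nrow(x$grid)))], col = gray(seq(0, 1, length.out = 256)),
        asp = nrow(x$grid) / ncol(x$grid), axes = FALSE, ...)
  invisible(x)
}

#' @rdname plot.uncertainty_map
#' @export
plot.error_map <- plot.uncertainty_map

#' Write a map as a PNG image and a plain-text matrix
#'
#' Writes the grid twice, side by side: an 8-bit grayscale PNG (min-max
#' normalized; a constant-zero grid renders all black) and a row-major,
#' space-separated float text matrix at the same path with extension
#' `.txt`.
#'
#' @param map an `uncertainty_map`, `error_map`, or numeric matrix with
#'   finite non-negative entries.
#' @param path output PNG path; the text matrix goes to
#'   `sub("\\\\.png$", ".txt", path)`.
#' @return invisibly, `c(png = path, txt = text_path)`.
#' @export
write_map <- function(map, path) {
  g <- if (inherits(map, c("uncertainty_map", "error_map"))) map$grid else as.matrix(map)
  if (!all(is.finite(g)) || any(g < 0))
    stop_monogaze("monogaze_domain", "map grid must be finite and non-negative")
  rng <- max(g) - min(g)
  img <- if (rng > 0) (g - min(g)) / rng else matrix(0, nrow(g), ncol(g))
  ok <- try(png::writePNG(img, target = path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_monogaze("monogaze_io", paste0("cannot write map: ", path))
  txt <- sub("\\.png$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(apply(g, 1, function(r) paste(format(r, digits = 17), collapse = " ")), txt)
  invisible(c(png = path, txt = txt))
}

#' Read back the text matrix written by [write_map()]
#'
#' @param path path to the `.txt` matrix file.
#' @return numeric matrix.
#' @export
read_map_text <- function(path) {
  rows <- lapply(strsplit(readLines(path, warn = FALSE), "\\s+"), as.numeric)
  do.call(rbind, rows)
}
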