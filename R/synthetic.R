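# Synthetic ground-truth data: eye images, calibration markers, and full
# 114 Hz calibration sessions generated from a known quadratic pupil->world
# mapping, so every downstream stage can be tested without recordings.

QUAD_BASIS <- c("1", "u", "v", "u*v", "u^2", "v^2")

# Evaluate the 6-term bivariate quadratic basis at 0-based pupil pixels.
quad_design <- function(u, v) cbind(1, u, v, u * v, u^2, v^2)

#' A fixed ground-truth quadratic pupil-to-world mapping
#'
#' Returns the default ground-truth mapping used by [generate_session()]:
#' two 6-coefficient quadratic surfaces over the basis
#' `(1, u, v, uv, u^2, v^2)` taking eye-camera pupil pixels (640x480 frame)
#' to world-camera pixels (1920x1080 frame).  The map is dominated by its
#' affine part (so it is invertible over the pupil domain) with mild
#' quadratic terms of the magnitude a real eye/camera geometry produces.
#'
#' @return a list with elements `coeff_x` and `coeff_y` (named numeric
#'   vectors of length 6) of class `quad_map`.
#' @export
quadratic_truth_model <- function() {
  # Centred form x = 960 + 3.0 du + 0.20 dv + mild quadratics, du = u - 320.
  centered <- function(x0, au, av, auv, auu, avv, uc = 320, vc = 240) {
    c(x0 - au * uc - av * vc + auv * uc * vc + auu * uc^2 + avv * vc^2,
      au - auv * vc - 2 * auu * uc,
      av - auv * uc - 2 * avv * vc,
      auv, auu, avv)
  }
  m <- list(
    coeff_x = setNames(centered(960, 3.0, 0.20, 3e-5, 4e-4, -2e-4), QUAD_BASIS),
    coeff_y = setNames(centered(540, 0.15, 2.6, -2e-5, -1.5e-4, 3.5e-4), QUAD_BASIS)
  )
  class(m) <- "quad_map"
  m
}

# Evaluate a quad_map (truth or fitted coefficients on raw pixels) at pupil
# coordinates; uv is an n x 2 matrix.
eval_quad_map <- function(map, uv) {
  D <- quad_design(uv[, 1], uv[, 2])
  cbind(x = drop(D %*% map$coeff_x), y = drop(D %*% map$coeff_y))
}

# Invert a quad_map at world points m (n x 2) by Newton iteration from the
# affine-inverse start.  The default truth map is affine-dominated, so a
# handful of iterations reaches ~1e-12 px.
invert_quad_map <- function(map, m, tol = 1e-10, maxit = 50) {
  A <- rbind(map$coeff_x[2:3], map$coeff_y[2:3])      # affine Jacobian at origin
  b <- c(map$coeff_x[1], map$coeff_y[1])
  uv <- t(solve(A, t(m) - b))
  for (it in seq_len(maxit)) {
    f <- eval_quad_map(map, uv) - m
    if (max(abs(f)) < tol) break
    u <- uv[, 1]; v <- uv[, 2]
    # Jacobian entries of the quadratic surfaces.
    jxx <- map$coeff_x[2] + map$coeff_x[4] * v + 2 * map$coeff_x[5] * u
    jxy <- map$coeff_x[3] + map$coeff_x[4] * u + 2 * map$coeff_x[6] * v
    jyx <- map$coeff_y[2] + map$coeff_y[4] * v + 2 * map$coeff_y[5] * u
    jyy <- map$coeff_y[3] + map$coeff_y[4] * u + 2 * map$coeff_y[6] * v
    det <- jxx * jyy - jxy * jyx
    uv[, 1] <- u - ( jyy * f[, 1] - jxy * f[, 2]) / det
    uv[, 2] <- v - (-jyx * f[, 1] + jxx * f[, 2]) / det
  }
  colnames(uv) <- c("u", "v")
  uv
}

# Mild projective warp of world points, used to place the true pupil->world
# relation outside the quadratic family (model-mismatch mode).  strength 0 is
# the identity.
projective_warp <- function(m, strength, width = 1920, height = 1080) {
  if (strength == 0) return(m)
  xn <- (m[, 1] - width / 2) / (width / 2)
  yn <- (m[, 2] - height / 2) / (height / 2)
  w <- 1 + strength * (0.5 * xn + 0.3 * yn)
  cbind(width / 2 + (width / 2) * xn / w, height / 2 + (height / 2) * yn / w)
}

# Marker trajectories over the world frame; n samples, 0-based pixels.
marker_trajectory <- function(trajectory, n, width = 1920, height = 1080) {
  s <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  switch(trajectory,
    "grid9" = {
      fx <- c(0.2, 0.5, 0.8)
      pts <- as.matrix(expand.grid(x = fx * (width - 1), y = fx * (height - 1)))
      idx <- pmin(floor(s * 9) + 1, 9)     # equal dwell per target
      pts[idx, , drop = FALSE]
    },
    "pursuit-rect" = {
      x0 <- 0.15 * width;  x1 <- 0.85 * width
      y0 <- 0.15 * height; y1 <- 0.85 * height
      wx <- x1 - x0; wy <- y1 - y0
      per <- 2 * (wx + wy)
      d <- s * per
      x <- numeric(n); y <- numeric(n)
      a <- d < wx
      x[a] <- x0 + d[a];            y[a] <- y0
      b <- d >= wx & d < wx + wy
      x[b] <- x1;                   y[b] <- y0 + (d[b] - wx)
      cc <- d >= wx + wy & d < 2 * wx + wy
      x[cc] <- x1 - (d[cc] - wx - wy); y[cc] <- y1
      e <- d >= 2 * wx + wy
      x[e] <- x0;                   y[e] <- y1 - (d[e] - 2 * wx - wy)
      cbind(x, y)
    },
    "head-rotation" = {
      # Inward-then-outward spiral: the apparent path of a fixed marker in
      # the world camera while the head makes two rotations.
      rmax <- 0.40 * min(width, height)
      rmin <- 0.05 * min(width, height)
      r <- rmin + (rmax - rmin) * abs(1 - 2 * s)
      th <- 4 * pi * s
      cbind(width / 2 + r * cos(th), height / 2 + r * sin(th))
    },
    stop_monogaze("monogaze_domain", paste0("unknown trajectory: ", trajectory))
  )
}

#' Generate a synthetic calibration session with known ground truth
#'
#' Emulates a head-mounted tracker recording pupil/marker pairs at
#' `rate_hz` (default 114 Hz, the effective paired frame rate of the
#' modelled device).  The marker follows the named trajectory over a
#' 1920x1080 world frame; true pupil centres are obtained by inverting the
#' ground-truth quadratic map at each marker position.  Observed pupil
#' centres add (a) a slow smooth drift emulating headset slippage and
#' (b) i.i.d. Gaussian pixel noise.  Marker positions are exact stimulus
#' ground truth and carry no noise.
#'
#' @param trajectory `"head-rotation"` (spiral), `"pursuit-rect"`
#'   (rectangular smooth pursuit) or `"grid9"` (static 3x3 grid).
#' @param duration_s session length in seconds, in (0, 12].
#' @param rate_hz sampling rate, default 114.
#' @param noise_sd_px sd of Gaussian noise on pupil coordinates, px.
#' @param drift_px amplitude of the slow pupil drift, px (0 disables).
#' @param distortion projective model-mismatch strength (0 = the true
#'   relation lies exactly in the fitted quadratic family).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param true_model a `quad_map`, default [quadratic_truth_model()].
#' @param width,height world frame size in pixels.
#' @return an object of class `gaze_session`: a list with `table` (the
#'   session `data.frame`, see [read_session()]), `truth` (noiseless marker
#'   positions per row), and the generating parameters.
#' @export
generate_session <- function(trajectory = c("head-rotation", "pursuit-rect", "grid9"),
                             duration_s = 5, rate_hz = 114,
                             noise_sd_px = 1.0, drift_px = 5.0, distortion = 0,
                             seed = 1L, true_model = quadratic_truth_model(),
                             width = 1920, height = 1080) {
  trajectory <- match.arg(trajectory)
  if (!is.numeric(duration_s) || duration_s <= 0 || duration_s > 12)
    stop_monogaze("monogaze_domain", "duration_s must lie in (0, 12]")
  n <- floor(rate_hz * duration_s)
  t_ms <- as.integer(round((seq_len(n) - 1) * 1000 / rate_hz))
  marker <- marker_trajectory(trajectory, n, width, height)
  pupil_true <- invert_quad_map(true_model, projective_warp(marker, distortion,
                                                            width, height))
  with_seed(seed, {
    # Drift: two seeded low-frequency sinusoids per axis (periods ~ the
    # session and a third of it), a smooth slippage-like bias.
    ph <- runif(4, 0, 2 * pi)
    ts <- t_ms / 1000
    drift_u <- drift_px * (0.7 * sin(2 * pi * ts / duration_s + ph[1]) +
                           0.3 * sin(2 * pi * 3 * ts / duration_s + ph[2]))
    drift_v <- drift_px * (0.7 * sin(2 * pi * ts / duration_s + ph[3]) +
                           0.3 * sin(2 * pi * 3 * ts / duration_s + ph[4]))
    z <- matrix(rnorm(2 * n), ncol = 2)
    tab <- data.frame(
      timestamp_ms = t_ms,
      pupil_u = pupil_true[, 1] + drift_u + noise_sd_px * z[, 1],
      pupil_v = pupil_true[, 2] + drift_v + noise_sd_px * z[, 2],
      marker_x = marker[, 1],
      marker_y = marker[, 2]
    )
    structure(list(
      table = tab,
      truth = data.frame(timestamp_ms = t_ms, x = marker[, 1], y = marker[, 2]),
      true_model = true_model, trajectory = trajectory,
      rate_hz = rate_hz, duration_s = duration_s,
      noise_sd_px = noise_sd_px, drift_px = drift_px,
      distortion = distortion, seed = seed,
      width = width, height = height
    ), class = "gaze_session")
  })
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("Synthetic gaze session: %s, %.3g s at %g Hz (%d rows)\n",
              x$trajectory, x$duration_s, x$rate_hz, nrow(x$table)))
  cat(sprintf("  pupil noise sd %.3g px, drift %.3g px, distortion %.3g, seed %d\n",
              x$noise_sd_px, x$drift_px, x$distortion, x$seed))
  invisible(x)
}

#' Specification of a synthetic eye-camera image
#'
#' Describes a dark-pupil eye frame: a filled dark ellipse (the pupil) over
#' an iris disk over a sclera background, with an optional specular glint
#' and additive Gaussian noise.
#'
#' @param width,height image size in pixels (default 640x480).
#' @param pupil_center `(u, v)` pupil centre, 0-based pixels.
#' @param pupil_axes `(a, b)` ellipse semi-axes, px, `a >= b > 0`.
#' @param pupil_angle ellipse orientation in degrees (major axis vs. u axis).
#' @param pupil_gray,iris_gray,sclera_gray intensities in 0-255 with
#'   `pupil_gray < iris_gray < sclera_gray` and `pupil_gray <= 60`
#'   (dark-pupil regime).
#' @param glint optional `list(center = c(u, v), radius, intensity = 255)`.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param seed integer seed for the noise.
#' @return a list of class `eye_image_spec`.
#' @export
eye_image_spec <- function(width = 640, height = 480,
                           pupil_center = c(320, 240), pupil_axes = c(40, 30),
                           pupil_angle = 0,
                           pupil_gray = 20, iris_gray = 100, sclera_gray = 200,
                           glint = NULL, noise_sd = 0, seed = 1L) {
  spec <- list(width = width, height = height, pupil_center = pupil_center,
               pupil_axes = pupil_axes, pupil_angle = pupil_angle,
               pupil_gray = pupil_gray, iris_gray = iris_gray,
               sclera_gray = sclera_gray, glint = glint,
               noise_sd = noise_sd, seed = seed)
  if (!(pupil_gray < iris_gray && iris_gray < sclera_gray))
    stop_monogaze("monogaze_spec", "need pupil_gray < iris_gray < sclera_gray")
  if (pupil_gray > 60)
    stop_monogaze("monogaze_spec", "pupil_gray must be <= 60 (dark-pupil regime)")
  if (any(pupil_axes <= 0) || pupil_axes[1] < pupil_axes[2])
    stop_monogaze("monogaze_spec", "pupil_axes must satisfy a >= b > 0")
  a <- max(pupil_axes)
  if (pupil_center[1] - a < 0 || pupil_center[1] + a > width - 1 ||
      pupil_center[2] - a < 0 || pupil_center[2] + a > height - 1)
    stop_monogaze("monogaze_spec", "pupil ellipse must lie fully inside the image")
  class(spec) <- "eye_image_spec"
  spec
}

# Boolean mask of pixels (0-based centres) inside an ellipse.
ellipse_mask <- function(width, height, center, axes, angle_deg) {
  u <- matrix(rep(0:(width - 1), each = height), nrow = height)
  v <- matrix(rep(0:(height - 1), times = width), nrow = height)
  th <- angle_deg * pi / 180
  du <- u - center[1]; dv <- v - center[2]
  xr <- du * cos(th) + dv * sin(th)
  yr <- -du * sin(th) + dv * cos(th)
  (xr / axes[1])^2 + (yr / axes[2])^2 <= 1
}

#' Render a synthetic eye-camera frame
#'
#' @param spec an [eye_image_spec()].
#' @return a list of class `eye_image` with `image` (numeric matrix in
#'   `[0, 255]`, rows = v) and `truth` (the spec, echoing centre, axes and
#'   angle).
#' @export
generate_eye_image <- function(spec) {
  stopifnot(inherits(spec, "eye_image_spec"))
  w <- spec$width; h <- spec$height
  img <- matrix(spec$sclera_gray, nrow = h, ncol = w)
  iris_r <- 2.2 * max(spec$pupil_axes)
  img[ellipse_mask(w, h, spec$pupil_center, c(iris_r, iris_r), 0)] <- spec$iris_gray
  img[ellipse_mask(w, h, spec$pupil_center, spec$pupil_axes, spec$pupil_angle)] <-
    spec$pupil_gray
  if (!is.null(spec$glint))
    img[ellipse_mask(w, h, spec$glint$center,
                     rep(spec$glint$radius, 2), 0)] <-
      if (is.null(spec$glint$intensity)) 255 else spec$glint$intensity
  if (spec$noise_sd > 0)
    img <- with_seed(spec$seed,
                     pmin(pmax(img + rnorm(length(img), 0, spec$noise_sd), 0), 255))
  structure(list(image = img, truth = spec), class = "eye_image")
}

#' Render a concentric-ring calibration marker into a frame
#'
#' The marker is a thick black ring containing a white ring which encloses a
#' smaller filled black disk, with a white cross at the centre — radii in
#' 3:2:1 proportion.
#'
#' @param center `(x, y)` marker centre, 0-based world pixels.
#' @param outer_radius outer ring radius, px.
#' @param width,height frame size (default 1920x1080).
#' @param img optional existing frame matrix to draw into.
#' @param cross draw the central white cross (default `TRUE`).
#' @return numeric intensity matrix in `[0, 255]`.
#' @export
render_marker <- function(center, outer_radius, width = 1920, height = 1080,
                          img = NULL, cross = TRUE) {
  if (is.null(img)) img <- matrix(255, nrow = height, ncol = width)
  h <- nrow(img); w <- ncol(img)
  k <- outer_radius / 3
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  d2 <- (x - center[1])^2 + (y - center[2])^2
  img[d2 <= (3 * k)^2] <- 0      # outer black ring
  img[d2 <= (2 * k)^2] <- 255    # white ring
  img[d2 <= k^2] <- 0            # inner black disk
  if (cross) {
    arm <- max(1, round(k / 5))
    len <- 0.8 * k
    horiz <- abs(y - center[2]) <= arm & abs(x - center[1]) <= len
    vert  <- abs(x - center[1]) <= arm & abs(y - center[2]) <= len
    img[(horiz | vert) & d2 <= k^2] <- 255
  }
  img
}
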