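# Internal helpers shared across the pipeline.

# Classed error conditions so callers can distinguish failure modes
# (tryCatch(..., monogaze_no_pupil = )) without matching message text.
stop_monogaze <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "monogaze_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Run code with a private RNG state: the global .Random.seed is saved and
# restored so generators are deterministic without disturbing user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Images are plain numeric matrices in [0, 255], row = v (y, downward),
# column = u (x, rightward), pixel centres at 0-based integer coordinates:
# img[v + 1, u + 1] is the pixel at (u, v).  EBImage stores x as the first
# dimension, hence the transposition at the boundary.
as_ebimage <- function(img) EBImage::Image(t(img) / 255)

#' Read a grayscale image file
#'
#' Reads a PNG image and returns it as a numeric matrix of intensities in
#' `[0, 255]`, rows indexing the vertical (v) axis and columns the
#' horizontal (u) axis.  RGB input is converted to luminance.
#'
#' @param path path to a PNG file.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_monogaze("monogaze_io", paste0("no such image: ", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a * 255
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' @param img numeric matrix of intensities in `[0, 255]`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gray_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 255)
  ok <- try(png::writePNG(img / 255, target = path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_monogaze("monogaze_io", paste0("cannot write image: ", path))
  invisible(path)
}

# Euclidean norms of the rows of a 2-column matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# 0-based pixel-centre grids for a raster of the given size and integer
# downsampling factor: cell (i, j) covers factor x factor native pixels and
# its centre is returned in native pixel units.
raster_centers <- function(width, height, factor) {
  nx <- width %/% factor
  ny <- height %/% factor
  list(
    x = (seq_len(nx) - 1) * factor + (factor - 1) / 2,
    y = (seq_len(ny) - 1) * factor + (factor - 1) / 2,
    nx = nx, ny = ny
  )
}
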