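# Session tables: timestamped pupil/marker pairs stored as CSV.
#
# Column convention (one header row, comma separated, dot decimal):
#   timestamp_ms, pupil_u, pupil_v, marker_x, marker_y
# Pupil coordinates are eye-camera pixels, marker coordinates world-camera
# pixels; both 0-based with the origin at the top-left pixel centre.

SESSION_COLS <- c("timestamp_ms", "pupil_u", "pupil_v", "marker_x", "marker_y")

#' Default pipeline configuration
#'
#' Returns the configuration used across the pipeline: the IDW power `r`
#' (default 2), the Modified-IDW time window `window_ms` (default 200 ms),
#' the viewing distance `distance_cm` (default 75 cm), the world-plane scale
#' `px_per_cm`, the calibration/evaluation `split_fraction`, the RNG `seed`,
#' and the session-duration classification bounds (`short_long_threshold_s`,
#' `max_calibration_s`).
#'
#' @param ... named overrides of any default field.
#' @return a named list of class `gaze_config`.
#' @export
gaze_config <- function(...) {
  cfg <- list(
    r = 2, window_ms = 200, distance_cm = 75, px_per_cm = 25,
    split_fraction = 0.5, seed = 1L,
    short_long_threshold_s = 6, max_calibration_s = 12
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_monogaze("monogaze_config", paste0("unknown config field(s): ",
                                            paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  num <- setdiff(names(cfg), "seed")
  bad <- vapply(cfg[num], function(x) !is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0, TRUE)
  if (any(bad))
    stop_monogaze("monogaze_config", paste0("config fields must be positive scalars: ",
                                            paste(num[bad], collapse = ", ")))
  if (cfg$split_fraction >= 1)
    stop_monogaze("monogaze_config", "split_fraction must lie in (0, 1)")
  class(cfg) <- "gaze_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' The file is a flat `key: value` text file (one pair per line, `#`
#' comments allowed) whose keys mirror [gaze_config()].
#'
#' @param path path to the config file.
#' @return a `gaze_config` list.
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop_monogaze("monogaze_format", paste0("malformed config line: ", ln[bad][1]))
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(trimws(p[2])))
    if (is.na(v)) stop_monogaze("monogaze_parse",
                                paste0("non-numeric config value for '", trimws(p[1]), "'"))
    v
  })
  do.call(gaze_config, setNames(vals, vapply(kv, function(p) trimws(p[1]), "")))
}

#' Write a pipeline configuration file
#'
#' @param cfg a `gaze_config` list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste0(names(cfg), ": ", vapply(cfg, format, "")), path)
  invisible(path)
}

#' Read a session CSV of paired pupil and marker centres
#'
#' Parses the five-column session format and cleanses it: duplicated rows
#' (identical in all four coordinates at the stored 6-decimal precision) are
#' collapsed to their first occurrence, the pupil entry and its paired marker
#' entry being removed together.  The number of removed rows is reported via
#' `message()`.
#'
#' @param path path to a session CSV.
#' @return a cleansed `data.frame` with columns `timestamp_ms`, `pupil_u`,
#'   `pupil_v`, `marker_x`, `marker_y`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop_monogaze("monogaze_io", paste0("no such file: ", path))
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_monogaze("monogaze_format", conditionMessage(e))
  )
  missing <- setdiff(SESSION_COLS, names(df))
  if (length(missing))
    stop_monogaze("monogaze_format",
                  paste0("session file lacks column(s): ", paste(missing, collapse = ", ")))
  df <- df[SESSION_COLS]
  for (cn in SESSION_COLS) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[cn]])) | !nzchar(trimws(df[[cn]])))
    if (length(bad))
      stop_monogaze("monogaze_parse",
                    paste0("non-numeric value in column '", cn, "' at data row ", bad[1]))
    df[[cn]] <- v
  }
  if (nrow(df) == 0) {
    warning("empty session: header only, no samples")
    return(cleanse_session(df))
  }
  cleanse_session(df)
}

#' Remove duplicated pupil/marker pairs from a session table
#'
#' A row is a duplicate when all four coordinates agree with an earlier row
#' at 6-decimal precision; duplicates are excluded together with their pairs
#' (the whole row).  Rows are then ordered by timestamp; later rows sharing a
#' timestamp with an earlier one are dropped so that timestamps are strictly
#' increasing.  Idempotent.
#'
#' @param session a session `data.frame` (see [read_session()]).
#' @return the cleansed `data.frame`.
#' @export
cleanse_session <- function(session) {
  stopifnot(all(SESSION_COLS %in% names(session)))
  if (nrow(session) == 0) return(session[SESSION_COLS])
  key <- paste(
    sprintf("%.6f", session$pupil_u), sprintf("%.6f", session$pupil_v),
    sprintf("%.6f", session$marker_x), sprintf("%.6f", session$marker_y)
  )
  keep <- !duplicated(key)
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("cleansing removed %d duplicated pair(s) of %d", removed, nrow(session)))
  out <- session[keep, SESSION_COLS, drop = FALSE]
  out <- out[order(out$timestamp_ms), , drop = FALSE]
  tdup <- duplicated(out$timestamp_ms)
  if (any(tdup)) {
    warning(sprintf("dropped %d row(s) with repeated timestamps", sum(tdup)))
    out <- out[!tdup, , drop = FALSE]
  }
  if (!all(is.finite(as.matrix(out[SESSION_COLS]))))
    stop_monogaze("monogaze_format", "session contains non-finite coordinates")
  rownames(out) <- NULL
  out
}

#' Write a session table as CSV
#'
#' @param session a session `data.frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_session <- function(session, path) {
  stopifnot(all(SESSION_COLS %in% names(session)))
  write.csv(session[SESSION_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify a calibration session by duration
#'
#' Sessions shorter than 6 s follow the short-time calibration protocol,
#' sessions of 6-12 s the long-time protocol, and sessions over 12 s are
#' excluded from analysis.
#'
#' @param duration_s session duration in seconds (positive).
#' @param threshold_s short/long boundary, default 6 s.
#' @param max_s exclusion bound, default 12 s.
#' @return one of `"short"`, `"long"`, `"excluded"`.
#' @export
classify_session <- function(duration_s, threshold_s = 6, max_s = 12) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || !is.finite(duration_s) ||
      duration_s <= 0)
    stop_monogaze("monogaze_domain", "duration_s must be a positive number")
  if (duration_s > max_s) "excluded"
  else if (duration_s < threshold_s) "short"
  else "long"
}
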