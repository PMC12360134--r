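#' Midline sequence container
#'
#' Time-indexed dorsal-view body midlines for one trial: 200 points per
#' frame, calibrated length units (metres), points ordered snout to tail
#' tip and equally spaced in arc length.
#'
#' @param trial_id trial identifier.
#' @param fps frames per second.
#' @param body_length body length in metres; if `NULL`, inferred as the
#'   median polyline arc length.
#' @param x,y numeric matrices, frames x 200 stations, metres.
#' @param frame_labels original file frame indices (kept as labels).
#' @return An object of class `midline_sequence` with fields `x`, `y`,
#'   `time`, `fps`, `body_length`.
#' @export
midline_sequence <- function(trial_id, fps, body_length = NULL, x, y,
                             frame_labels = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 200L || ncol(y) != 200L)
    abort_field("x/y", sprintf("every frame needs exactly 200 points, got %d",
                               ncol(x)))
  if (!identical(dim(x), dim(y)))
    abort_field("x/y", "matrices must have identical dimensions")
  if (!is.finite(fps) || fps <= 0) abort_field("fps", "must be > 0")
  arcs <- vapply(seq_len(nrow(x)),
                 function(i) polyline_arclength(x[i, ], y[i, ]), 0)
  if (is.null(body_length)) body_length <- stats::median(arcs)
  bad <- abs(arcs - body_length) > 0.10 * body_length
  if (any(bad))
    warning(sprintf(
      "%d frame(s) with midline arc length deviating >10%% from body length",
      sum(bad)), call. = FALSE)
  structure(
    list(trial_id = trial_id, fps = fps, body_length = body_length,
         time = (seq_len(nrow(x)) - 1L) / fps, x = x, y = y,
         frame_labels = frame_labels %||% (seq_len(nrow(x)) - 1L)),
    class = "midline_sequence"
  )
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf("Midline sequence '%s': %d frames at %g fps, BL = %.4g m\n",
              x$trial_id, nrow(x$x), x$fps, x$body_length))
  invisible(x)
}

#' Landmark tracks container
#'
#' Per-frame positions of the four anatomical landmarks (1 snout tip,
#' 2 pectoral fin insertion, 3 pectoral fin tip, 4 pelvic fin insertion).
#' The lateral view supplies (x, z) for landmarks 1-4; the dorsal view
#' (x, y) for landmarks 2-4.  [merge_views()] fills the 3-D tracks.
#' Missing detections are `NA` and stay masked; they are never
#' interpolated by default.
#'
#' @param fps frames per second.
#' @param body_length body length in metres (used for merge tolerances).
#' @param lateral_x,lateral_z frames x 4 matrices, metres.
#' @param dorsal_x,dorsal_y frames x 3 matrices (landmarks 2-4), metres.
#' @return An object of class `landmark_tracks`.
#' @export
landmark_tracks <- function(fps, body_length, lateral_x, lateral_z,
                            dorsal_x, dorsal_y) {
  lateral_x <- as.matrix(lateral_x); lateral_z <- as.matrix(lateral_z)
  dorsal_x <- as.matrix(dorsal_x); dorsal_y <- as.matrix(dorsal_y)
  if (ncol(lateral_x) != 4L || ncol(lateral_z) != 4L)
    abort_field("lateral", "lateral view must track 4 landmarks")
  if (ncol(dorsal_x) != 3L || ncol(dorsal_y) != 3L)
    abort_field("dorsal", "dorsal view must track landmarks 2-4 (3 tracks)")
  nl <- nrow(lateral_x); nd <- nrow(dorsal_x)
  if (nl != nd) {
    warning(sprintf(
      "lateral (%d) and dorsal (%d) frame counts differ; keeping the first %d",
      nl, nd, min(nl, nd)), call. = FALSE)
    k <- min(nl, nd)
    lateral_x <- lateral_x[seq_len(k), , drop = FALSE]
    lateral_z <- lateral_z[seq_len(k), , drop = FALSE]
    dorsal_x <- dorsal_x[seq_len(k), , drop = FALSE]
    dorsal_y <- dorsal_y[seq_len(k), , drop = FALSE]
  }
  structure(
    list(fps = fps, body_length = body_length,
         lateral_x = lateral_x, lateral_z = lateral_z,
         dorsal_x = dorsal_x, dorsal_y = dorsal_y,
         merged = NULL, merge_flagged = NULL),
    class = "landmark_tracks"
  )
}

#' @export
print.landmark_tracks <- function(x, ...) {
  cat(sprintf("Landmark tracks: %d frames, 4 lateral + 3 dorsal landmarks\n",
              nrow(x$lateral_x)))
  if (!is.null(x$merged))
    cat(sprintf("  merged 3-D frames: %d (flagged: %d)\n",
                sum(stats::complete.cases(x$merged$x)),
                sum(x$merge_flagged)))
  invisible(x)
}

#' Merge orthogonal camera views into 3-D landmark tracks
#'
#' For landmarks 2-4 visible in both views, the 3-D point is
#' (mean of the two views' x, dorsal y, lateral z).  Frames where the two
#' views' streamwise coordinates disagree by more than `tolerance` are
#' flagged and excluded from the merged tracks.
#'
#' @param tracks a [landmark_tracks()] object.
#' @param tolerance maximum |x_lateral - x_dorsal| in metres; default 2%
#'   of body length.
#' @return `tracks` with `merged` (list of frames x 3 matrices `x`, `y`,
#'   `z`) and a logical `merge_flagged` vector filled in.
#' @export
merge_views <- function(tracks, tolerance = 0.02 * tracks$body_length) {
  stopifnot(inherits(tracks, "landmark_tracks"))
  lat_x <- tracks$lateral_x[, 2:4, drop = FALSE]
  dor_x <- tracks$dorsal_x
  dx <- abs(lat_x - dor_x)
  flagged <- apply(dx, 1L, function(r) any(is.finite(r) & r > tolerance))
  both <- is.finite(lat_x) & is.finite(dor_x)
  if (!any(both))
    stop("no overlapping frames between lateral and dorsal views",
         call. = FALSE)
  mx <- (lat_x + dor_x) / 2
  my <- tracks$dorsal_y
  mz <- tracks$lateral_z[, 2:4, drop = FALSE]
  drop <- !both | flagged
  mx[drop] <- NA_real_; my[drop] <- NA_real_; mz[drop] <- NA_real_
  tracks$merged <- list(x = mx, y = my, z = mz)
  tracks$merge_flagged <- flagged
  tracks
}

# ---------------------------------------------------------------------------
# delimited-text readers/writers (CurveMapper-style midlines, DLTdv-style
# landmarks); pixel coordinates on disk, metres in memory

#' Read a digitized midline file
#'
#' Expects delimited text (comma or tab, sniffed), one row per frame:
#' a frame index followed by 400 alternating x, y pixel values.
#'
#' @param path file path.
#' @param calibration metres per pixel.
#' @param fps frames per second.
#' @param trial_id,body_length passed to [midline_sequence()].
#' @return A [midline_sequence()].
#' @export
read_midlines <- function(path, calibration, fps, trial_id = basename(path),
                          body_length = NULL) {
  if (!is.finite(calibration) || calibration <= 0)
    abort_field("calibration", "must be a positive length per pixel")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- sniff_delim(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 401L)
  if (length(bad))
    stop(sprintf("midline parse error: row(s) %s have %s fields, expected 401",
                 paste(bad, collapse = ", "),
                 paste(unique(nf[bad]), collapse = "/")), call. = FALSE)
  m <- matrix(as.numeric(unlist(fields)), nrow = length(lines), byrow = TRUE)
  idx <- m[, 1L]
  if (any(diff(idx) <= 0))
    stop("midline ordering error: frame indices are not strictly increasing",
         call. = FALSE)
  coords <- m[, -1L, drop = FALSE] * calibration
  x <- coords[, seq(1L, 399L, by = 2L), drop = FALSE]
  y <- coords[, seq(2L, 400L, by = 2L), drop = FALSE]
  midline_sequence(trial_id = trial_id, fps = fps, body_length = body_length,
                   x = x, y = y, frame_labels = idx)
}

#' Write a midline sequence to delimited text
#'
#' Inverse of [read_midlines()]: full-precision values, so a file written
#' with `calibration = 1` round-trips bit-identically.
#'
#' @param midlines a [midline_sequence()].
#' @param path output path.
#' @param calibration metres per pixel used to convert back to pixels.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_midlines <- function(midlines, path, calibration = 1, sep = ",") {
  n <- nrow(midlines$x)
  rows <- character(n)
  for (i in seq_len(n)) {
    inter <- as.vector(rbind(midlines$x[i, ], midlines$y[i, ])) / calibration
    rows[i] <- paste(c(fmt_num(midlines$frame_labels[i]), fmt_num(inter)),
                     collapse = sep)
  }
  writeLines(rows, path)
  invisible(path)
}

.read_view <- function(path, n_landmarks, calibration, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- sniff_delim(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  expect <- 1L + 2L * n_landmarks
  if (any(nf != expect))
    stop(sprintf(
      "%s landmark file schema error: expected %d landmarks (%d fields), row(s) %s differ",
      what, n_landmarks, expect,
      paste(which(nf != expect), collapse = ", ")), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              nrow = length(lines), byrow = TRUE)
  coords <- m[, -1L, drop = FALSE] * calibration
  list(frame = m[, 1L],
       a = coords[, seq(1L, 2L * n_landmarks - 1L, by = 2L), drop = FALSE],
       b = coords[, seq(2L, 2L * n_landmarks, by = 2L), drop = FALSE])
}

#' Read lateral + dorsal landmark files
#'
#' Delimited text, one row per frame: frame index then x, y pixel pairs per
#' landmark (4 landmarks lateral, 3 dorsal).  Missing detections may be
#' encoded as `NaN`, `NA` or blank fields; they stay masked as `NA`.
#' When the views disagree on frame count, the overlap is kept with a
#' warning.
#'
#' @param path_lateral,path_dorsal file paths.
#' @param calibration metres per pixel (both views).
#' @param fps frames per second.
#' @param body_length body length in metres.
#' @return A [landmark_tracks()] (2-D parts only; run [merge_views()]).
#' @export
read_landmarks <- function(path_lateral, path_dorsal, calibration, fps,
                           body_length) {
  lat <- .read_view(path_lateral, 4L, calibration, "lateral")
  dor <- .read_view(path_dorsal, 3L, calibration, "dorsal")
  landmark_tracks(fps = fps, body_length = body_length,
                  lateral_x = lat$a, lateral_z = lat$b,
                  dorsal_x = dor$a, dorsal_y = dor$b)
}

#' Write landmark tracks to delimited text
#'
#' Inverse of [read_landmarks()] (bit-identical with `calibration = 1`).
#'
#' @param tracks a [landmark_tracks()].
#' @param path_lateral,path_dorsal output paths.
#' @param calibration metres per pixel.
#' @param sep field separator.
#' @return The two paths, invisibly.
#' @export
write_landmarks <- function(tracks, path_lateral, path_dorsal,
                            calibration = 1, sep = ",") {
  wv <- function(a, b, path) {
    n <- nrow(a)
    rows <- character(n)
    for (i in seq_len(n)) {
      inter <- as.vector(rbind(a[i, ], b[i, ])) / calibration
      rows[i] <- paste(c(fmt_num(i - 1L), fmt_num(inter)), collapse = sep)
    }
    writeLines(rows, path)
  }
  wv(tracks$lateral_x, tracks$lateral_z, path_lateral)
  wv(tracks$dorsal_x, tracks$dorsal_y, path_dorsal)
  invisible(c(path_lateral, path_dorsal))
}

# ---------------------------------------------------------------------------
# trial bundle: midlines.csv + landmarks_{lateral,dorsal}.csv + meta.json

#' Write a trial bundle
#'
#' Writes a trial as the canonical on-disk bundle: `midlines.csv`,
#' `landmarks_lateral.csv`, `landmarks_dorsal.csv` and a `meta.json`
#' sidecar holding the [trial_meta()] and calibration.  Synthetic and
#' digitized trials are indistinguishable on disk.
#'
#' @param trial a `swim_trial` (or list with `midlines`, `landmarks`,
#'   `meta`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_midlines(trial$midlines, file.path(dir, "midlines.csv"))
  write_landmarks(trial$landmarks,
                  file.path(dir, "landmarks_lateral.csv"),
                  file.path(dir, "landmarks_dorsal.csv"))
  meta <- trial$meta
  jsonlite::write_json(
    list(individual_id = meta$individual_id, sex = meta$sex,
         body_length = meta$body_length, speed_bl = meta$speed_bl,
         temperature = meta$temperature,
         kinematic_viscosity = meta$kinematic_viscosity,
         fps = trial$midlines$fps, calibration = 1),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a trial bundle written by [write_trial()]
#'
#' @param dir bundle directory.
#' @return A list of class `swim_trial`.
#' @export
read_trial <- function(dir) {
  meta_j <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
  meta <- trial_meta(individual_id = meta_j$individual_id,
                     body_length = meta_j$body_length,
                     speed_bl = meta_j$speed_bl,
                     sex = meta_j$sex %||% NA_character_,
                     temperature = meta_j$temperature %||% NA_real_,
                     kinematic_viscosity = meta_j$kinematic_viscosity)
  cal <- meta_j$calibration %||% 1
  midlines <- read_midlines(file.path(dir, "midlines.csv"),
                            calibration = cal, fps = meta_j$fps,
                            trial_id = basename(dir),
                            body_length = meta_j$body_length)
  landmarks <- read_landmarks(file.path(dir, "landmarks_lateral.csv"),
                              file.path(dir, "landmarks_dorsal.csv"),
                              calibration = cal, fps = meta_j$fps,
                              body_length = meta_j$body_length)
  landmarks <- merge_views(landmarks)
  structure(list(midlines = midlines, landmarks = landmarks, meta = meta),
            class = "swim_trial")
}
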