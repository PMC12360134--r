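#' Body angle over one cycle
#'
#' Pitch of the snout-tip-to-pelvic-insertion line in the lateral view:
#' per frame, `atan2(z_snout - z_pelvic, |x_snout - x_pelvic|)` in
#' degrees, positive when the snout is above the pelvic insertion.  The
#' trial value is the mean over the cycle frames; at least half of the
#' cycle frames must have both landmarks.
#'
#' @param tracks a [landmark_tracks()].
#' @param cycle a [detect_cycle()] window (`NULL` = all frames).
#' @param min_presence minimum fraction of usable cycle frames.
#' @return Mean body angle in degrees.
#' @export
body_angle <- function(tracks, cycle = NULL, min_presence = 0.5) {
  stopifnot(inherits(tracks, "landmark_tracks"))
  idx <- if (is.null(cycle)) seq_len(nrow(tracks$lateral_x)) else
    seq(cycle$start_frame, min(cycle$end_frame, nrow(tracks$lateral_x)))
  x1 <- tracks$lateral_x[idx, 1L]; z1 <- tracks$lateral_z[idx, 1L]
  x4 <- tracks$lateral_x[idx, 4L]; z4 <- tracks$lateral_z[idx, 4L]
  ok <- is.finite(x1) & is.finite(z1) & is.finite(x4) & is.finite(z4)
  if (mean(ok) < min_presence)
    stop(sprintf("body angle needs landmarks 1 and 4 in >= %.0f%% of cycle frames",
                 100 * min_presence), call. = FALSE)
  dx <- abs(x1[ok] - x4[ok]); dz <- z1[ok] - z4[ok]
  if (any(dx == 0 & dz == 0))
    stop("degenerate body axis: snout and pelvic landmarks coincide",
         call. = FALSE)
  mean(atan2(dz, dx)) * 180 / pi
}

#' Three-dimensional angle of attack over one cycle
#'
#' Inclination of the pectoral-fin-tip-to-pelvic-insertion chord relative
#' to the horizontal plane, from the merged 3-D landmark tracks: per
#' frame, `asin(dz / |chord|)` in degrees for the chord directed from the
#' pelvic insertion (landmark 4) to the pectoral tip (landmark 3), so a
#' snout-up posture gives a positive angle.  The trial value is the mean
#' over the cycle frames.
#'
#' @param tracks a [landmark_tracks()] with merged 3-D tracks (see
#'   [merge_views()]).
#' @param cycle a [detect_cycle()] window (`NULL` = all frames).
#' @param min_presence minimum fraction of usable cycle frames.
#' @return Mean angle of attack in degrees.
#' @export
angle_of_attack <- function(tracks, cycle = NULL, min_presence = 0.5) {
  stopifnot(inherits(tracks, "landmark_tracks"))
  if (is.null(tracks$merged))
    stop("merged 3-D tracks missing: run merge_views() first", call. = FALSE)
  m <- tracks$merged                     # columns are landmarks 2, 3, 4
  idx <- if (is.null(cycle)) seq_len(nrow(m$x)) else
    seq(cycle$start_frame, min(cycle$end_frame, nrow(m$x)))
  dx <- m$x[idx, 2L] - m$x[idx, 3L]      # pectoral tip minus pelvic insertion
  dy <- m$y[idx, 2L] - m$y[idx, 3L]
  dz <- m$z[idx, 2L] - m$z[idx, 3L]
  ok <- is.finite(dx) & is.finite(dy) & is.finite(dz)
  if (mean(ok) < min_presence)
    stop(sprintf(
      "angle of attack needs merged landmarks 3 and 4 in >= %.0f%% of cycle frames",
      100 * min_presence), call. = FALSE)
  nrm <- sqrt(dx[ok]^2 + dy[ok]^2 + dz[ok]^2)
  if (any(nrm == 0))
    stop("degenerate chord: pectoral tip and pelvic insertion coincide",
         call. = FALSE)
  mean(asin(dz[ok] / nrm)) * 180 / pi
}
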