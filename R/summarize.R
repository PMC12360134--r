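#' Per-trial kinematic summary
#'
#' Runs the full per-trial analysis on one trial: detects the first
#' complete tail beat cycle from the tail-tip trace, then computes tail
#' beat frequency, peak-to-peak tail amplitude, traveling-wave speed and
#' wavelength (single-frequency phase gradient), maximum midline curvature
#' and its body location, body angle, three-dimensional angle of attack,
#' fin effort, and the Reynolds and Strouhal numbers.  The Strouhal number
#' is computed as `fin_effort / speed_bl`, which equals `TBF * A / U`
#' identically when amplitude is in BL and speed in BL/s.
#'
#' Angle computations that fail (e.g. missing dorsal landmarks) yield `NA`
#' with a warning carrying the trial id; the remaining variables are still
#' reported.
#'
#' @param midlines a [midline_sequence()].
#' @param landmarks a [landmark_tracks()] (merged via [merge_views()] for
#'   the angle of attack), or `NULL` to skip both angles.
#' @param meta a [trial_meta()].
#' @param curvature_window,curvature_order Savitzky-Golay tunables, see
#'   [curvature_field()].
#' @param fit_region posterior phase-fit region, see [wave_speed()].
#' @return A one-row data frame of class `kinematic_summary` with columns
#'   `trial_id`, `individual`, `speed_bl`, `tbf` (Hz), `amplitude` (BL),
#'   `wave_speed` (BL/s), `wavelength` (BL), `k_max` (1/BL), `k_max_loc`,
#'   `fin_effort` (BL/s), `body_angle` (deg), `angle_of_attack` (deg),
#'   `reynolds`, `strouhal`.
#' @export
summarize_trial <- function(midlines, landmarks, meta,
                            curvature_window = 15L, curvature_order = 3L,
                            fit_region = c(0.50, 0.95)) {
  stopifnot(inherits(midlines, "midline_sequence"),
            inherits(meta, "trial_meta"))
  bl <- midlines$body_length
  tip <- midlines$y[, ncol(midlines$y)]
  cyc <- tryCatch(
    detect_cycle(tip, midlines$fps, body_length = bl),
    error = function(e) stop(sprintf("trial %s: %s", midlines$trial_id,
                                     conditionMessage(e)), call. = FALSE))
  tbf <- tail_beat_frequency(cyc)
  amp <- tail_amplitude(tip, cyc, bl)

  prof <- wave_phase_profile(midlines, cyc, tbf)
  wv <- wave_speed(prof, tbf, fit_region = fit_region)

  kf <- curvature_field(midlines, window = curvature_window,
                        order = curvature_order)
  mk <- max_curvature(kf, cyc)

  with_na <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("trial %s: %s unavailable (%s)", midlines$trial_id,
                      what, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }
  ba <- if (is.null(landmarks)) NA_real_ else
    with_na(body_angle(landmarks, cyc), "body angle")
  aa <- if (is.null(landmarks)) NA_real_ else
    with_na(angle_of_attack(landmarks, cyc), "angle of attack")

  fe <- fin_effort(tbf, amp)
  st <- if (meta$speed_bl > 0) fe / meta$speed_bl else NA_real_
  re <- reynolds(meta$speed_ms, meta$body_length, meta$kinematic_viscosity)

  out <- data.frame(
    trial_id = midlines$trial_id, individual = meta$individual_id,
    speed_bl = meta$speed_bl,
    tbf = tbf, amplitude = amp,
    wave_speed = wv$wave_speed, wavelength = wv$wavelength,
    k_max = mk$k_max, k_max_loc = mk$k_max_loc,
    fin_effort = fe, body_angle = ba, angle_of_attack = aa,
    reynolds = re, strouhal = st,
    stringsAsFactors = FALSE)
  class(out) <- c("kinematic_summary", "data.frame")
  out
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("Kinematic summary, trial '%s' (%.3g BL/s):\n",
              x$trial_id[1L], x$speed_bl[1L]))
  cat(sprintf("  TBF %.3g Hz  A %.3g BL  c %.3g BL/s  lambda %.3g BL\n",
              x$tbf, x$amplitude, x$wave_speed, x$wavelength))
  cat(sprintf("  k_max %.3g 1/BL at u = %.2f  fin effort %.3g BL/s\n",
              x$k_max, x$k_max_loc, x$fin_effort))
  cat(sprintf("  BA %.3g deg  AA %.3g deg  Re %.4g  St %.3g\n",
              x$body_angle, x$angle_of_attack, x$reynolds, x$strouhal))
  invisible(x)
}

#' Summarize every trial of a cohort
#'
#' @param cohort a [generate_cohort()] result (with coordinates), or a
#'   list of `swim_trial` objects.
#' @param ... passed to [summarize_trial()].
#' @return A data frame with one [summarize_trial()] row per trial.
#' @export
summarize_cohort <- function(cohort, ...) {
  trials <- if (inherits(cohort, "swim_cohort")) cohort$trials else cohort
  if (is.null(trials))
    stop("cohort has no generated coordinates; rerun generate_cohort()",
         call. = FALSE)
  rows <- lapply(trials, function(tr)
    summarize_trial(tr$midlines, tr$landmarks, tr$meta, ...))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
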