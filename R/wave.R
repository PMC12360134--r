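#' Phase profile of the body's traveling wave
#'
#' For each of the 200 arc-length stations, extracts the phase of the
#' discrete Fourier component at the tail beat frequency from that
#' station's lateral-displacement series over one cycle.  A head-to-tail
#' traveling wave shows phase decreasing linearly along the body with
#' slope `-2 * pi / wavelength` (wavelength in BL).  Stations whose
#' oscillation power at the tail beat frequency is below 1% of the tail
#' tip's are excluded.  The phase is unwrapped from the tail toward the
#' head (the tail end has the strongest, cleanest oscillation).
#'
#' @param midlines a [midline_sequence()].
#' @param cycle a [detect_cycle()] window.
#' @param tbf tail beat frequency in Hz.
#' @param min_power_frac stations with power below this fraction of the
#'   tip power are excluded (default 0.01).
#' @return An object of class `wave_phase_profile`: data frame columns
#'   `u` (arc-length fraction), `phase` (radians, unwrapped), `power`,
#'   `included`.
#' @export
wave_phase_profile <- function(midlines, cycle, tbf, min_power_frac = 0.01) {
  stopifnot(inherits(midlines, "midline_sequence"),
            inherits(cycle, "cycle_window"))
  fps <- midlines$fps
  n_cycle <- round(cycle$period * fps)
  i0 <- cycle$start_frame
  if (i0 + n_cycle - 1L > nrow(midlines$y))
    n_cycle <- nrow(midlines$y) - i0 + 1L
  idx <- seq(i0, i0 + n_cycle - 1L)
  t_rel <- (idx - idx[1L]) / fps
  w <- exp(-2i * pi * tbf * t_rel)

  yseg <- midlines$y[idx, , drop = FALSE]
  yseg <- sweep(yseg, 2L, colMeans(yseg))
  coef <- as.vector(t(yseg) %*% w)      # one complex coefficient per station
  power <- Mod(coef)^2
  phase <- Arg(coef)
  included <- power >= min_power_frac * power[length(power)]

  # unwrap from the tail toward the head over included stations
  inc_idx <- which(included)
  ph_inc <- rev(unwrap_phase(rev(phase[inc_idx])))
  phase_unwrapped <- rep(NA_real_, length(phase))
  phase_unwrapped[inc_idx] <- ph_inc

  structure(
    data.frame(u = seq(0, 1, length.out = ncol(midlines$y)),
               phase = phase_unwrapped, power = power,
               included = included),
    class = c("wave_phase_profile", "data.frame"),
    tbf = tbf
  )
}

#' Traveling-wave speed and wavelength from the phase gradient
#'
#' Fits the unwrapped phase profile against arc-length fraction by least
#' squares over a posterior fit region (default the posterior half of the
#' body excluding the final 5%, where tip digitizing noise concentrates).
#' With slope `s` (radians per BL), the wave speed is
#' `c = 2 * pi * tbf / |s|` BL/s and the wavelength `lambda = c / tbf` BL.
#' The slope must be negative (head-to-tail propagation).
#'
#' @param profile a [wave_phase_profile()].
#' @param tbf tail beat frequency in Hz.
#' @param fit_region numeric length-2, arc-length fraction bounds of the
#'   fit region (default `c(0.50, 0.95)`).
#' @param min_slope slopes with magnitude below this (radians/BL) are
#'   treated as a standing wave (default 0.5).
#' @return A list with `wave_speed` (BL/s), `wavelength` (BL), `slope`
#'   (radians/BL) and `n_stations`.
#' @export
wave_speed <- function(profile, tbf, fit_region = c(0.50, 0.95),
                       min_slope = 0.5) {
  stopifnot(inherits(profile, "wave_phase_profile"))
  sel <- profile$included & profile$u >= fit_region[1L] &
    profile$u <= fit_region[2L] & is.finite(profile$phase)
  if (sum(sel) < 10L)
    stop("insufficient data: fewer than 10 usable stations in the fit region",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, profile$u[sel]), profile$phase[sel])
  s <- fit$coefficients[[2L]]
  if (abs(s) < min_slope)
    stop("no traveling wave: phase gradient magnitude below threshold",
         call. = FALSE)
  if (s > 0)
    stop("no traveling wave: phase gradient indicates tail-to-head propagation",
         call. = FALSE)
  c_bl <- 2 * pi * tbf / abs(s)
  list(wave_speed = c_bl, wavelength = c_bl / tbf, slope = s,
       n_stations = sum(sel))
}

#' Wavelength from wave speed and tail beat frequency
#'
#' @param wave_speed_bl wave speed in BL/s.
#' @param tbf tail beat frequency in Hz.
#' @return Wavelength in BL (`c / TBF`).
#' @export
wavelength <- function(wave_speed_bl, tbf) wave_speed_bl / tbf
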