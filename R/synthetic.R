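#' Specification of a synthetic traveling-wave swimmer
#'
#' Ground-truth parameters for one simulated trial.  The dorsal-view lateral
#' displacement at arc-length fraction `u` in [0, 1] and time `t` is
#'
#'   y(u, t) = (tip_amplitude_pp / 2) * u^envelope_power *
#'             sin(2 * pi * (u / wavelength - tbf * t) + phase0) + noise
#'
#' (all lengths in BL), i.e. a posteriorly growing traveling wave moving
#' head-to-tail with wave speed `wavelength * tbf` BL/s.  The midline is
#' sampled as 200 points equally spaced in arc length, so the polyline arc
#' length is exactly one body length.  The lateral view places the four
#' anatomical landmarks on a rigid anterior axis pitched by `body_angle`,
#' and the pectoral-tip-to-pelvic-insertion chord at pitch `aa_chord_pitch`.
#'
#' @param body_length body length in metres.
#' @param tbf tail beat frequency in Hz.
#' @param tip_amplitude_pp peak-to-peak lateral excursion of the tail tip,
#'   in BL (0 < value < 1).
#' @param wavelength body wavelength in BL.
#' @param envelope_power exponent p >= 0 of the `u^p` amplitude envelope.
#' @param body_angle pitch of the snout-to-pelvic-insertion axis, degrees,
#'   positive = snout up.
#' @param aa_chord_pitch pitch of the pectoral-tip-to-pelvic-insertion
#'   chord, degrees.
#' @param fps frames per second; must give at least 10 samples per
#'   half-cycle (fps >= 20 * tbf).
#' @param duration trial duration in seconds; at least two full cycles.
#' @param noise_sd Gaussian digitizing noise SD per coordinate, in BL.
#' @param phase0 wave phase at the snout at t = 0, radians.
#' @param seed integer RNG seed; identical seeds give bit-identical trials.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(body_length = 0.16, tbf = 2.5,
                           tip_amplitude_pp = 0.16, wavelength = 0.55,
                           envelope_power = 2, body_angle = 35,
                           aa_chord_pitch = 11, fps = 250,
                           duration = NULL, noise_sd = 0,
                           phase0 = 0, seed = 1L) {
  duration <- duration %||% (2.2 / tbf)
  if (!is.finite(body_length) || body_length <= 0)
    abort_field("body_length", "must be > 0")
  if (!is.finite(tbf) || tbf <= 0) abort_field("tbf", "must be > 0")
  if (!is.finite(tip_amplitude_pp) || tip_amplitude_pp <= 0 ||
      tip_amplitude_pp >= 1)
    abort_field("tip_amplitude_pp", "must be in (0, 1) BL")
  if (!is.finite(wavelength) || wavelength <= 0)
    abort_field("wavelength", "must be > 0")
  if (!is.finite(envelope_power) || envelope_power < 0)
    abort_field("envelope_power", "must be >= 0")
  if (!is.finite(fps) || fps < 20 * tbf)
    abort_field("fps", "must be >= 20 * tbf (>= 10 samples per half-cycle)")
  if (!is.finite(duration) || duration < 2 / tbf)
    abort_field("duration", "must cover at least two full cycles (>= 2/tbf)")
  if (!is.finite(noise_sd) || noise_sd < 0)
    abort_field("noise_sd", "must be >= 0")
  structure(
    list(body_length = body_length, tbf = tbf,
         tip_amplitude_pp = tip_amplitude_pp, wavelength = wavelength,
         envelope_power = envelope_power, body_angle = body_angle,
         aa_chord_pitch = aa_chord_pitch, fps = fps, duration = duration,
         noise_sd = noise_sd, phase0 = phase0, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic swimmer spec\n")
  cat(sprintf("  TBF %.3g Hz, tip amplitude (pp) %.3g BL, wavelength %.3g BL\n",
              x$tbf, x$tip_amplitude_pp, x$wavelength))
  cat(sprintf("  envelope u^%.3g, body angle %.3g deg, chord pitch %.3g deg\n",
              x$envelope_power, x$body_angle, x$aa_chord_pitch))
  cat(sprintf("  %.3g s at %g fps, noise %.3g BL, seed %d\n",
              x$duration, x$fps, x$noise_sd, x$seed))
  invisible(x)
}

# arc-length fractions of the anatomical landmarks along the body axis
.landmark_u <- c(snout = 0, pectoral_insertion = 0.25, pelvic_insertion = 0.45)
.chord_length_bl <- 0.22   # pectoral tip -> pelvic insertion chord, BL
.fin_offset_bl <- 0.06     # lateral offset of the pectoral fin tip, BL

#' Generate one synthetic trial
#'
#' Produces the midline sequence, landmark tracks and trial metadata for a
#' simulated swimmer.  With `noise_sd = 0` every downstream kinematic
#' variable is recoverable from the output to numerical precision.
#'
#' @param spec a [synthetic_spec()].
#' @param individual_id identifier stored in the metadata.
#' @param speed_bl nominal flow speed in BL/s stored in the metadata
#'   (the generated wave itself is expressed in the body frame).
#' @param kinematic_viscosity passed to [trial_meta()].
#' @return A list of class `swim_trial` with elements `midlines`
#'   ([midline_sequence]), `landmarks` (landmark tracks with merged 3-D
#'   coordinates computable via [merge_views()]), `meta` ([trial_meta()])
#'   and `spec` (the generating spec).
#' @export
generate_trial <- function(spec, individual_id = "sim1", speed_bl = 1,
                           kinematic_viscosity = 1e-6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bl <- spec$body_length
  n_pts <- 200L
  n_fine <- 1991L                      # 10 fine steps per output station
  nt <- floor(spec$fps * spec$duration) + 1L
  t <- (seq_len(nt) - 1L) / spec$fps
  u_fine <- seq(0, 1, length.out = n_fine)

  # lateral displacement of the fine midline, metres: rows = stations
  amp <- (spec$tip_amplitude_pp / 2) * u_fine^spec$envelope_power * bl
  phase_sp <- 2 * pi * u_fine / spec$wavelength + spec$phase0
  y_fine <- amp * sin(outer(phase_sp, 2 * pi * spec$tbf * t, `-`))

  # x by integrating dx = sqrt(ds^2 - dy^2): arc length is exactly BL
  ds <- bl / (n_fine - 1L)
  dy <- y_fine[-1L, , drop = FALSE] - y_fine[-n_fine, , drop = FALSE]
  dx <- sqrt(pmax(ds^2 - dy^2, 0))
  x_fine <- rbind(0, apply(dx, 2L, cumsum))

  keep <- seq(1L, n_fine, by = 10L)    # 200 stations, equal arc spacing
  x <- t(x_fine[keep, , drop = FALSE])
  y <- t(y_fine[keep, , drop = FALSE])

  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sd * bl), nrow(x))
    y <- y + matrix(stats::rnorm(length(y), 0, spec$noise_sd * bl), nrow(y))
  }

  midlines <- midline_sequence(
    trial_id = paste0(individual_id, "_", format(speed_bl)),
    fps = spec$fps, body_length = bl, x = x, y = y)

  # landmarks on the rigid pitched anterior axis -------------------------
  ba <- spec$body_angle * pi / 180
  aa <- spec$aa_chord_pitch * pi / 180
  u_lm <- .landmark_u
  x_axis <- u_lm * bl * cos(ba)                       # streamwise
  z_axis <- (u_lm["pelvic_insertion"] - u_lm) * bl * sin(ba)  # vertical

  # dorsal-view lateral position of on-axis landmarks follows the wave
  wave_y <- function(u) {
    (spec$tip_amplitude_pp / 2) * u^spec$envelope_power * bl *
      sin(2 * pi * u / spec$wavelength + spec$phase0 - 2 * pi * spec$tbf * t)
  }
  y2 <- wave_y(u_lm[["pectoral_insertion"]])
  y4 <- wave_y(u_lm[["pelvic_insertion"]])

  # pectoral fin tip: fixed 3-D chord to the pelvic insertion with pitch aa
  dz <- .chord_length_bl * bl * sin(aa)
  dy_fin <- .fin_offset_bl * bl
  dx_fin <- -sqrt((.chord_length_bl * bl * cos(aa))^2 - dy_fin^2)
  x3 <- x_axis[["pelvic_insertion"]] + dx_fin
  y3 <- y4 + dy_fin
  z3 <- dz

  rep_col <- function(v) matrix(v, nt, 1L)
  lateral_x <- cbind(rep_col(x_axis[["snout"]]),
                     rep_col(x_axis[["pectoral_insertion"]]),
                     rep_col(x3),
                     rep_col(x_axis[["pelvic_insertion"]]))
  lateral_z <- cbind(rep_col(z_axis[["snout"]]),
                     rep_col(z_axis[["pectoral_insertion"]]),
                     rep_col(z3),
                     rep_col(z_axis[["pelvic_insertion"]]))
  dorsal_x <- lateral_x[, 2:4, drop = FALSE]
  dorsal_y <- cbind(y2, y3, y4)

  if (spec$noise_sd > 0) {
    nz <- function(m) m + matrix(stats::rnorm(length(m), 0, spec$noise_sd * bl),
                                 nrow(m))
    lateral_x <- nz(lateral_x); lateral_z <- nz(lateral_z)
    dorsal_x <- nz(dorsal_x); dorsal_y <- nz(dorsal_y)
  }

  landmarks <- landmark_tracks(fps = spec$fps, body_length = bl,
                               lateral_x = lateral_x, lateral_z = lateral_z,
                               dorsal_x = dorsal_x, dorsal_y = dorsal_y)
  landmarks <- merge_views(landmarks)

  meta <- trial_meta(individual_id = individual_id, body_length = bl,
                     speed_bl = speed_bl,
                     kinematic_viscosity = kinematic_viscosity)

  structure(list(midlines = midlines, landmarks = landmarks, meta = meta,
                 spec = spec),
            class = "swim_trial")
}

#' Reference per-speed kinematic trends
#'
#' Published per-speed means and standard deviations of tail beat frequency,
#' wave speed, fin effort and body angle for steadily swimming catsharks at
#' the 11 tested flow speeds.  Used as the default speed trends of
#' [cohort_design()] so that simulated cohorts carry a realistic
#' speed-dependence.
#'
#' @return A data frame with one row per speed and columns
#'   `speed_bl`, `tbf_mean`, `tbf_sd`, `wave_speed_mean`, `wave_speed_sd`,
#'   `fin_effort_mean`, `fin_effort_sd`, `body_angle_mean`, `body_angle_sd`.
#' @export
reference_speed_trends <- function() {
  path <- system.file("extdata", "reference_speed_trends.csv",
                      package = "undulokin", mustWork = TRUE)
  utils::read.csv(path)
}

#' Design of a simulated swimming cohort
#'
#' Describes a repeated-measures experiment: `n_individuals` animals each
#' swimming at every speed in `speeds`, minus the `(individual, speed)`
#' pairs listed in `missing`.  The default reproduces the study design of
#' 5 individuals at 11 speeds (0.5-6 BL/s) with 4 trials unusable for one
#' individual, giving 51 trials.  Speed trends (expected tail beat
#' frequency, wave speed, fin effort and body angle as functions of speed)
#' default to linear interpolation of [reference_speed_trends()].
#'
#' @param n_individuals number of animals.
#' @param speeds flow speeds in BL/s.
#' @param missing data frame with columns `individual` (index) and
#'   `speed_bl`, trials to drop.
#' @param trend_tbf,trend_wave_speed,trend_fin_effort,trend_body_angle
#'   functions speed -> expected value.
#' @param sd_between named numeric: between-individual SDs for
#'   `tbf` (Hz), `wave_speed` (BL/s), `fin_effort` (BL/s),
#'   `body_angle` (deg), `aa` (deg).
#' @param sd_within named numeric: residual trial-to-trial SDs, same names.
#' @param body_lengths individual body lengths in metres (recycled).
#' @param noise_sd digitizing noise per coordinate, BL.
#' @param fps,envelope_power passed to each trial's [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_individuals = 5L,
                          speeds = c(0.5, 0.75, 1, 1.25, 1.5, 1.75,
                                     2, 3, 4, 5, 6),
                          missing = data.frame(
                            individual = 5L,
                            speed_bl = c(0.5, 0.75, 1.75, 6)),
                          trend_tbf = NULL,
                          trend_wave_speed = NULL,
                          trend_fin_effort = NULL,
                          trend_body_angle = NULL,
                          sd_between = c(tbf = 0.20, wave_speed = 0.12,
                                         fin_effort = 0.04, body_angle = 3.0,
                                         aa = 2.0),
                          sd_within = c(tbf = 0.18, wave_speed = 0.12,
                                        fin_effort = 0.045, body_angle = 3.5,
                                        aa = 2.5),
                          body_lengths = c(0.155, 0.158, 0.160, 0.162, 0.165),
                          noise_sd = 0.001, fps = 250, envelope_power = 2,
                          seed = 1L) {
  ref <- reference_speed_trends()
  interp <- function(col) {
    xs <- ref$speed_bl; ys <- ref[[col]]
    function(s) stats::approx(xs, ys, xout = s, rule = 2)$y
  }
  design <- structure(
    list(n_individuals = as.integer(n_individuals), speeds = speeds,
         missing = missing,
         trend_tbf = trend_tbf %||% interp("tbf_mean"),
         trend_wave_speed = trend_wave_speed %||% interp("wave_speed_mean"),
         trend_fin_effort = trend_fin_effort %||% interp("fin_effort_mean"),
         trend_body_angle = trend_body_angle %||% interp("body_angle_mean"),
         sd_between = sd_between, sd_within = sd_within,
         body_lengths = rep_len(body_lengths, n_individuals),
         noise_sd = noise_sd, fps = fps, envelope_power = envelope_power,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
  if (n_individuals < 2L)
    abort_field("n_individuals", "must be >= 2")
  if (any(duplicated(speeds)))
    abort_field("speeds", "must be distinct")
  design
}

#' Number of trials a design will generate
#' @param design a [cohort_design()].
#' @return Integer trial count.
#' @export
n_trials <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n_missing <- if (is.null(design$missing)) 0L else nrow(design$missing)
  design$n_individuals * length(design$speeds) - n_missing
}

#' Generate a simulated cohort
#'
#' Draws per-individual effects and per-trial targets from the design's
#' trends and SDs, builds one [synthetic_spec()] per retained
#' (individual, speed) pair, and generates every trial.  The returned
#' ground-truth table records each trial's generative parameters; its
#' `wave_speed` column is `wavelength * tbf` exactly.
#'
#' @param design a [cohort_design()].
#' @param generate if `FALSE`, return only the ground-truth table and specs
#'   (fast, no coordinate synthesis).
#' @return A list of class `swim_cohort` with elements `trials` (list of
#'   `swim_trial`, `NULL` when `generate = FALSE`), `truth` (data frame)
#'   and `design`.
#' @export
generate_cohort <- function(design, generate = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  nind <- design$n_individuals
  sb <- design$sd_between; sw <- design$sd_within
  eff <- list(
    tbf = stats::rnorm(nind, 0, sb[["tbf"]]),
    wave_speed = stats::rnorm(nind, 0, sb[["wave_speed"]]),
    fin_effort = stats::rnorm(nind, 0, sb[["fin_effort"]]),
    body_angle = stats::rnorm(nind, 0, sb[["body_angle"]]),
    aa = stats::rnorm(nind, 0, sb[["aa"]])
  )

  grid <- expand.grid(individual = seq_len(nind),
                      speed_bl = design$speeds, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(design$missing) && nrow(design$missing)) {
    drop <- paste(design$missing$individual, design$missing$speed_bl)
    grid <- grid[!(paste(grid$individual, grid$speed_bl) %in% drop), ,
                 drop = FALSE]
  }
  grid <- grid[order(grid$individual, grid$speed_bl), , drop = FALSE]

  rows <- vector("list", nrow(grid))
  specs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ind <- grid$individual[i]; s <- grid$speed_bl[i]
    tbf <- design$trend_tbf(s) + eff$tbf[ind] +
      stats::rnorm(1, 0, sw[["tbf"]])
    if (!is.finite(tbf) || tbf <= 0)
      stop("speed trend produced non-positive tail beat frequency at speed ",
           s, " BL/s", call. = FALSE)
    ws <- design$trend_wave_speed(s) + eff$wave_speed[ind] +
      stats::rnorm(1, 0, sw[["wave_speed"]])
    ws <- max(ws, 0.3 * tbf)           # keep wavelength physical (>0.3 BL)
    fe <- design$trend_fin_effort(s) + eff$fin_effort[ind] +
      stats::rnorm(1, 0, sw[["fin_effort"]])
    amp <- min(max(fe / tbf, 0.05), 0.5)
    ba <- design$trend_body_angle(s) + eff$body_angle[ind] +
      stats::rnorm(1, 0, sw[["body_angle"]])
    aa <- 11 + eff$aa[ind] + stats::rnorm(1, 0, sw[["aa"]])
    wavelength <- ws / tbf
    bl <- design$body_lengths[ind]
    spec <- synthetic_spec(
      body_length = bl, tbf = tbf, tip_amplitude_pp = amp,
      wavelength = wavelength, envelope_power = design$envelope_power,
      body_angle = ba, aa_chord_pitch = aa, fps = design$fps,
      noise_sd = design$noise_sd, phase0 = stats::runif(1, 0, 2 * pi),
      seed = derive_seed(design$seed, i))
    specs[[i]] <- spec
    rows[[i]] <- data.frame(
      individual = paste0("ind", ind), speed_bl = s, body_length = bl,
      tbf = tbf, tip_amplitude_pp = amp, wavelength = wavelength,
      wave_speed = wavelength * tbf, fin_effort = tbf * amp,
      body_angle = ba, aa_chord_pitch = aa,
      envelope_power = design$envelope_power, noise_sd = design$noise_sd,
      fps = design$fps, phase0 = spec$phase0, seed = spec$seed)
  }
  truth <- do.call(rbind, rows)

  trials <- NULL
  if (generate) {
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      trials[[i]] <- generate_trial(
        specs[[i]], individual_id = truth$individual[i],
        speed_bl = truth$speed_bl[i])
    }
  }
  structure(list(trials = trials, truth = truth, design = design,
                 specs = specs),
            class = "swim_cohort")
}

#' @export
print.swim_cohort <- function(x, ...) {
  cat(sprintf("Simulated swimming cohort: %d trials (%d individuals x %d speeds)\n",
              nrow(x$truth), x$design$n_individuals, length(x$design$speeds)))
  if (!is.null(x$design$missing) && nrow(x$design$missing))
    cat(sprintf("  %d (individual, speed) cells missing\n",
                nrow(x$design$missing)))
  cat(if (is.null(x$trials)) "  coordinates not generated\n"
      else "  coordinates generated\n")
  invisible(x)
}
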