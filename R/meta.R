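#' Trial metadata
#'
#' Bundles the per-trial context needed to interpret digitized coordinates:
#' who swam, how long the body is, the imposed flow speed, and the water's
#' kinematic viscosity.  Speed in m/s is always derived from the speed in
#' body lengths per second (BL/s) times the body length, so the two can
#' never disagree.
#'
#' @param individual_id character or integer identifier of the animal.
#' @param body_length body length in metres (snout tip to tail tip).
#' @param speed_bl imposed flow speed in BL/s.
#' @param sex optional sex label.
#' @param temperature water temperature in degrees C (informational).
#' @param kinematic_viscosity kinematic viscosity of water in m^2/s
#'   (default 1e-6, fresh water at ~20 C).
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(individual_id, body_length, speed_bl,
                       sex = NA_character_, temperature = NA_real_,
                       kinematic_viscosity = 1e-6) {
  if (!is.finite(body_length) || body_length <= 0)
    abort_field("body_length", "must be a positive length in metres")
  if (!is.finite(speed_bl) || speed_bl < 0)
    abort_field("speed_bl", "must be a non-negative speed in BL/s")
  if (!is.finite(kinematic_viscosity) || kinematic_viscosity <= 0)
    abort_field("kinematic_viscosity", "must be > 0")
  structure(
    list(
      individual_id = as.character(individual_id),
      sex = sex,
      body_length = body_length,
      speed_bl = speed_bl,
      speed_ms = speed_bl * body_length,
      temperature = temperature,
      kinematic_viscosity = kinematic_viscosity
    ),
    class = "trial_meta"
  )
}

#' @export
print.trial_meta <- function(x, ...) {
  cat("Trial metadata\n")
  cat(sprintf("  individual: %s   body length: %.3f m\n",
              x$individual_id, x$body_length))
  cat(sprintf("  flow speed: %.3g BL/s = %.4g m/s   nu = %.3g m^2/s\n",
              x$speed_bl, x$speed_ms, x$kinematic_viscosity))
  invisible(x)
}
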