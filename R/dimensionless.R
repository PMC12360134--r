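#' Reynolds number
#'
#' `Re = U * BL / nu`: the ratio of inertial to viscous forces for a body
#' of length `BL` moving at speed `U` through water of kinematic
#' viscosity `nu`.
#'
#' @param speed_ms swimming speed U in m/s.
#' @param body_length body length in m.
#' @param viscosity kinematic viscosity in m^2/s (default 1e-6, water).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(speed_ms, body_length, viscosity = 1e-6) {
  if (any(viscosity <= 0)) abort_field("viscosity", "must be > 0")
  speed_ms * body_length / viscosity
}

#' Strouhal number
#'
#' `St = TBF * A / U`, with the tail beat frequency in Hz, the
#' peak-to-peak tail amplitude and the swimming speed in consistent
#' units.  Undulatory propulsion is most efficient for St in 0.2-0.4.
#'
#' @param tbf tail beat frequency in Hz.
#' @param amplitude peak-to-peak tail amplitude (m, or BL).
#' @param speed swimming speed (m/s, or BL/s — same unit system as
#'   `amplitude`).
#' @return Dimensionless Strouhal number.
#' @export
strouhal <- function(tbf, amplitude, speed) {
  if (any(speed <= 0)) abort_field("speed", "must be > 0 for the Strouhal number")
  tbf * amplitude / speed
}

#' Fin effort
#'
#' The product of tail beat frequency and peak-to-peak tail amplitude,
#' `TBF * A`, in BL/s: a kinematic proxy for the energetic cost of
#' undulatory swimming.  Note `St = fin_effort / speed_bl` when the
#' amplitude is in BL and the speed in BL/s.
#'
#' @param tbf tail beat frequency in Hz.
#' @param amplitude_bl peak-to-peak tail amplitude in BL.
#' @return Fin effort in BL/s.
#' @export
fin_effort <- function(tbf, amplitude_bl) tbf * amplitude_bl
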