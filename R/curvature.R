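#' Midline curvature field
#'
#' Smooths each frame's midline with a least-squares local polynomial
#' (Savitzky-Golay) filter along arc length and evaluates the signed-free
#' planar curvature
#' `kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2)`
#' by central differences on the smoothed curve.  The formula is invariant
#' to the curve parametrization, so equal-index differencing is exact up
#' to discretization error.  Curvature is returned non-dimensionalized by
#' body length (units BL^-1).  The two end stations have no central
#' difference and are `NA`.
#'
#' @param midlines a [midline_sequence()].
#' @param window Savitzky-Golay window length in stations (odd; default 15
#'   of 200).
#' @param order polynomial order (default 3).
#' @return An object of class `curvature_field`: matrix frames x 200 of
#'   curvature in BL^-1, with attribute `u` (arc-length fractions).
#' @export
curvature_field <- function(midlines, window = 15L, order = 3L) {
  stopifnot(inherits(midlines, "midline_sequence"))
  if (window %% 2L == 0L) window <- window + 1L
  nst <- ncol(midlines$x)
  bl <- midlines$body_length
  kap <- matrix(NA_real_, nrow(midlines$x), nst)
  for (i in seq_len(nrow(midlines$x))) {
    x <- midlines$x[i, ]; y <- midlines$y[i, ]
    if (any(diff(x)^2 + diff(y)^2 == 0))
      stop("degenerate geometry: duplicate consecutive midline points in frame ",
           i, call. = FALSE)
    xs <- signal::sgolayfilt(x, p = order, n = window)
    ys <- signal::sgolayfilt(y, p = order, n = window)
    j <- 2:(nst - 1L)
    xp <- (xs[j + 1L] - xs[j - 1L]) / 2
    yp <- (ys[j + 1L] - ys[j - 1L]) / 2
    xpp <- xs[j + 1L] - 2 * xs[j] + xs[j - 1L]
    ypp <- ys[j + 1L] - 2 * ys[j] + ys[j - 1L]
    kap[i, j] <- abs(xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  }
  structure(kap * bl, u = seq(0, 1, length.out = nst),
            class = "curvature_field")
}

#' Maximum curvature and its body location over one cycle
#'
#' @param field a [curvature_field()].
#' @param cycle a [detect_cycle()] window (`NULL` = all frames).
#' @return A list with `k_max` (BL^-1) and `k_max_loc` (arc-length
#'   fraction in [0, 1]).
#' @export
max_curvature <- function(field, cycle = NULL) {
  stopifnot(inherits(field, "curvature_field"))
  k <- unclass(field)
  if (!is.null(cycle)) {
    stopifnot(inherits(cycle, "cycle_window"))
    k <- k[seq(cycle$start_frame, min(cycle$end_frame, nrow(k))), ,
           drop = FALSE]
  }
  pos <- which(k == max(k, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(k_max = k[pos[1L], pos[2L]],
       k_max_loc = attr(field, "u")[pos[2L]])
}
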