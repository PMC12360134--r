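#' Detect the first complete tail beat cycle
#'
#' Detrends the tail-tip lateral-displacement trace (removing its mean and
#' any linear drift), applies a zero-phase moving-average low-pass filter,
#' and locates same-direction (upward) zero crossings with sub-frame
#' precision by linear interpolation.  Consecutive crossings alternate
#' direction, so the window from the first crossing to the third (the next
#' crossing in the same direction) spans exactly one full oscillation.
#'
#' @param tip_trace numeric vector, lateral displacement of the tail tip
#'   (metres or BL), one value per frame.
#' @param fps frames per second.
#' @param body_length body length in the units of `tip_trace` (used only
#'   to detect a degenerate flat trace); default 1 treats the trace as
#'   already BL-normalized.
#' @param nominal_freq expected tail beat frequency in Hz used to size the
#'   low-pass window (`fps / (10 * nominal_freq)` frames); if `NULL`,
#'   estimated from the dominant discrete Fourier component.
#' @return An object of class `cycle_window` with fields `start_frame`,
#'   `end_frame` (inclusive, 1-based), `t_start`, `t_end` (s, sub-frame),
#'   `period` (s) and `method`.
#' @export
detect_cycle <- function(tip_trace, fps, body_length = 1,
                         nominal_freq = NULL) {
  y <- as.numeric(tip_trace)
  n <- length(y)
  if (any(!is.finite(y)))
    stop("tip trace contains non-finite values", call. = FALSE)
  if (diff(range(y)) < 1e-6 * body_length)
    stop("degenerate tip trace: lateral excursion below 1e-6 BL",
         call. = FALSE)
  t <- (seq_len(n) - 1L) / fps

  if (is.null(nominal_freq)) {
    yc <- y - mean(y)
    sp <- Mod(stats::fft(yc))[2:floor(n / 2)]
    nominal_freq <- which.max(sp) * fps / n
  }
  lowpass <- function(v, freq) {
    w <- max(1L, round(fps / (10 * freq)))
    if (w <= 1L) return(v)
    # zero-phase moving average (symmetric kernel => no phase shift)
    if (w %% 2L == 0L) w <- w + 1L
    vs <- stats::filter(v, rep(1 / w, w), sides = 2)
    pad <- (w - 1L) %/% 2L
    vs[seq_len(pad)] <- v[seq_len(pad)]
    vs[(n - pad + 1L):n] <- v[(n - pad + 1L):n]
    as.numeric(vs)
  }
  crossings <- function(v) which(v[-n] * v[-1L] < 0 |
                                   (v[-n] == 0 & v[-1L] != 0))

  # pass 1: mean-centring only.  Same-direction crossings of a sine shift
  # equally under a constant offset, so the period estimate is unbiased
  # even over a non-integer number of cycles.
  ys <- lowpass(y - mean(y), nominal_freq)
  cr <- crossings(ys)
  if (length(cr) < 3L)
    stop("no complete cycle: fewer than 3 qualifying zero crossings",
         call. = FALSE)
  t0 <- t[cr] + (0 - ys[cr]) / (ys[cr + 1L] - ys[cr]) / fps
  f0 <- 1 / (t0[3L] - t0[1L])

  # pass 2: remove linear drift estimated jointly with the oscillation at
  # the pass-1 frequency (a plain line fit over partial cycles would soak
  # up some of the sine and bias the crossings)
  X <- cbind(1, t, cos(2 * pi * f0 * t), sin(2 * pi * f0 * t))
  beta <- stats::lm.fit(X, y)$coefficients
  yd <- y - (beta[[1L]] + beta[[2L]] * t)
  ys <- lowpass(yd, f0)

  # all zero crossings; consecutive ones alternate direction, so crossing
  # i and i+2 share a direction and bound exactly one full oscillation
  cr <- which(ys[-n] * ys[-1L] < 0 | (ys[-n] == 0 & ys[-1L] != 0))
  if (length(cr) < 3L)
    stop("no complete cycle: fewer than 3 qualifying zero crossings",
         call. = FALSE)
  # sub-frame crossing times by linear interpolation
  tc <- t[cr] + (0 - ys[cr]) / (ys[cr + 1L] - ys[cr]) / fps
  t_start <- tc[1L]; t_end <- tc[3L]
  structure(
    list(start_frame = cr[1L], end_frame = cr[3L] + 1L,
         t_start = t_start, t_end = t_end,
         period = t_end - t_start, fps = fps,
         method = "upward zero crossings of the detrended, low-passed tip trace"),
    class = "cycle_window"
  )
}

#' @export
print.cycle_window <- function(x, ...) {
  cat(sprintf("Tail beat cycle: frames %d-%d, period %.4g s (TBF %.4g Hz)\n",
              x$start_frame, x$end_frame, x$period, 1 / x$period))
  invisible(x)
}

#' Tail beat frequency from a detected cycle
#'
#' @param cycle a [detect_cycle()] result.
#' @return Frequency in Hz (`1 / period`).
#' @export
tail_beat_frequency <- function(cycle) {
  stopifnot(inherits(cycle, "cycle_window"))
  1 / cycle$period
}

#' Peak-to-peak tail amplitude over one cycle
#'
#' Maximum minus minimum lateral displacement of the tail tip within the
#' cycle window, expressed in body lengths.
#'
#' @param tip_trace tail-tip lateral displacement per frame, metres.
#' @param cycle a [detect_cycle()] result.
#' @param body_length body length in metres.
#' @return Peak-to-peak amplitude in BL.
#' @export
tail_amplitude <- function(tip_trace, cycle, body_length) {
  stopifnot(inherits(cycle, "cycle_window"))
  idx <- seq(cycle$start_frame, cycle$end_frame)
  if (cycle$end_frame > length(tip_trace) || cycle$start_frame < 1L)
    stop("cycle window lies outside the tip trace", call. = FALSE)
  seg <- tip_trace[idx]
  (max(seg) - min(seg)) / body_length
}
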