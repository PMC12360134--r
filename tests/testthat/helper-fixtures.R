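# shared fixtures, built in code

study_speeds <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 3, 4, 5, 6)

# trial table with the study's unbalanced repeated-measures layout
make_trial_table <- function(n_ind = 5L, speeds = study_speeds,
                             missing_ind5 = c(0.5, 0.75, 1.75, 6),
                             trend = function(s) rep(0, length(s)),
                             sd_ind = 1, sd_err = 1, seed = 1L,
                             noise = stats::rnorm) {
  set.seed(seed)
  d <- expand.grid(individual = paste0("i", seq_len(n_ind)),
                   speed_bl = speeds, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  if (length(missing_ind5))
    d <- d[!(d$individual == paste0("i", n_ind) &
               d$speed_bl %in% missing_ind5), , drop = FALSE]
  ind_eff <- stats::rnorm(n_ind, 0, sd_ind)
  d$y <- trend(d$speed_bl) +
    ind_eff[as.integer(sub("i", "", d$individual))] +
    noise(nrow(d)) * sd_err
  d
}

# single-frame midline sequence from bare coordinates (warnings about
# arc length are irrelevant for geometric fixtures)
make_midline_frame <- function(x, y, body_length = 1, fps = 100) {
  suppressWarnings(midline_sequence(
    "fixture", fps = fps, body_length = body_length,
    x = matrix(x, 1L, 200L, byrow = TRUE),
    y = matrix(y, 1L, 200L, byrow = TRUE)))
}

# a small, fast synthetic spec
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(tbf = 2.5, tip_amplitude_pp = 0.16, wavelength = 0.8,
                   fps = 150, noise_sd = 0, seed = 1L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}
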