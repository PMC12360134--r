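test_that("phase profile of a generated wave has slope -2*pi/wavelength", {
  for (lam in c(0.6, 1)) {
    sp <- quick_spec(wavelength = lam, fps = 250)
    tr <- generate_trial(sp)
    tip <- tr$midlines$y[, 200]
    cyc <- detect_cycle(tip, sp$fps, body_length = sp$body_length)
    prof <- wave_phase_profile(tr$midlines, cyc, tail_beat_frequency(cyc))
    sel <- prof$included & prof$u >= 0.5 & prof$u <= 0.95
    slope <- coef(lm(phase ~ u, prof[sel, ]))[[2]]
    expect_equal(slope, -2 * pi / lam, tolerance = 5e-3)
  }
})

test_that("wave speed and wavelength follow c = lambda * f", {
  run <- function(lam, f) {
    sp <- quick_spec(wavelength = lam, tbf = f, fps = 250)
    tr <- generate_trial(sp)
    cyc <- detect_cycle(tr$midlines$y[, 200], sp$fps,
                        body_length = sp$body_length)
    tbf <- tail_beat_frequency(cyc)
    wave_speed(wave_phase_profile(tr$midlines, cyc, tbf), tbf)
  }
  w <- run(1, 2.5)
  expect_equal(w$wave_speed, 2.5, tolerance = 5e-3)
  expect_equal(w$wavelength, 1, tolerance = 5e-3)
  w2 <- run(0.8, 2)
  expect_equal(w2$wave_speed, 1.6, tolerance = 5e-3)
  expect_equal(w2$wave_speed / w2$wavelength, 2, tolerance = 1e-9)
  expect_equal(wavelength(w2$wave_speed, 2), w2$wavelength)
})

test_that("a standing wave raises a no-traveling-wave error", {
  # all stations oscillate in phase: no phase gradient
  t <- seq(0, 1, by = 1 / 200)
  u <- seq(0, 1, length.out = 200)
  y <- outer(sin(2 * pi * 2.5 * t), 0.05 * u^2)
  x <- matrix(u * 0.16, length(t), 200, byrow = TRUE)
  ms <- suppressWarnings(midline_sequence("standing", 200, 0.16, x, y))
  cyc <- detect_cycle(y[, 200], 200)
  prof <- wave_phase_profile(ms, cyc, tail_beat_frequency(cyc))
  expect_error(wave_speed(prof, tail_beat_frequency(cyc)),
               "no traveling wave")
})

test_that("too few usable stations in the fit region is an error", {
  sp <- quick_spec()
  tr <- generate_trial(sp)
  cyc <- detect_cycle(tr$midlines$y[, 200], sp$fps,
                      body_length = sp$body_length)
  tbf <- tail_beat_frequency(cyc)
  prof <- wave_phase_profile(tr$midlines, cyc, tbf)
  prof$included[prof$u > 0.4] <- FALSE
  expect_error(wave_speed(prof, tbf), "insufficient")
})

test_that("wave speed estimation stays within 3% under digitizing noise", {
  rel <- vapply(1:20, function(s) {
    sp <- quick_spec(wavelength = 0.7, tbf = 2.4, noise_sd = 0.002,
                     fps = 250, seed = 100L + s)
    tr <- suppressWarnings(generate_trial(sp))
    cyc <- detect_cycle(tr$midlines$y[, 200], sp$fps,
                        body_length = sp$body_length)
    tbf <- tail_beat_frequency(cyc)
    w <- wave_speed(wave_phase_profile(tr$midlines, cyc, tbf), tbf)
    abs(w$wave_speed - 0.7 * 2.4) / (0.7 * 2.4)
  }, 0)
  expect_lt(mean(rel), 0.03)
})
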