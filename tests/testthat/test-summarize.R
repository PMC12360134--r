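test_that("noise-free trials recover every generative parameter within 1%", {
  sp <- quick_spec(tbf = 2.2, tip_amplitude_pp = 0.18, wavelength = 0.7,
                   body_angle = 33, aa_chord_pitch = 9, fps = 250)
  tr <- generate_trial(sp, speed_bl = 1.5)
  s <- summarize_trial(tr$midlines, tr$landmarks, tr$meta)
  expect_equal(s$tbf, 2.2, tolerance = 0.01)
  expect_equal(s$amplitude, 0.18, tolerance = 0.01)
  expect_equal(s$wavelength, 0.7, tolerance = 0.01)
  expect_equal(s$wave_speed, 0.7 * 2.2, tolerance = 0.01)
  expect_equal(s$body_angle, 33, tolerance = 1e-4)
  expect_equal(s$angle_of_attack, 9, tolerance = 1e-4)
})

test_that("dimensionless identities hold exactly in the summary", {
  tr <- generate_trial(quick_spec(seed = 2L), speed_bl = 1.25)
  s <- summarize_trial(tr$midlines, tr$landmarks, tr$meta)
  expect_identical(s$fin_effort, s$tbf * s$amplitude)
  expect_identical(s$strouhal, s$fin_effort / s$speed_bl)
  expect_identical(s$reynolds,
                   tr$meta$speed_ms * tr$meta$body_length /
                     tr$meta$kinematic_viscosity)
  # wave speed and wavelength derive from the same phase slope
  expect_equal(s$wave_speed, s$wavelength * s$tbf, tolerance = 1e-12)
})

test_that("missing dorsal landmarks leave AA missing but the rest computed", {
  tr <- generate_trial(quick_spec(seed = 4L))
  tr$landmarks$merged$z[] <- NA_real_
  expect_warning(
    s <- summarize_trial(tr$midlines, tr$landmarks, tr$meta),
    "angle of attack")
  expect_true(is.na(s$angle_of_attack))
  expect_false(is.na(s$tbf))
  expect_false(is.na(s$body_angle))
})

test_that("BL-normalized outputs are invariant to a global rescaling", {
  sp1 <- quick_spec(body_length = 0.16, seed = 6L)
  sp2 <- quick_spec(body_length = 0.48, seed = 6L)
  t1 <- generate_trial(sp1, speed_bl = 2)
  t2 <- generate_trial(sp2, speed_bl = 2)
  s1 <- summarize_trial(t1$midlines, t1$landmarks, t1$meta)
  s2 <- summarize_trial(t2$midlines, t2$landmarks, t2$meta)
  for (v in c("tbf", "amplitude", "wave_speed", "wavelength", "k_max",
              "k_max_loc", "fin_effort", "body_angle", "angle_of_attack",
              "strouhal"))
    expect_equal(s1[[v]], s2[[v]], tolerance = 1e-9, label = v)
  # Re is not BL-normalized: it scales with U * BL, i.e. with k^2
  expect_equal(s2$reynolds / s1$reynolds, 9, tolerance = 1e-9)
})

test_that("summarize_cohort returns one labelled row per trial", {
  d <- cohort_design(n_individuals = 2L, speeds = c(1, 2, 3),
                     missing = NULL, fps = 120, seed = 5L)
  co <- generate_cohort(d)
  sm <- summarize_cohort(co)
  expect_identical(nrow(sm), 6L)
  expect_setequal(unique(sm$individual), c("ind1", "ind2"))
  # recovered values track the ground-truth table
  expect_lt(median(abs(sm$tbf - co$truth$tbf) / co$truth$tbf), 0.02)
})
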