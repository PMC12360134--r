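test_that("generated tail-tip trace has the specified period and amplitude", {
  sp <- quick_spec(tbf = 2.5, tip_amplitude_pp = 0.16, fps = 250)
  tr <- generate_trial(sp)
  tip <- tr$midlines$y[, 200] / sp$body_length
  cyc <- detect_cycle(tip, sp$fps)
  expect_equal(cyc$period, 0.4, tolerance = 1 / sp$fps / 0.4)
  expect_equal(max(tip) - min(tip), 0.16, tolerance = 1e-3)
})

test_that("identical seeds give bit-identical trials, different seeds differ", {
  a <- suppressWarnings(generate_trial(quick_spec(noise_sd = 0.002, seed = 7L)))
  b <- suppressWarnings(generate_trial(quick_spec(noise_sd = 0.002, seed = 7L)))
  c <- suppressWarnings(generate_trial(quick_spec(noise_sd = 0.002, seed = 8L)))
  expect_identical(a$midlines$y, b$midlines$y)
  expect_identical(a$landmarks$lateral_x, b$landmarks$lateral_x)
  expect_false(identical(a$midlines$y, c$midlines$y))
})

test_that("spec invariant violations raise errors naming the field", {
  expect_error(quick_spec(tbf = -1), "tbf")
  expect_error(quick_spec(tip_amplitude_pp = 1.2), "tip_amplitude_pp")
  expect_error(quick_spec(fps = 10, tbf = 2.5), "fps")
  expect_error(quick_spec(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_spec(duration = 0.1), "duration")
})

test_that("midline arc length equals one body length and stations are equispaced", {
  tr <- generate_trial(quick_spec())
  x <- tr$midlines$x[1, ]; y <- tr$midlines$y[1, ]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  # chord sums undershoot the true arc by O(curvature^2 / n^2) only
  expect_equal(sum(seg), tr$midlines$body_length, tolerance = 1e-4)
  expect_lt(diff(range(seg)) / mean(seg), 1e-3)
})

test_that("amplitude envelope is monotone non-decreasing along the body", {
  for (p in c(0, 1, 2, 3.5)) {
    tr <- generate_trial(quick_spec(envelope_power = p))
    env <- apply(abs(tr$midlines$y), 2, max)
    # tolerance covers discrete-time sampling of the per-station maxima
    expect_true(all(diff(env) > -2e-3 * max(env)))
  }
})

test_that("default cohort design reproduces the 51-trial study layout", {
  d <- cohort_design()
  expect_identical(n_trials(d), 51L)
  expect_identical(length(d$speeds), 11L)
  co <- generate_cohort(d, generate = FALSE)
  expect_identical(nrow(co$truth), 51L)
  # one individual is missing exactly 4 speeds
  tab <- table(co$truth$individual)
  expect_setequal(as.integer(tab), c(11L, 11L, 11L, 11L, 7L))
})

test_that("cohort with no missing cells yields n_individuals x n_speeds trials", {
  d <- cohort_design(missing = NULL)
  expect_identical(n_trials(d), 55L)
  expect_identical(nrow(generate_cohort(d, generate = FALSE)$truth), 55L)
})

test_that("cohort ground truth is seed-reproducible and satisfies c = lambda * f", {
  t1 <- generate_cohort(cohort_design(seed = 11L), generate = FALSE)$truth
  t2 <- generate_cohort(cohort_design(seed = 11L), generate = FALSE)$truth
  expect_identical(t1, t2)
  expect_identical(t1$wave_speed, t1$wavelength * t1$tbf)
})

test_that("a speed trend producing non-positive TBF is rejected", {
  d <- cohort_design(trend_tbf = function(s) -s)
  expect_error(generate_cohort(d, generate = FALSE), "non-positive")
})
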