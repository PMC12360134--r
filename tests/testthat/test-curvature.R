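test_that("circular arcs recover kappa = 1/R at every interior station", {
  for (R in c(0.25, 0.5, 1, 2)) {
    th <- seq(0, 1 / R, length.out = 200)      # unit arc length
    ms <- make_midline_frame(R * cos(th), R * sin(th))
    kf <- curvature_field(ms)
    k <- unclass(kf)[1, 2:199]
    expect_lt(max(abs(k - 1 / R)) * R, 0.01)
  }
})

test_that("a straight midline has zero curvature", {
  ms <- make_midline_frame(seq(0, 1, length.out = 200), rep(0, 200))
  expect_lt(max(unclass(curvature_field(ms))[1, ], na.rm = TRUE), 1e-9)
})

test_that("sinusoidal midline peaks at kappa = a * (2*pi/lambda)^2", {
  u <- seq(0, 1, length.out = 200)
  ms <- make_midline_frame(u, 0.1 * sin(2 * pi * u))
  mk <- max_curvature(curvature_field(ms))
  expect_equal(mk$k_max, 0.1 * (2 * pi)^2, tolerance = 0.02)
  # maxima sit at the displacement peaks (u = 0.25 or 0.75)
  expect_true(min(abs(mk$k_max_loc - c(0.25, 0.75))) < 0.02)
})

test_that("curvature is reported in BL^-1 (scale invariant)", {
  u <- seq(0, 1, length.out = 200)
  for (bl in c(0.1, 0.16, 1)) {
    ms <- make_midline_frame(u * bl, 0.1 * bl * sin(2 * pi * u),
                             body_length = bl)
    mk <- max_curvature(curvature_field(ms))
    expect_equal(mk$k_max, 0.1 * (2 * pi)^2, tolerance = 0.02)
  }
})

test_that("duplicate consecutive midline points are a degenerate-geometry error", {
  x <- seq(0, 1, length.out = 200); y <- rep(0, 200)
  x[51] <- x[50]
  ms <- make_midline_frame(x, y)
  expect_error(curvature_field(ms), "degenerate geometry")
})

test_that("max_curvature respects the cycle window", {
  u <- seq(0, 1, length.out = 200)
  x <- matrix(u, 4, 200, byrow = TRUE)
  y <- rbind(matrix(0.01 * sin(2 * pi * u), 2, 200, byrow = TRUE),
             matrix(0.2 * sin(2 * pi * u), 2, 200, byrow = TRUE))
  ms <- suppressWarnings(midline_sequence("w", 100, 1, x, y))
  kf <- curvature_field(ms)
  win <- structure(list(start_frame = 1L, end_frame = 2L),
                   class = "cycle_window")
  expect_lt(max_curvature(kf, win)$k_max, 1)
  expect_gt(max_curvature(kf)$k_max, 4)
})
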