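# hand-built landmark tracks: one frame, landmarks 1-4 lateral,
# 2-4 dorsal/merged
make_tracks <- function(snout_xz, pelvic_xz, tip_xyz = c(0.1, 0, 0),
                        pelvic_y = 0) {
  lt <- landmark_tracks(
    fps = 100, body_length = 1,
    lateral_x = matrix(c(snout_xz[1], 0.05, tip_xyz[1], pelvic_xz[1]), 1),
    lateral_z = matrix(c(snout_xz[2], 0.01, tip_xyz[3], pelvic_xz[2]), 1),
    dorsal_x = matrix(c(0.05, tip_xyz[1], pelvic_xz[1]), 1),
    dorsal_y = matrix(c(0, tip_xyz[2], pelvic_y), 1))
  merge_views(lt, tolerance = 10)
}

test_that("body angle follows the snout-to-pelvic-insertion pitch", {
  expect_equal(body_angle(make_tracks(c(0, 1), c(-1, 0))), 45)
  expect_equal(body_angle(make_tracks(c(0, 0), c(-1, 0))), 0)
  expect_lt(body_angle(make_tracks(c(0, -0.3), c(-1, 0))), 0)
})

test_that("coincident snout and pelvic landmarks are degenerate", {
  expect_error(body_angle(make_tracks(c(0.3, 0.1), c(0.3, 0.1))),
               "degenerate|coincide")
})

test_that("angle of attack is the 3-D chord's elevation", {
  # chord = pectoral tip - pelvic insertion, with the pelvic point at origin
  aa_of <- function(tip) angle_of_attack(
    make_tracks(c(0, 0.5), c(0, 0), tip_xyz = tip))
  expect_equal(aa_of(c(1, 0, 0)), 0)
  expect_equal(aa_of(c(0, 0, 1)), 90)
  expect_equal(aa_of(c(1, 0, 1)), 45)
  expect_equal(aa_of(c(1, 0, -1)), -45)     # tip below insertion
})

test_that("angle of attack requires merged 3-D tracks", {
  lt <- landmark_tracks(100, 1,
                        lateral_x = matrix(c(0, 1, 2, 3), 1),
                        lateral_z = matrix(0, 1, 4),
                        dorsal_x = matrix(c(1, 2, 3), 1),
                        dorsal_y = matrix(0, 1, 3))
  expect_error(angle_of_attack(lt), "merge_views")
})

test_that("cycle-mean angles of a noise-free trial match the generator", {
  sp <- quick_spec(body_angle = 27, aa_chord_pitch = 13)
  tr <- generate_trial(sp)
  cyc <- detect_cycle(tr$midlines$y[, 200], sp$fps,
                      body_length = sp$body_length)
  expect_equal(body_angle(tr$landmarks, cyc), 27, tolerance = 1e-6)
  expect_equal(angle_of_attack(tr$landmarks, cyc), 13, tolerance = 1e-6)
})

test_that("angles need landmarks in at least half of the cycle frames", {
  sp <- quick_spec()
  tr <- generate_trial(sp)
  cyc <- detect_cycle(tr$midlines$y[, 200], sp$fps,
                      body_length = sp$body_length)
  tr$landmarks$lateral_z[, 1] <- NA_real_
  expect_error(body_angle(tr$landmarks, cyc), "50%")
})
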