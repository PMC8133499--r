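# Direct numerical checks of the per-note feature formulas on a hand-built
# performance, then the structural invariants on noisy synthetic input.

test_that("per-note log-ratio features match hand arithmetic", {
  sc <- toy_unison_score(c(60, 62, 64))     # eighths at 120 bpm: 0.25 s
  # legato right hand except a clipped middle note; steady left hand
  rh_on <- c(0.0, 0.25, 0.50)
  lh_on <- rh_on
  p <- toy_performance(
    pitch = c(60, 62, 64, 36, 38, 40),
    onset = c(rh_on, lh_on),
    dur = c(0.25, 0.125, 0.20, 0.25, 0.25, 0.25),
    vel = c(70, 70, 70, 60, 60, 60)
  )
  nf <- compute_note_features(split_hands(p, sc), p, sc)
  rh <- nf[nf$hand == "RH", ]
  expect_equal(rh$rDuration, log(c(0.25, 0.125, 0.20) / 0.25))
  expect_equal(rh$rDuration[2], -0.6931, tolerance = 1e-4)
  expect_equal(rh$rIOI, c(0, 0, NA))
  expect_equal(rh$Articulation[2], log(0.125 / 0.25))
  expect_equal(rh$Articulation[1], 0)
  # deltas are undefined on the first note, telescoping elsewhere
  expect_true(is.na(rh$rDuration_delta[1]))
  expect_equal(sum(rh$rDuration_delta, na.rm = TRUE),
               rh$rDuration[3] - rh$rDuration[1])
})

test_that("DBH records subtract left from right with the printed signs", {
  sc <- toy_unison_score(c(60, 62))
  p <- toy_performance(
    pitch = c(60, 62, 36, 38),
    onset = c(1.000, 1.250, 1.004, 1.254),
    dur = c(0.26, 0.20, 0.24, 0.20),
    vel = c(60, 64, 50, 52)
  )
  nf <- compute_note_features(split_hands(p, sc), p, sc)
  dbh <- compute_dbh(nf, sc)
  expect_equal(dbh$attack_dev, c(-0.004, -0.004))   # RH earlier => negative
  expect_equal(dbh$duration[1], 0.26 - 0.24)
  expect_equal(dbh$velocity, c(10, 12))
  expect_true(is.na(dbh$velocity_delta[1]))
  expect_equal(dbh$velocity_delta[2], 2)
})

test_that("an octave-shifted copy of one hand gives all-zero DBH values", {
  sc <- toy_unison_score(c(60, 62, 64, 65))
  on <- c(0, 0.25, 0.5, 0.75)
  p <- toy_performance(pitch = c(60, 62, 64, 65, 36, 38, 40, 41),
                       onset = c(on, on), dur = 0.22, vel = 66)
  nf <- compute_note_features(split_hands(p, sc), p, sc)
  dbh <- compute_dbh(nf, sc)
  expect_true(all(abs(dbh$duration) < 1e-12))
  expect_true(all(abs(dbh$attack_dev) < 1e-12))
  expect_true(all(abs(dbh$velocity) < 1e-12))
  expect_true(all(abs(dbh$articulation) < 1e-12, na.rm = TRUE))
})

test_that("articulation equals rDuration minus rIOI on isochronous scores", {
  for (sc in small_excerpts()) {
    p <- generate_performance(sc, group_params("amateur"), performer_seed = 21)
    nf <- compute_note_features(split_hands(p, sc), p, sc)
    ok <- !is.na(nf$rIOI)
    expect_gt(sum(ok), 50)
    expect_true(all(abs(nf$Articulation[ok] -
                          (nf$rDuration[ok] - nf$rIOI[ok])) < 1e-12))
  }
})

test_that("temporal features ignore dynamics and velocity ignores tempo", {
  sc <- small_excerpts()$hanon
  p <- generate_performance(sc, group_params("expert"), performer_seed = 3)
  fv0 <- extract_features(p, sc)
  tempo_cols <- grep("rDuration|rIOI|Articulation", names(fv0), value = TRUE)
  vel_cols <- grep("elocity", names(fv0), value = TRUE)

  louder <- as.data.frame(p)
  louder$velocity <- pmin(127, louder$velocity + 10)
  fv1 <- extract_features(piano_performance(louder), sc)
  expect_equal(fv1[tempo_cols], fv0[tempo_cols])

  slower <- as.data.frame(p)
  slower$onset_sec <- slower$onset_sec * 1.5
  slower$offset_sec <- slower$offset_sec * 1.5
  fv2 <- extract_features(piano_performance(slower), sc)
  expect_equal(fv2[vel_cols], fv0[vel_cols])
})

test_that("aggregation yields 48 Basic + 16 DBH entries with BH averaging", {
  fn <- feature_names()
  expect_length(fn, 64)
  expect_equal(sum(startsWith(fn, "DBH_")), 16)
  expect_equal(sum(!startsWith(fn, "DBH_")), 48)

  sc <- toy_unison_score(c(60, 62, 64, 65))
  on <- c(0, 0.25, 0.5, 0.75)
  p <- toy_performance(pitch = c(60, 62, 64, 65, 36, 38, 40, 41),
                       onset = c(on, on), dur = 0.2, vel = 64)
  fv <- extract_features(p, sc)
  expect_length(fv, 64)
  expect_equal(unname(fv["RH_Velocity_mean"]), 64)
  expect_equal(unname(fv["LH_Velocity_mean"]), 64)
  expect_equal(unname(fv["BH_Velocity_mean"]), 64)
  expect_equal(unname(fv["RH_Velocity_sd"]), 0)

  # BH is the average of the hand statistics, including when hands differ
  p2 <- toy_performance(pitch = c(60, 62, 64, 65, 36, 38, 40, 41),
                        onset = c(on, on), dur = 0.2,
                        vel = c(60, 60, 60, 60, 50, 50, 50, 50))
  fv2 <- extract_features(p2, sc)
  expect_equal(unname(fv2["BH_Velocity_mean"]), 55)
  expect_equal(unname(fv2["DBH_velocity_mean"]), 10)
  for (x in c("rDuration", "Velocity")) {
    for (s in c("mean", "sd")) {
      expect_equal(unname(fv2[paste0("BH_", x, "_", s)]),
                   unname((fv2[paste0("RH_", x, "_", s)] +
                             fv2[paste0("LH_", x, "_", s)]) / 2))
    }
  }
})

test_that("excerpt averaging is the element-wise mean", {
  sc <- small_excerpts()
  p1 <- generate_performance(sc$hanon, group_params("expert"), 31)
  p2 <- generate_performance(sc$scale, group_params("expert"), 31, 33)
  v1 <- extract_features(p1, sc$hanon)
  v2 <- extract_features(p2, sc$scale)
  avg <- average_excerpts(v1, v2)
  expect_equal(avg, (v1 + v2) / 2)
  expect_equal(average_excerpts(v1, v1), v1)
  zero <- v1; zero[] <- 0
  expect_equal(average_excerpts(v1, zero), v1 / 2)
})
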