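test_that("link_tracks assembles, gates and fragments tracks", {
  # two well separated particles over 10 frames -> two 10-frame tracks
  sp <- data.frame(frame = rep(0:9, 2),
                   x = c(seq(0, 0.9, 0.1), seq(20, 20.9, 0.1)),
                   y = rep(c(0, 5), each = 10))
  trks <- link_tracks(sp, frame_interval = 0.2)
  expect_length(trks, 2)
  expect_true(all(vapply(trks, function(t) length(t$x), integer(1)) == 10L))
  expect_s3_class(trks[[1]], "Trajectory")
  expect_equal(trks[[1]]$frame_interval, 0.2)

  # a 4-frame track falls under the default min_length of 5 and is dropped
  sp4 <- data.frame(frame = 0:3, x = 0:3 / 10, y = 0)
  expect_length(link_tracks(sp4, 0.2), 0)

  # a missing detection splits a 12-frame track; no gap bridging
  spg <- data.frame(frame = c(0:4, 6:11), x = c(0:4, 6:11) / 10, y = 0)
  frag <- link_tracks(spg, 0.2)
  expect_length(frag, 2)
  expect_setequal(vapply(frag, function(t) length(t$x), integer(1)),
                  c(5L, 6L))

  # displacements beyond the gate start a new track
  spj <- data.frame(frame = 0:9, x = c(rep(0, 5), rep(10, 5)), y = 0)
  expect_length(link_tracks(spj, 0.2, max_displacement_um = 1), 2)

  # duplicate coordinates in one frame warn about the tie break
  spd <- data.frame(frame = c(0, 1, 1, 2:5),
                    x = c(0, 0.1, 0.1, 2:5 / 10), y = 0)
  expect_warning(link_tracks(spd, 0.2), "duplicate")
})

test_that("msd_paper matches the hand example and a brute-force oracle", {
  tr <- trajectory("t1", c(0, 1, 2), c(0, 0, 0), frame_interval = 1)
  mp <- msd_paper(tr)
  expect_equal(mp$value, c(1, 2))
  expect_equal(mp$lag_s, c(1, 2))
  expect_equal(mp$variant, "paper")

  # invariant under rotation about the first point
  th <- 0.7
  tr_rot <- trajectory("t1", cos(th) * tr$x - sin(th) * tr$y,
                       sin(th) * tr$x + cos(th) * tr$y, 1)
  expect_equal(msd_paper(tr_rot)$value, mp$value)

  # a stationary track has an all-zero curve
  tr0 <- trajectory("s", rep(2, 8), rep(-1, 8), 0.2)
  expect_true(all(msd_paper(tr0)$value == 0))

  # agrees with an independently coded oracle on a random walk
  withr::with_seed(13, {
    x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  })
  trr <- trajectory("r", x, y, 0.5)
  expect_lt(max(abs(msd_paper(trr)$value - oracle_msd_paper(x, y))), 1e-12)

  expect_error(msd_paper(trajectory("x", 1, 1, 1)), "at least 2")
})

test_that("msd_standard is the time-averaged MSD and is rigid-motion invariant", {
  tr <- trajectory("t1", c(0, 1, 2), c(0, 0, 0), frame_interval = 1)
  ms <- msd_standard(tr)
  expect_equal(ms$value, c(1, 4))
  expect_equal(ms$variant, "standard")

  withr::with_seed(14, {
    x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
  })
  tra <- trajectory("a", x, y, 0.2)
  th <- -1.1
  trb <- trajectory("b", 3 + cos(th) * x - sin(th) * y,
                    -7 + sin(th) * x + cos(th) * y, 0.2)
  expect_equal(msd_standard(trb)$value, msd_standard(tra)$value)
})

test_that("estimate_D recovers exact slopes in both conventions", {
  lag <- seq(0.2, 1.6, by = 0.2)
  std <- msd_curve_from(lag, 4 * 0.05 * lag + 0.01)
  est <- estimate_D(std)
  expect_equal(est$D, 0.05)
  expect_equal(est$intercept, 0.01)
  expect_equal(est$r_squared, 1)

  pap <- structure(list(variant = "paper", lag_s = lag, value = 0.03 * lag,
                        frame_interval = 0.2), class = "MSDCurve")
  expect_equal(estimate_D(pap)$D, 0.03)  # paper mode: D is the raw slope

  # a flat curve gives D = 0 (and negative slopes are clipped to 0)
  expect_equal(estimate_D(msd_curve_from(lag, rep(0, 8)))$D, 0)
  expect_equal(estimate_D(msd_curve_from(lag, 1 - lag))$D, 0)
  expect_error(estimate_D(msd_curve_from(lag[1:2], c(1, 2))), "fewer")
})

test_that("detect_plateau flags saturating curves and ignores lines", {
  lag <- seq(0.2, 3, by = 0.2)
  # pure line through the origin: no plateau
  expect_null(detect_plateau(msd_curve_from(lag, 0.2 * lag)))
  # flat zero curve: plateau at the first lag
  expect_equal(detect_plateau(msd_curve_from(lag, rep(0, length(lag)))),
               0.2)
  # exponential saturation 0.25 * (1 - exp(-t / 0.3)): localized at 0.6 s
  sat <- msd_curve_from(lag, 0.25 * (1 - exp(-lag / 0.3)))
  expect_equal(detect_plateau(sat), 0.6)
  expect_error(detect_plateau(msd_curve_from(lag[1:5], lag[1:5])),
               "at least 6")
})

test_that("classify_motility applies the published class boundaries", {
  expect_equal(classify_motility(0.057), "diffusive")
  expect_equal(classify_motility(0.021, plateau_time = 0.8), "confined")
  expect_equal(classify_motility(0.005), "stationary")
  # confined label requires the plateau; high-D without plateau is diffusive
  expect_equal(classify_motility(0.021), "diffusive")
  expect_error(classify_motility(-0.1), "non-negative")
})

test_that("analyze_trajectory and segment_states work end to end", {
  tr <- simulate_trajectory(motion_model("brownian", D = 0.06,
                                         sigma_loc = 0.02),
                            frame_interval = 0.2, n_frames = 60, seed = 42)
  row <- analyze_trajectory(tr)
  expect_equal(row$class, "diffusive")
  expect_gt(row$D_standard, 0.02)
  expect_true(is.na(row$plateau_s))

  # a homogeneous track yields a single segment and no change points
  seg <- segment_states(tr)
  expect_equal(nrow(seg$segments), 1)
  expect_length(seg$change_points_s, 0)
  expect_equal(seg$segments$start_s, 0)
  expect_equal(seg$segments$end_s, (60 - 1) * 0.2)

  short <- simulate_trajectory(motion_model("brownian", D = 0.05,
                                            sigma_loc = 0.02),
                               0.2, 12, seed = 1)
  expect_error(segment_states(short), "too short")

  rows <- analyze_tracks(list(tr, short))
  expect_equal(nrow(rows), 2)
  expect_true(is.na(rows$n_segments[2]))
  expect_equal(rows$n_segments[1], 1)
})
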