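test_that("synthetic stacks honour their ground truth tables", {
  sim <- simulate_nuclei_stack(
    n_nuclei = 2, radius_range = c(2, 2.5), shape = c(30, 140, 140),
    voxel_size = c(0.2, 0.1, 0.1),
    focus_channels = list(terra = focus_channel_spec(n_range = c(2, 4))),
    seed = 11)
  expect_s3_class(sim$stack, "ImageStack3D")
  expect_equal(sim$stack$channel_names, c("dna", "terra"))
  expect_equal(nrow(sim$nuclei), 2)
  expect_true(all(sim$foci$nucleus_id %in% sim$nuclei$nucleus_id))
  # nuclear foci sit inside their nucleus sphere
  i <- match(sim$foci$nucleus_id, sim$nuclei$nucleus_id)
  d <- sqrt((sim$foci$x_um - sim$nuclei$x_um[i])^2 +
            (sim$foci$y_um - sim$nuclei$y_um[i])^2 +
            (sim$foci$z_um - sim$nuclei$z_um[i])^2)
  expect_true(all(d <= sim$nuclei$r_um[i] + 1e-9))
  expect_true(all(sim$foci$rendered_mass > 0))
  # nuclei do not overlap
  dd <- dist(sim$nuclei[, c("x_um", "y_um", "z_um")])
  expect_true(all(dd > sum(sim$nuclei$r_um) * 0.9))

  # same seed, same stack; different seed, different stack
  sim2 <- simulate_nuclei_stack(
    n_nuclei = 2, radius_range = c(2, 2.5), shape = c(30, 140, 140),
    voxel_size = c(0.2, 0.1, 0.1),
    focus_channels = list(terra = focus_channel_spec(n_range = c(2, 4))),
    seed = 11)
  expect_identical(sim2$stack$voxels, sim$stack$voxels)
  expect_identical(sim2$foci, sim$foci)
})

test_that("zone-biased focus placement converges to the requested bias", {
  pts <- sample_focus_positions(c(0, 0, 0), 1, 6000,
                                zone_probs = c(0.1, 0.2, 0.7),
                                convention = "equal_area", seed = 3)
  rho <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  zones <- assign_zone(rho, convention = "equal_area")
  frac <- tabulate(zones, 3) / length(zones)
  expect_equal(frac, c(0.1, 0.2, 0.7), tolerance = 0.05)
})

test_that("brownian trajectories have the prescribed increment variance", {
  trks <- simulate_tracks(50, motion_model("brownian", D = 0.05,
                                           sigma_loc = 0),
                          frame_interval = 0.2, n_frames = 100, seed = 5)
  inc <- unlist(lapply(trks, function(tr) c(diff(tr$x), diff(tr$y))))
  expect_equal(var(inc), 2 * 0.05 * 0.2, tolerance = 0.05)
  expect_equal(mean(inc), 0, tolerance = 0.002)
})

test_that("stationary and confined models respect their geometry", {
  tr0 <- simulate_trajectory(motion_model("stationary", sigma_loc = 0),
                             0.2, 30, seed = 1)
  expect_true(all(tr0$x == tr0$x[1]) && all(tr0$y == tr0$y[1]))

  trc <- simulate_trajectory(motion_model("confined", D = 0.1, R = 0.5,
                                          sigma_loc = 0.02),
                             0.2, 600, seed = 2)
  dmax <- max(sqrt((trc$x - trc$x[1])^2 + (trc$y - trc$y[1])^2))
  expect_lte(dmax, 0.5 + 3 * 0.02 + 2 * 0.02)  # R + noise on both endpoints
})

test_that("switching models need segment durations matching the track", {
  segs <- list(list(kind = "brownian", D = 0.05, duration = 15),
               list(kind = "stationary", duration = 14.8))
  m <- motion_model("switching", sigma_loc = 0.02, segments = segs)
  tr <- simulate_trajectory(m, 0.2, 150, seed = 3)
  expect_length(tr$x, 150)
  bad <- list(list(kind = "brownian", D = 0.05, duration = 5),
              list(kind = "stationary", duration = 5))
  expect_error(simulate_trajectory(
    motion_model("switching", sigma_loc = 0, segments = bad), 0.2, 150,
    seed = 1), "duration")
})

test_that("zero-noise Ct tables encode the expression model exactly", {
  ct <- simulate_ct_table(
    expression = list(wt = c(telo = 1), mut = c(telo = 4)),
    efficiency = 1, housekeeping = "hk", n_replicates = 3,
    noise_sd = 0, baseline_ct = 15, seed = 1)
  expect_s3_class(ct, "CtTable")
  expect_setequal(unique(ct$role), c("target", "housekeeping"))
  # expression 4 with perfect doubling is exactly 2 cycles earlier
  wt_t <- ct$ct[ct$sample == "wt" & ct$role == "target"]
  mut_t <- ct$ct[ct$sample == "mut" & ct$role == "target"]
  expect_equal(unique(wt_t), 15)
  expect_equal(unique(mut_t), 13)
  expect_equal(unique(ct$ct[ct$role == "housekeeping"]), 15)
  # reproducible under a seed even with noise
  a <- simulate_ct_table(list(wt = c(telo = 2)), noise_sd = 0.2, seed = 4)
  b <- simulate_ct_table(list(wt = c(telo = 2)), noise_sd = 0.2, seed = 4)
  expect_identical(a, b)
})
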