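test_that("otsu threshold separates a bimodal image", {
  withr::with_seed(1, {
    v <- c(rnorm(4000, 100, 10), rnorm(1000, 600, 30))
  })
  thr <- terrafoci:::otsu_threshold(v)
  expect_gt(thr, 120)
  expect_lt(thr, 550)
  expect_true(is.na(terrafoci:::otsu_threshold(rep(3, 100))))
})

test_that("3D connected components count and separate objects", {
  m <- array(FALSE, c(6, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE
  m[5, 8:9, 8:9] <- TRUE
  lab <- terrafoci:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == 1), 8)
  expect_equal(sum(lab == 2), 4)
  # diagonal voxels connect under 26- but not 6-connectivity
  d <- array(FALSE, c(3, 3, 3))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(max(terrafoci:::label_components(d, connectivity = 26)), 1)
  expect_equal(max(terrafoci:::label_components(d, connectivity = 6)), 2)
})

test_that("equal-volume sphere fit recovers a digital ball radius", {
  vs <- c(0.2, 0.1, 0.1)
  dim3 <- c(40, 120, 120)
  iz <- slice.index(array(0, dim3), 1)
  iy <- slice.index(array(0, dim3), 2)
  ix <- slice.index(array(0, dim3), 3)
  zz <- (iz - 0.5) * vs[1]; yy <- (iy - 0.5) * vs[2]; xx <- (ix - 0.5) * vs[3]
  r_true <- 2.5
  mask <- (zz - 4)^2 + (yy - 6)^2 + (xx - 6)^2 <= r_true^2
  fit <- fit_nucleus_sphere(mask, vs)
  expect_lt(abs(fit$r_um - r_true), max(vs) / 2)  # within half a voxel
  expect_lt(max(abs(fit$centroid - c(6, 6, 4))), max(vs) / 2)
})

test_that("touching nuclei are split by the watershed markers", {
  vs <- c(0.2, 0.1, 0.1)
  dim3 <- c(36, 128, 128)
  vox <- array(100, dim3)
  iz <- slice.index(vox, 1); iy <- slice.index(vox, 2); ix <- slice.index(vox, 3)
  zz <- (iz - 0.5) * vs[1]; yy <- (iy - 0.5) * vs[2]; xx <- (ix - 0.5) * vs[3]
  for (ctr in list(c(3.6, 5, 5), c(3.6, 5, 8.6))) {  # 3.6 um apart, r = 2
    vox <- vox + 400 * ((zz - ctr[1])^2 + (yy - ctr[2])^2 +
                          (xx - ctr[3])^2 <= 4)
  }
  st <- image_stack(array(vox, c(1, dim3)), vs, "dna")
  nuc <- segment_nuclei(st, "dna", run_config())
  expect_equal(nrow(nuc$table), 2)
  expect_equal(sort(nuc$table$x_um), c(5, 8.6), tolerance = 0.05)
  expect_equal(nuc$table$r_um, c(2, 2), tolerance = 0.05)
  # without watershed the fused blob stays one object
  nuc1 <- segment_nuclei(st, "dna", run_config(detection = list(watershed = FALSE)))
  expect_equal(nrow(nuc1$table), 1)
})

test_that("radial position and zones follow the sphere geometry", {
  ntab <- data.frame(nucleus_id = 1, x_um = 0, y_um = 0, z_um = 0, r_um = 2)
  foci <- data.frame(focus_id = 1:2, nucleus_id = 1,
                     x_um = c(1, 0), y_um = 0, z_um = c(0, 2.4))
  rp <- radial_position(foci, ntab)
  expect_equal(rp$d_center_um, c(1, 2.4))
  expect_equal(rp$d_edge_um, c(1, -0.4))   # negative outside the sphere
  expect_equal(rp$rho, c(0.5, 1))          # the outside focus is clamped
  expect_equal(rp$rho_clamped, c(FALSE, TRUE))

  b <- sqrt(c(1, 2) / 3)
  expect_equal(assign_zone(c(0, b[1] - 1e-9, b[1] + 1e-9, b[2] + 1e-9, 1)),
               c(3L, 3L, 2L, 1L, 1L))
  expect_equal(assign_zone(0.9, convention = "equal_volume"), 1L)
  expect_error(assign_zone(1.2), "rho")

  foci <- data.frame(zone = c(1, 1, 2, 3, NA))
  zf <- zone_fractions(foci)
  expect_equal(unname(zf), c(50, 25, 25))
  expect_error(zone_fractions(data.frame(zone = NA)), "no zoned foci")
})

test_that("foci are detected, measured and zoned on a synthetic stack", {
  sim <- simulate_nuclei_stack(
    n_nuclei = 2, radius_range = c(2, 2.5), shape = c(30, 150, 150),
    voxel_size = c(0.2, 0.1, 0.1),
    focus_channels = list(terra = focus_channel_spec(
      n_range = c(3, 5), amplitude_range = c(120, 200))),
    seed = 21)
  res <- quantify_stack(sim$stack, dna_channel = "dna",
                        config = run_config(seed = 21))
  expect_equal(nrow(res$nuclei$table), 2)
  expect_true(all(c("focus_id", "x_um", "volume_um3", "integrated_density",
                    "compartment", "rho", "zone") %in% names(res$foci)))
  # every true focus has a detection within 0.35 um (matched greedily)
  truth <- sim$foci
  found <- res$foci
  dmat <- sqrt(outer(truth$x_um, found$x_um, `-`)^2 +
               outer(truth$y_um, found$y_um, `-`)^2 +
               outer(truth$z_um, found$z_um, `-`)^2)
  expect_true(all(apply(dmat, 1, min) < 0.35))
  expect_equal(nrow(found), nrow(truth))
  # intensities track the rendered truth
  j <- apply(dmat, 1, which.min)
  rel <- found$integrated_density[j] / truth$rendered_mass - 1
  expect_lt(abs(median(rel)), 0.1)
  expect_true(all(found$compartment == "nuclear"))
  expect_true(all(found$zone %in% 1:3))
  # summary aggregates per nucleus
  expect_equal(res$summary$n_nuclei, 2)
  expect_equal(res$summary$n_foci, nrow(found))
})

test_that("cytoplasmic foci are classified outside nuclei", {
  sim <- simulate_nuclei_stack(
    n_nuclei = 2, radius_range = c(2, 2.2), shape = c(30, 150, 150),
    voxel_size = c(0.2, 0.1, 0.1),
    focus_channels = list(terra = focus_channel_spec(
      n_range = c(3, 3), amplitude_range = c(150, 200),
      compartment = "cytoplasmic")),
    seed = 31)
  nuc <- segment_nuclei(sim$stack, "dna", run_config())
  foci <- detect_foci(sim$stack, "terra", nuc, restrict_to_nuclei = FALSE,
                      config = run_config())
  expect_gt(nrow(foci), 0)
  expect_true(mean(foci$compartment == "cytoplasmic") > 0.8)
  expect_true(all(is.na(foci$zone[foci$compartment == "cytoplasmic"])))
})
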