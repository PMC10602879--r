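test_that("match_objects pairs greedily one-to-one within nuclei", {
  # two A foci, two B foci in one nucleus; volumes give r ~ 0.2485 um each
  v <- 4 / 3 * pi * 0.2485^3
  fa <- data.frame(focus_id = 1:2, nucleus_id = 1,
                   x_um = c(0, 2), y_um = 0, z_um = 0, volume_um3 = v)
  fb <- data.frame(focus_id = 1:2, nucleus_id = 1,
                   x_um = c(0.3, 5), y_um = 0, z_um = 0, volume_um3 = v)
  pr <- match_objects(fa, fb)
  expect_s3_class(pr, "ColocPairs")
  expect_equal(nrow(pr), 2)
  # A1-B1 is the closest candidate and wins; A2 is left with B2
  expect_equal(pr$focus_b[pr$focus_a == 1], 1)
  expect_equal(pr$focus_b[pr$focus_a == 2], 2)
  expect_equal(pr$center_distance_um, c(0.3, 3))
  # colocalized iff distance <= sum of equal-volume radii (~0.497)
  expect_equal(pr$colocalized, c(TRUE, FALSE))
  expect_equal(pr$d_max_um, rep(2 * 0.2485, 2), tolerance = 1e-6)

  # tolerance relaxes the criterion
  pr2 <- match_objects(fa, fb, tolerance_um = 3)
  expect_true(all(pr2$colocalized))

  # an A focus with no B focus in its nucleus stays unmatched
  fa2 <- rbind(fa, data.frame(focus_id = 3, nucleus_id = 2, x_um = 0,
                              y_um = 0, z_um = 0, volume_um3 = v))
  pr3 <- match_objects(fa2, fb)
  row3 <- pr3[pr3$focus_a == 3, ]
  expect_true(is.na(row3$focus_b))
  expect_false(row3$colocalized)

  # missing measured columns / volumes are errors
  expect_error(match_objects(fa[, -6], fb), "volume_um3")
  fa_na <- fa; fa_na$volume_um3[1] <- NA
  expect_error(match_objects(fa_na, fb), "volume")
})

test_that("equal-volume radius inverts the sphere volume", {
  r <- terrafoci:::equal_volume_radius(4 / 3 * pi * 0.4^3)
  expect_equal(r, 0.4)
})

test_that("shuffle null gives calibrated p-values on independent channels", {
  nuclei <- make_nuclei_table(60, r_um = 2.5, seed = 101)
  withr::with_seed(202, {
    fa <- make_random_foci(nuclei, per_nuc = 2)
    fb <- make_random_foci(nuclei, per_nuc = 4)
  })
  pairs <- match_objects(fa, fb)
  expect_error(shuffle_null(pairs, fa, fb, nuclei, n_shuffles = 10), "19")
  pairs <- shuffle_null(pairs, fa, fb, nuclei, n_shuffles = 49, seed = 7)
  expect_true(all(pairs$p_shuffle >= 1 / 50 - 1e-12))
  expect_true(all(pairs$p_shuffle <= 1))
  # independent channels: significant fraction near alpha, not wildly above
  expect_lt(mean(pairs$significant), 0.12)
  # deterministic under the seed
  pairs2 <- shuffle_null(match_objects(fa, fb), fa, fb, nuclei,
                         n_shuffles = 49, seed = 7)
  expect_identical(pairs2$p_shuffle, pairs$p_shuffle)
})

test_that("coincident foci are significant and classified telomeric", {
  nuclei <- make_nuclei_table(12, r_um = 2.5, seed = 5)
  withr::with_seed(6, fa <- make_random_foci(nuclei, per_nuc = 1))
  fb <- fa  # exact coincidence
  fb$focus_id <- seq_len(nrow(fb)) + 1000L
  pairs <- match_objects(fa, fb)
  expect_true(all(pairs$colocalized))
  pairs <- shuffle_null(pairs, fa, fb, nuclei, n_shuffles = 99, seed = 3)
  expect_true(all(pairs$p_shuffle == 1 / 100))
  expect_true(all(pairs$significant))
  cls <- classify_telomeric(fa, pairs)
  expect_equal(unname(cls$summary["telomeric"]), 100)
  expect_true(all(cls$labels$label == "telomeric"))
})

test_that("signal correlation is Spearman over significant pairs", {
  nuclei <- make_nuclei_table(10, r_um = 2.5, seed = 8)
  withr::with_seed(9, fa <- make_random_foci(nuclei, per_nuc = 1))
  fb <- fa
  fb$focus_id <- fa$focus_id + 500L
  # monotone but non-linear relation between the two intensity metrics
  fa$integrated_density <- seq_len(nrow(fa))
  fb$integrated_density <- exp(seq_len(nrow(fb)))
  pairs <- shuffle_null(match_objects(fa, fb), fa, fb, nuclei,
                        n_shuffles = 99, seed = 2)
  sc <- signal_correlation(pairs, fa, fb)
  expect_equal(sc$estimate, 1)
  expect_equal(sc$n, nrow(fa))
  expect_false(sc$undefined)

  # zero-variance metric is flagged undefined, not an error
  fb$integrated_density <- 7
  sc0 <- signal_correlation(pairs, fa, fb)
  expect_true(sc0$undefined)
  expect_true(is.na(sc0$estimate))

  # too few significant pairs is an error
  few <- pairs[1:2, ]
  expect_error(signal_correlation(few, fa, fb), "fewer than 3")
})
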