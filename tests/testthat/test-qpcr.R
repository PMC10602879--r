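test_that("primer efficiency converts the standard-curve slope", {
  ld <- c(0, -1, -2, -3)
  # perfect doubling: slope -1/log10(2)
  fit <- primer_efficiency(ld, 20 - ld / log10(2))
  expect_equal(fit$slope, -1 / log10(2))
  expect_equal(fit$e_percent, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # 90 % efficiency round trip
  s90 <- -1 / log10(1.9)
  fit90 <- primer_efficiency(ld, 20 + s90 * ld)
  expect_equal(fit90$e_percent, 90, tolerance = 1e-9)
  expect_error(primer_efficiency(c(0, -1), c(20, 23)), "at least 3")
})

test_that("delta_ct combines replicate means and errors", {
  t_ct <- c(20.1, 19.9, 20.0)
  hk_ct <- c(18.0, 18.2, 17.8)
  dc <- delta_ct(t_ct, hk_ct)
  expect_equal(dc$delta_ct, mean(t_ct) - mean(hk_ct))
  expect_equal(dc$e, sqrt(var(t_ct) + var(hk_ct)))

  # two housekeeping genes: average of means, variance of the average
  hk2 <- list(a = c(18, 18.2), b = c(16, 16.4))
  dc2 <- delta_ct(t_ct, hk2)
  expect_equal(dc2$delta_ct, 20 - (18.1 + 16.2) / 2)
  expect_equal(dc2$e, sqrt(var(t_ct) + (var(hk2$a) + var(hk2$b)) / 4))

  expect_error(delta_ct(20, hk_ct), "at least 2")
})

test_that("relative expression propagates errors in both modes", {
  re <- rel_expression(2, 0.36, error_mode = "paper")
  expect_equal(re$rel_expr, 0.25)
  expect_equal(re$i, 0.045)  # e * 2^-dCt / dCt = 0.36 * 0.25 / 2, exactly

  rc <- rel_expression(2, 0.36, error_mode = "corrected")
  expect_equal(rc$i, log(2) * 0.36 * 0.25)

  # the verbatim formula is singular at delta_ct = 0; corrected mode is not
  expect_error(rel_expression(0, 0.2, error_mode = "paper"), "singular")
  expect_equal(rel_expression(0, 0.2)$i, log(2) * 0.2)
})

test_that("fold changes normalize to the reference sample", {
  res <- data.frame(sample = c("wt", "mut"), primer = "telo",
                    rel_expr = c(0.25, 1))
  fc <- fold_change(res, "wt")
  expect_equal(fc$fold_change, c(1, 4))
  expect_error(fold_change(res, "nope"), "missing reference")
})

test_that("zero-noise Ct tables round-trip fold changes exactly", {
  ct <- simulate_ct_table(
    expression = list(wt = c(telo = 1, other = 1),
                      mut = c(telo = 4, other = 0.5)),
    efficiency = 1, housekeeping = "hk", n_replicates = 3,
    noise_sd = 0, baseline_ct = 15, seed = 2)
  res <- qpcr_analysis(ct, reference = "wt")
  telo <- res[res$primer == "telo", ]
  expect_equal(telo$rel_expr[telo$sample == "wt"], 1)
  expect_equal(telo$fold_change[telo$sample == "mut"], 4)
  other <- res[res$primer == "other", ]
  expect_equal(other$rel_expr[other$sample == "mut"], 0.5)
  expect_equal(res$e, rep(0, nrow(res)))
  # paper error mode fails loudly on the wt sample where delta_ct = 0
  expect_error(qpcr_analysis(ct, reference = "wt", error_mode = "paper"),
               "singular")
})
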