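mk_summary <- function(n_red, n_blue, n_coloc, area_px2 = 512^2) {
  # build a coloc_summary with the requested counts
  red <- cbind(seq_len(max(n_red, 1)) * 10, 1)[seq_len(n_red), , drop = FALSE]
  blue <- cbind(seq_len(max(n_blue, 1)) * 10, 1)[seq_len(n_blue), , drop = FALSE]
  blue[, 1] <- blue[, 1] + 5          # off by 5 px: no match
  if (n_coloc > 0) {
    blue[seq_len(n_coloc), 1] <- red[seq_len(n_coloc), 1]
    blue[seq_len(n_coloc), 2] <- 2    # off by 1 px: matched
  }
  m <- match_spots(red, blue, d_max_px = 3)
  stopifnot(nrow(m$pairs) == n_coloc)
  coloc_summary(m, n_red, n_blue, area_px2, pixel_size_um = 0.325)
}

test_that("summarize_well sums fields and reports densities per mm^2", {
  s1 <- mk_summary(10, 8, 4)
  s2 <- mk_summary(6, 6, 2)
  w <- summarize_well(list(s1, s2), dilution_factor = 100,
                      well_id = "A1", sample_id = "PD_01")
  expect_s3_class(w, "well_summary")
  expect_identical(w$n_fields, 2L)
  expect_identical(w$total_red, 16L)
  expect_identical(w$total_coloc, 6L)
  area <- 2 * 512^2 * (0.325e-3)^2
  expect_equal(w$total_area_mm2, area)
  expect_equal(w$density_coloc, 6 / area)
  expect_equal(w$mean_coloc_per_field, 3)
  expect_identical(w$dilution_factor, 100)
  expect_error(summarize_well(list()), class = "dualspot_param_error")
  expect_error(summarize_well(list(1)), class = "dualspot_param_error")
})

test_that("standard_series validates structure", {
  expect_error(standard_series(c(1, 2, 3), 1:3, 1:3),
               class = "dualspot_param_error")  # not decreasing
  expect_error(standard_series(c(1, 0.2), c(5, 1, 1), c(0, 0)),
               class = "dualspot_param_error")  # length mismatch
  expect_error(standard_series(c(1, 0.2), c(5, -1), c(0, 0)),
               class = "dualspot_param_error")
  s <- standard_series(c(1, 0.2, 0.04), c(500, 100, 20), c(1, 0, 0),
                       standard_type = "alpha_syn_only", blank_red = 1)
  expect_s3_class(s, "standard_series")
})

test_that("dilution_linearity recovers exact closed-form slopes", {
  s <- standard_series(c(1, 0.2, 0.04), c(500, 100, 20), c(0, 0, 0))
  fit <- dilution_linearity(s)
  expect_equal(fit$slope, 1)
  expect_true(fit$monotone)
  expect_equal(fit$r_squared, 1)
  flat <- standard_series(c(1, 0.2, 0.04), c(7, 7, 7), c(0, 0, 0))
  expect_equal(dilution_linearity(flat)$slope, 0)
  # blue channel selection
  sb <- standard_series(c(1, 0.2, 0.04), c(1, 1, 1), c(250, 50, 10))
  expect_equal(dilution_linearity(sb, channel = "blue")$slope, 1)
})

test_that("min_count excludes sub-quantitation steps from the fit", {
  # ideal 5x series except the last step sits on a false-count floor
  s <- standard_series(c(1, 0.2, 0.04, 0.008, 0.0016),
                       c(625, 125, 25, 5, 5), c(0, 0, 0, 0, 0))
  naive <- dilution_linearity(s)
  loq <- dilution_linearity(s, min_count = 6)
  expect_lt(naive$slope, 0.95)     # floor flattens the naive fit
  expect_equal(loq$slope, 1)
  expect_identical(loq$n_used, 3L)
  expect_error(dilution_linearity(s, min_count = 600),
               class = "dualspot_param_error")  # < 3 steps left
})

test_that("non-monotone counts are reported", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008), c(500, 600, 20, 4),
                       c(0, 0, 0, 0))
  expect_false(dilution_linearity(s)$monotone)
})

test_that("clean monotone standards pass batch QC", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6),
                       rep(0, 4), standard_type = "alpha_syn_only")
  v <- qc_batch(s)
  expect_s3_class(v, "qc_verdict")
  expect_true(v$passed)
  expect_length(v$reasons, 0)
})

test_that("Poisson-level inversions below the blank floor do not fail QC", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008, 0.0016, 0.00032),
                       c(800, 160, 32, 6, 0, 1), rep(0, 6),
                       blank_red = 0)
  expect_true(qc_batch(s)$passed)
})

test_that("shuffled standards fail with poor_standard_curve", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008), c(160, 800, 6, 32),
                       rep(0, 4))
  v <- qc_batch(s)
  expect_false(v$passed)
  expect_true("poor_standard_curve" %in% v$reasons)
})

test_that("a top standard at the blank level fails QC", {
  s <- standard_series(c(1, 0.2, 0.04), c(5, 3, 2), c(0, 0, 0),
                       blank_red = 5)
  v <- qc_batch(s)
  expect_false(v$passed)
  expect_true("poor_standard_curve" %in% v$reasons)
})

test_that("heavy blue signal on an alpha-syn-only standard is bleed-through", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6),
                       c(400, 80, 16, 3), standard_type = "alpha_syn_only")
  v <- qc_batch(s)
  expect_false(v$passed)
  expect_identical(v$reasons, "amylin_bleedthrough")
  # the same counts on a co-aggregate standard are expected signal
  s2 <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6),
                        c(400, 80, 16, 3), standard_type = "coaggregate")
  expect_true(qc_batch(s2)$passed)
  # and 5% blue is tolerated on the alpha-syn-only standard
  s3 <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6),
                        c(40, 8, 2, 0), standard_type = "alpha_syn_only")
  expect_true(qc_batch(s3)$passed)
})

test_that("qc_thresholds are applied", {
  s <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6),
                       c(40, 8, 2, 0), standard_type = "alpha_syn_only")
  strict <- qc_thresholds(max_bleedthrough_frac = 0.01)
  expect_false(qc_batch(s, strict)$passed)
  expect_error(qc_thresholds(min_rank_corr = 2),
               class = "dualspot_param_error")
})
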