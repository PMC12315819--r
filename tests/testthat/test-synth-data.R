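test_that("field_params validates its inputs and names the offending field", {
  err <- expect_error(field_params(width_px = 8), class = "dualspot_param_error")
  expect_match(conditionMessage(err), "width_px")
  expect_error(field_params(lambda_pair = -1), class = "dualspot_param_error")
  expect_error(field_params(psf_sigma_px = 0), class = "dualspot_param_error")
  expect_error(field_params(shot_noise = "yes"), class = "dualspot_param_error")
})

test_that("default field parameters sit at peak SNR 10", {
  expect_equal(peak_snr(field_params()), 10)
})

test_that("generate_field is deterministic in params + seed", {
  p <- field_params(width_px = 64, height_px = 64, lambda_pair = 5,
                    lambda_red_only = 3, lambda_blue_only = 3, seed = 11)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$field$red_image, b$field$red_image)
  expect_identical(a$field$blue_image, b$field$blue_image)
  expect_identical(a$truth$red_centers, b$truth$red_centers)
  p2 <- field_params(width_px = 64, height_px = 64, lambda_pair = 5,
                     lambda_red_only = 3, lambda_blue_only = 3, seed = 12)
  expect_false(identical(generate_field(p2)$field$red_image,
                         a$field$red_image))
})

test_that("generate_field does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_field(field_params(width_px = 64, height_px = 64,
                                        seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("generated field has the declared shape, range and truth", {
  p <- field_params(width_px = 96, height_px = 64, lambda_pair = 8,
                    lambda_red_only = 4, lambda_blue_only = 2, seed = 21)
  fg <- generate_field(p)
  img <- fg$field$red_image
  expect_identical(dim(img), c(64L, 96L))
  expect_true(is.integer(img))
  expect_true(all(img >= 0 & img <= 65535))
  tr <- fg$truth
  n_pair <- nrow(tr$pair_index)
  expect_true(n_pair <= min(nrow(tr$red_centers), nrow(tr$blue_centers)))
  expect_equal(tr$coloc_fraction, n_pair / nrow(tr$red_centers))
  # all centers are inside the 3-sigma border margin
  m <- 3 * p$psf_sigma_px
  cen <- rbind(tr$red_centers, tr$blue_centers)
  expect_true(all(cen[, 1] >= m & cen[, 1] <= 96 - 1 - m))
  expect_true(all(cen[, 2] >= m & cen[, 2] <= 64 - 1 - m))
  # paired blue spots sit close to their red partners (jitter sd 1 px)
  if (n_pair > 0) {
    dd <- sqrt(rowSums((tr$red_centers[tr$pair_index[, 1], , drop = FALSE] -
                          tr$blue_centers[tr$pair_index[, 2], , drop = FALSE])^2))
    expect_true(all(dd < 6))
  }
})

test_that("zero spot rates give a pure-background field with empty truth", {
  p <- field_params(width_px = 64, height_px = 64, lambda_pair = 0,
                    lambda_red_only = 0, lambda_blue_only = 0, seed = 31)
  fg <- generate_field(p)
  expect_identical(nrow(fg$truth$red_centers), 0L)
  expect_identical(nrow(fg$truth$pair_index), 0L)
  expect_equal(fg$truth$coloc_fraction, 0)
  # background level ~100 with shot + read noise
  expect_lt(abs(mean(fg$field$red_image) - 100), 2)
})

test_that("dilution series scales rates by fold^-step with derived seeds", {
  base <- field_params(width_px = 64, height_px = 64, lambda_pair = 20,
                       lambda_red_only = 10, lambda_blue_only = 10, seed = 41)
  ser <- generate_dilution_series(base, fold = 5, steps = 4)
  expect_length(ser, 4)
  expect_equal(vapply(ser, `[[`, numeric(1), "rel_conc"), 5^-(0:3))
  expect_equal(vapply(ser, `[[`, numeric(1), "step"), 0:3)
  ser2 <- generate_dilution_series(base, fold = 5, steps = 4)
  expect_identical(ser[[3]]$field$red_image, ser2[[3]]$field$red_image)
  # steps are independent draws, not rescaled copies
  expect_false(identical(ser[[1]]$field$red_image, ser[[2]]$field$red_image))
  expect_error(generate_dilution_series(base, fold = 1),
               class = "dualspot_param_error")
})

test_that("generate_cohort is reproducible with the declared shape", {
  cp <- cohort_params(n_per_group = 6, seed = 51)
  tab <- generate_cohort(cp)
  expect_s3_class(tab, "cohort_table")
  expect_identical(nrow(tab), 12L)
  expect_identical(sort(unique(tab$group)), c("HC", "PD"))
  expect_true(all(c("alpha_syn_count", "coagg_count", "HbA1c_pct") %in%
                    names(tab)))
  reads <- attr(tab, "readouts")
  expect_identical(nrow(reads), 12L * 12L)  # 2 replicates x 6 readouts each
  expect_identical(tab, generate_cohort(cp))
  # per-sample count is the mean of that sample's 12 readouts
  s1 <- tab$sample_id[1]
  expect_equal(tab$coagg_count[1],
               mean(reads$coagg_count[reads$sample_id == s1]))
})

test_that("cohort covariate attains the requested rank correlation", {
  cp <- cohort_params(n_per_group = 400, covariate_rank_corr = 0.6, seed = 61)
  tab <- generate_cohort(cp)
  r <- cor(tab$coagg_count, tab$HbA1c_pct, method = "spearman")
  expect_lt(abs(r - 0.6), 0.08)
  cp0 <- cohort_params(n_per_group = 400, covariate_rank_corr = 0, seed = 62)
  r0 <- cor(generate_cohort(cp0)$coagg_count,
            generate_cohort(cp0)$HbA1c_pct, method = "spearman")
  expect_lt(abs(r0), 0.1)
})

test_that("PD group means exceed HC in the default design", {
  tab <- generate_cohort(cohort_params(n_per_group = 200, seed = 71))
  expect_gt(mean(tab$coagg_count[tab$group == "PD"]),
            mean(tab$coagg_count[tab$group == "HC"]))
})

test_that("simulate_sensorgram matches the closed-form model exactly", {
  kp <- kinetic_params(5809, 2.136e-3, 100)
  sg <- simulate_sensorgram(kp, conc = 4e-7, t_assoc = 300, t_dissoc = 200)
  expect_equal(sg$response,
               langmuir_response(sg$t, 4e-7, kp$ka, kp$kd, kp$Rmax, 300))
  # a long association phase approaches Req = Rmax C / (C + KD)
  long <- simulate_sensorgram(kp, 4e-7, t_assoc = 5000, t_dissoc = 10)
  req <- 100 * 4e-7 / (4e-7 + kp$KD)
  expect_lt(abs(long$response[long$t == 5000] - req) / req, 0.01)
  # noisy simulation is seed-deterministic
  a <- simulate_sensorgram(kp, 4e-7, 300, 200, noise_sd = 1, seed = 7)
  b <- simulate_sensorgram(kp, 4e-7, 300, 200, noise_sd = 1, seed = 7)
  expect_identical(a, b)
})

test_that("derive_seed is deterministic, varied, and in the valid range", {
  s <- vapply(0:200, function(k) derive_seed(123, k), integer(1))
  expect_identical(s, vapply(0:200, function(k) derive_seed(123, k),
                             integer(1)))
  expect_gt(length(unique(s)), 195)
  expect_true(all(s >= 1 & s <= 2^31 - 2))
})
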