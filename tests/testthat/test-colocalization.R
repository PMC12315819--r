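test_that("match_spots pairs nearby spots and respects the radius", {
  red <- cbind(c(10, 50), c(10, 50))
  blue <- cbind(c(11, 90), c(10, 90))
  m <- match_spots(red, blue, d_max_px = 3)
  expect_s3_class(m, "coloc_match")
  expect_identical(nrow(m$pairs), 1L)
  expect_equal(m$pairs$distance_px, 1)
  expect_identical(m$pairs$red_index, 1L)
  expect_identical(nrow(match_spots(red, blue, d_max_px = 0.5)$pairs), 0L)
  expect_error(match_spots(red, blue, d_max_px = 0),
               class = "dualspot_param_error")
})

test_that("matching is maximum cardinality, not greedy nearest-neighbour", {
  # greedy would take r1-b1 (d = 1) and strand r2; the maximum matching
  # pairs r1-b2 and r2-b1
  red <- cbind(c(0, 2), c(0, 0))
  blue <- cbind(c(1, -2), c(0, 0))
  m <- match_spots(red, blue, d_max_px = 2.5)
  expect_identical(nrow(m$pairs), 2L)
  expect_equal(sort(m$pairs$blue_index), c(1L, 2L))
})

test_that("among maximum matchings the total distance is minimized", {
  red <- cbind(0, 0)
  blue <- cbind(c(1, 0), c(0, 1.5))
  m <- match_spots(red, blue, d_max_px = 3)
  expect_identical(m$pairs$blue_index, 1L)
  expect_equal(m$pairs$distance_px, 1)
})

test_that("empty channels give an empty match", {
  m <- match_spots(cbind(numeric(0), numeric(0)), cbind(1, 1), 3)
  expect_identical(nrow(m$pairs), 0L)
})

test_that("matched count equals the exhaustive oracle on random instances", {
  set.seed(501)
  for (i in 1:50) {
    nr <- sample(0:8, 1); nb <- sample(0:8, 1)
    box <- sample(c(8, 12, 20), 1)
    red <- rand_spots(nr, box); blue <- rand_spots(nb, box)
    got <- nrow(match_spots(red, blue, d_max_px = 3)$pairs)
    expect_identical(got, as.integer(bf_max_matching_size(red, blue, 3)))
  }
})

test_that("matching accepts spot tables from detect_spots", {
  red <- data.frame(x_px = c(5, 20), y_px = c(5, 20))
  blue <- data.frame(x_px = c(6, 40), y_px = c(5, 40))
  expect_identical(nrow(match_spots(red, blue, 3)$pairs), 1L)
  expect_error(match_spots(data.frame(a = 1), blue, 3),
               class = "dualspot_param_error")
})

test_that("expected_chance_coloc implements the CSR dilute formula", {
  expect_equal(expected_chance_coloc(20, 20, 512^2, 3),
               20 * 20 * pi * 9 / 512^2)
  expect_equal(expected_chance_coloc(0, 20, 512^2, 3), 0)
  expect_error(expected_chance_coloc(20, 20, 0, 3),
               class = "dualspot_param_error")
})

test_that("coloc_summary combines counts, chance correction and rate", {
  m <- match_spots(cbind(c(1, 30), c(1, 30)), cbind(c(1.5, 60), c(1, 60)), 3)
  s <- coloc_summary(m, n_red = 2, n_blue = 2, area_px2 = 512^2,
                     pixel_size_um = 0.325)
  expect_s3_class(s, "coloc_summary")
  expect_identical(s$n_coloc, 1L)
  expect_equal(s$expected_chance, expected_chance_coloc(2, 2, 512^2, 3))
  expect_equal(s$corrected_count, 1 - s$expected_chance)
  expect_equal(s$coloc_rate, 0.5)
  expect_equal(s$field_area_mm2, 512^2 * (0.325e-3)^2)
  # the corrected count never goes negative
  m0 <- match_spots(cbind(1, 1), cbind(100, 100), 3)
  s0 <- coloc_summary(m0, 200, 200, 100, pixel_size_um = 1)
  expect_identical(s0$corrected_count, 0)
  expect_error(coloc_summary(m, n_red = 0, n_blue = 2, area_px2 = 512^2))
})

test_that("coloc_field runs end to end on a synthetic field", {
  p <- field_params(width_px = 256, height_px = 256, lambda_pair = 10,
                    lambda_red_only = 5, lambda_blue_only = 5, seed = 511)
  fg <- generate_field(p)
  res <- coloc_field(fg$field, detect_config(), d_max_px = 3)
  expect_true(all(c("red", "blue", "match", "summary") %in% names(res)))
  expect_identical(res$summary$n_red, nrow(res$red))
  expect_identical(res$summary$n_coloc, nrow(res$match$pairs))
  expect_gt(res$summary$n_coloc, 0L)
})

test_that("register_channels recovers a known integer shift", {
  set.seed(521)
  img <- matrix(0, 64, 64)
  pts <- cbind(sample(15:48, 8), sample(15:48, 8))
  sh <- matrix(0, 64, 64)
  img[pts] <- 100
  sh[pts + matrix(c(-2L, 3L), 8, 2, byrow = TRUE)] <- 100
  k <- EBImage::makeBrush(9, "gaussian", sigma = 1.5)
  red <- as.matrix(EBImage::filter2(img, k)) + 1
  blue <- as.matrix(EBImage::filter2(sh, k)) + 1
  # blue displaced by (dx, dy) = (+3, -2); aligning shift is the negative
  expect_identical(register_channels(red, blue), c(dx = -3L, dy = 2L))
  expect_identical(register_channels(red, red), c(dx = 0L, dy = 0L))
  expect_error(register_channels(red, blue[1:32, ]),
               class = "dualspot_param_error")
})
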