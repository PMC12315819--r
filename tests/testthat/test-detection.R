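clean_spot_image <- function(centers, amp = 2000, size = 64, sigma = 1.5,
                             bg = 100) {
  img <- matrix(bg, size, size)
  img <- dualspot:::render_spots(img, centers, rep(amp, nrow(centers)), sigma)
  # mild read noise: a perfectly constant background is not a realistic
  # acquisition and degenerates rank-based enhancement
  img <- img + dualspot:::with_seed(4242, rnorm(length(img), 0, 3))
  pmax(round(img), 0)
}

test_that("enhance maps intensities through the empirical CDF to 8 bits", {
  m <- matrix(c(10, 90, 90, 90), 2, 2)
  e <- enhance(m)
  expect_identical(dim(e), dim(m))
  expect_identical(e[m == 10][1], 64L)   # round(255 * 0.25)
  expect_identical(e[m == 90][1], 255L)  # top level -> full scale
  # constant image maps to the top of the range, rank order is preserved
  expect_true(all(enhance(matrix(5, 3, 3)) == 255L))
  set.seed(2)
  r <- matrix(sample(1:500, 100), 10, 10)
  er <- enhance(r)
  expect_true(all(er >= 0 & er <= 255))
  expect_identical(order(r), order(er))
  # clahe variant returns the same shape on the same scale
  ec <- enhance(r, method = "clahe")
  expect_identical(dim(ec), dim(r))
  expect_true(all(ec >= 0 & ec <= 255))
})

test_that("detect_config validates parameters", {
  expect_error(detect_config(min_area_px = 10, max_area_px = 5),
               class = "dualspot_param_error")
  expect_error(detect_config(min_circularity = 2),
               class = "dualspot_param_error")
  expect_error(detect_config(hough_r_min_px = 8, hough_r_max_px = 2),
               class = "dualspot_param_error")
  expect_error(detect_config(threshold_method = "fixed"),
               class = "dualspot_param_error")  # fixed_threshold missing
  expect_error(detect_spots(matrix(-1, 40, 40)),
               class = "dualspot_param_error")
})

test_that("a single clean spot is found with sub-pixel accuracy", {
  img <- clean_spot_image(cbind(30.4, 20.7))
  d <- detect_spots(img, detect_config())
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$x_px - 30.4), 0.5)
  expect_lt(abs(d$y_px - 20.7), 0.5)
  expect_gt(d$radius_px, 0.5)
})

test_that("multiple spots are found and ordered by (y, x)", {
  img <- clean_spot_image(cbind(c(10, 40, 40), c(10, 10, 45)))
  d <- detect_spots(img, detect_config())
  expect_identical(nrow(d), 3L)
  expect_true(!is.unsorted(d$y_px))
  expect_equal(sort(round(d$x_px)), c(10, 40, 40))
})

test_that("the contour detector reports one component per blob", {
  img <- clean_spot_image(cbind(c(15, 45), c(15, 45)))
  d <- detect_spots_contour(img, detect_config())
  expect_identical(nrow(d), 2L)
  expect_true(all(d$method == "contour"))
})

test_that("the Hough detector finds circular spots on the equalized image", {
  img <- clean_spot_image(cbind(c(20, 44), c(20, 40)), sigma = 2)
  eq <- enhance(img)
  d <- detect_spots_hough(eq, detect_config())
  expect_identical(nrow(d), 2L)
  expect_lt(min(abs(d$x_px - 20), abs(d$x_px - 44)), 1.5)
})

test_that("near-blank noisy fields yield almost no detections", {
  n_fp <- 0
  for (i in 1:5) {
    p <- field_params(width_px = 256, height_px = 256, lambda_pair = 0,
                      lambda_red_only = 0, lambda_blue_only = 0,
                      seed = 7000 + i)
    fg <- generate_field(p)
    n_fp <- n_fp + nrow(detect_spots(fg$field$red_image, detect_config()))
  }
  expect_lte(n_fp, 2)
})

test_that("fixed thresholding is honoured", {
  img <- clean_spot_image(cbind(30, 30))
  cfg_lo <- detect_config(threshold_method = "fixed", fixed_threshold = 150)
  expect_identical(nrow(detect_spots_contour(img, cfg_lo)), 1L)
  cfg_hi <- detect_config(threshold_method = "fixed", fixed_threshold = 1e5)
  expect_identical(nrow(detect_spots_contour(img, cfg_hi)), 0L)
})

test_that("detectors agree on clean fields and merged rows are flagged", {
  img <- clean_spot_image(cbind(c(16, 48), c(16, 44)), sigma = 2)
  d <- detect_spots(img, detect_config())
  expect_identical(nrow(d), 2L)
  expect_true(any(d$method == "merged"))
  expect_true(all(d$method %in% c("merged", "contour", "hough")))
})

test_that("detection on a realistic field reaches high recall and precision", {
  p <- field_params(seed = 7101)
  fg <- generate_field(p)
  d <- detect_spots(fg$field$red_image, detect_config(), channel = "red")
  tr <- fg$truth$red_centers
  m <- match_spots(tr, d, d_max_px = 2)
  tp <- nrow(m$pairs)
  expect_gte(tp / nrow(tr), 0.9)   # recall
  expect_gte(tp / nrow(d), 0.9)    # precision
  expect_true(all(d$channel == "red"))
})
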