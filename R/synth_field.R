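#' Parameters for a synthetic dual-channel field
#'
#' Describes one simulated field of the surface assay: diffraction-limited
#' circular particles rendered as 2-D Gaussians on a noisy CCD background, in
#' a red (alpha-synuclein) and a blue/far-red (amylin) channel, with a
#' controllable fraction of particles truly co-localized across channels.
#'
#' Spot counts are Poisson: `lambda_pair` true red/blue co-aggregate pairs,
#' plus `lambda_red_only` and `lambda_blue_only` singletons per channel. The
#' blue partner of each pair is displaced from its red partner by isotropic
#' Gaussian jitter of sd `registration_jitter_sd_px` (residual chromatic /
#' stage registration error). Peak amplitudes are log-normal per spot and
#' channel. Defaults emulate a moderately loaded field at peak
#' signal-to-noise ratio 10, where peak SNR is defined as
#' `exp(amplitude_log_mean) / sqrt(background_level + read_noise_sd^2)`
#' (the Poisson variance of the background plus read-noise variance).
#'
#' @param width_px,height_px image size in pixels (>= 32).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param lambda_pair expected number of true co-localized red/blue pairs.
#' @param lambda_red_only,lambda_blue_only expected singleton counts.
#' @param psf_sigma_px Gaussian spot width (sd) in pixels.
#' @param amplitude_log_mean,amplitude_log_sd log-normal peak-amplitude
#'   parameters (counts above background).
#' @param background_level mean background in counts.
#' @param read_noise_sd Gaussian read noise sd in counts.
#' @param shot_noise apply Poisson shot noise to signal + background?
#' @param registration_jitter_sd_px sd of the blue partner displacement.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical fields.
#' @return an object of class `field_params`.
#' @export
#' @examples
#' p <- field_params(lambda_pair = 10, seed = 1)
#' p$lambda_pair
field_params <- function(width_px = 512L, height_px = 512L,
                         pixel_size_um = 0.325,
                         lambda_pair = 30, lambda_red_only = 20,
                         lambda_blue_only = 20,
                         psf_sigma_px = 1.5,
                         amplitude_log_mean = log(10 * sqrt(100 + 5^2)),
                         amplitude_log_sd = 0.25,
                         background_level = 100,
                         read_noise_sd = 5,
                         shot_noise = TRUE,
                         registration_jitter_sd_px = 1,
                         seed = 1L) {
  check_scalar_num(width_px, "width_px", lower = 32)
  check_scalar_num(height_px, "height_px", lower = 32)
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  check_scalar_num(lambda_pair, "lambda_pair", lower = 0)
  check_scalar_num(lambda_red_only, "lambda_red_only", lower = 0)
  check_scalar_num(lambda_blue_only, "lambda_blue_only", lower = 0)
  check_scalar_num(psf_sigma_px, "psf_sigma_px", lower = 1e-9)
  check_scalar_num(amplitude_log_mean, "amplitude_log_mean")
  check_scalar_num(amplitude_log_sd, "amplitude_log_sd", lower = 0)
  check_scalar_num(background_level, "background_level", lower = 0)
  check_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  check_that(is.logical(shot_noise) && length(shot_noise) == 1L,
             "shot_noise", "must be TRUE or FALSE")
  check_scalar_num(registration_jitter_sd_px, "registration_jitter_sd_px",
                   lower = 0)
  check_scalar_num(seed, "seed")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    lambda_pair = lambda_pair, lambda_red_only = lambda_red_only,
    lambda_blue_only = lambda_blue_only,
    psf_sigma_px = psf_sigma_px,
    amplitude_log_mean = amplitude_log_mean,
    amplitude_log_sd = amplitude_log_sd,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    registration_jitter_sd_px = registration_jitter_sd_px,
    seed = as.integer(seed)
  ), class = "field_params")
}

#' Peak signal-to-noise ratio implied by field parameters
#'
#' @param params a [field_params()] object.
#' @return median peak amplitude divided by the background noise sd.
#' @export
peak_snr <- function(params) {
  stopifnot(inherits(params, "field_params"))
  noise_var <- params$read_noise_sd^2 +
    if (params$shot_noise) params$background_level else 0
  exp(params$amplitude_log_mean) / sqrt(noise_var)
}

# Uniform positions inside the border margin (spots within 3*sigma of the
# border are never placed, so no truncated spots bias detection tests).
draw_positions <- function(n, width, height, margin) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  lo_x <- margin; hi_x <- width - 1 - margin
  lo_y <- margin; hi_y <- height - 1 - margin
  if (lo_x >= hi_x || lo_y >= hi_y)
    stop_param("psf_sigma_px", "border margin leaves no interior to place spots")
  cbind(x = runif(n, lo_x, hi_x), y = runif(n, lo_y, hi_y))
}

# Additively render 2-D Gaussian spots onto `img` (matrix indexed [y, x],
# 0-based spot coordinates at pixel centers).
render_spots <- function(img, centers, amplitudes, sigma) {
  if (nrow(centers) == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    x0 <- max(0, floor(cx) - r); x1 <- min(w - 1, ceiling(cx) + r)
    y0 <- max(0, floor(cy) - r); y1 <- min(h - 1, ceiling(cy) + r)
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
    gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amplitudes[i] * outer(gy, gx)
  }
  img
}

quantize_16bit <- function(img, background, read_noise_sd, shot_noise) {
  if (shot_noise) {
    img <- matrix(rpois(length(img), lambda = pmax(img, 0)),
                  nrow = nrow(img))
  }
  if (read_noise_sd > 0) img <- img + rnorm(length(img), 0, read_noise_sd)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  storage.mode(img) <- "integer"
  img
}

#' Generate one synthetic dual-channel field with ground truth
#'
#' Draws Poisson spot counts, places spots uniformly away from the border,
#' renders them as 2-D Gaussians, and adds CCD-style noise (Poisson shot
#' noise on signal + background, then Gaussian read noise, quantized to the
#' 16-bit range). The returned ground truth records every true center and
#' which red/blue spots form true co-aggregate pairs.
#'
#' @param params a [field_params()] object.
#' @param field_id,well_id,sample_id identifier strings attached to the field.
#' @return a list with elements `field` (class `dual_field`: `red_image`,
#'   `blue_image` as integer matrices indexed `[y, x]`, plus acquisition
#'   metadata) and `truth` (class `ground_truth_field`: `red_centers`,
#'   `blue_centers` as two-column `(x, y)` matrices of 0-based coordinates,
#'   `pair_index` as a two-column matrix of 1-based `(red, blue)` indices,
#'   and `coloc_fraction` = pairs / red spots, 0 when no red spots).
#' @export
#' @examples
#' fg <- generate_field(field_params(lambda_pair = 5, seed = 7))
#' dim(fg$field$red_image)
#' fg$truth$coloc_fraction
generate_field <- function(params, field_id = "field1", well_id = "well1",
                           sample_id = "sample1") {
  stopifnot(inherits(params, "field_params"))
  w <- params$width_px; h <- params$height_px
  sigma <- params$psf_sigma_px
  margin <- 3 * sigma
  with_seed(params$seed, {
    n_pair <- rpois(1, params$lambda_pair)
    n_red_only <- rpois(1, params$lambda_red_only)
    n_blue_only <- rpois(1, params$lambda_blue_only)

    pair_red <- draw_positions(n_pair, w, h, margin)
    # Blue partners: red position + isotropic jitter, redrawn while outside
    # the margin box so no partner is truncated at the border.
    pair_blue <- pair_red
    if (n_pair > 0 && params$registration_jitter_sd_px > 0) {
      todo <- seq_len(n_pair)
      while (length(todo) > 0) {
        jit <- matrix(rnorm(2 * length(todo), 0,
                            params$registration_jitter_sd_px), ncol = 2)
        cand <- pair_red[todo, , drop = FALSE] + jit
        ok <- cand[, 1] >= margin & cand[, 1] <= w - 1 - margin &
          cand[, 2] >= margin & cand[, 2] <= h - 1 - margin
        pair_blue[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
    }
    red_only <- draw_positions(n_red_only, w, h, margin)
    blue_only <- draw_positions(n_blue_only, w, h, margin)

    red_centers <- rbind(pair_red, red_only)
    blue_centers <- rbind(pair_blue, blue_only)
    n_red <- nrow(red_centers); n_blue <- nrow(blue_centers)

    amp_red <- rlnorm(n_red, params$amplitude_log_mean, params$amplitude_log_sd)
    amp_blue <- rlnorm(n_blue, params$amplitude_log_mean, params$amplitude_log_sd)

    base <- matrix(params$background_level, nrow = h, ncol = w)
    red_img <- render_spots(base, red_centers, amp_red, sigma)
    blue_img <- render_spots(base, blue_centers, amp_blue, sigma)
    red_img <- quantize_16bit(red_img, params$background_level,
                              params$read_noise_sd, params$shot_noise)
    blue_img <- quantize_16bit(blue_img, params$background_level,
                               params$read_noise_sd, params$shot_noise)

    field <- structure(list(
      red_image = red_img, blue_image = blue_img,
      pixel_size_um = params$pixel_size_um,
      exposure_red_s = 0.5, exposure_blue_s = 2,
      field_id = field_id, well_id = well_id, sample_id = sample_id
    ), class = "dual_field")

    pair_index <- if (n_pair > 0) cbind(red = seq_len(n_pair),
                                        blue = seq_len(n_pair))
    else cbind(red = integer(0), blue = integer(0))
    truth <- structure(list(
      red_centers = red_centers, blue_centers = blue_centers,
      pair_index = pair_index,
      coloc_fraction = if (n_red > 0) n_pair / n_red else 0
    ), class = "ground_truth_field")

    list(field = field, truth = truth)
  })
}

#' @export
print.dual_field <- function(x, ...) {
  cat(sprintf("<dual_field> %s (well %s, sample %s): %d x %d px, %.3f um/px\n",
              x$field_id, x$well_id, x$sample_id,
              ncol(x$red_image), nrow(x$red_image), x$pixel_size_um))
  invisible(x)
}

#' Field area in mm^2
#' @param field a `dual_field` object, or missing when `npix`/`pixel_size_um`
#'   are given directly.
#' @param npix number of pixels (defaults to the field's image size).
#' @param pixel_size_um pixel pitch in micrometres.
#' @return area in mm^2.
#' @export
field_area_mm2 <- function(field = NULL, npix = NULL, pixel_size_um = NULL) {
  if (!is.null(field)) {
    stopifnot(inherits(field, "dual_field"))
    npix <- length(field$red_image)
    pixel_size_um <- field$pixel_size_um
  }
  check_scalar_num(npix, "npix", lower = 1)
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  npix * (pixel_size_um * 1e-3)^2
}

#' Generate a fold-diluted series of synthetic fields
#'
#' Step `k` (0-based) scales all three spot rates of `base` by `fold^-k`,
#' emulating a serial dilution of the standard (default 5-fold across 7
#' steps). Per-step seeds are derived deterministically from the base seed so
#' the series is reproducible yet steps are independent.
#'
#' @param base a [field_params()] object for the undiluted step.
#' @param fold dilution factor between steps (> 1).
#' @param steps number of steps (>= 2).
#' @return a list of length `steps`; each element has `field`, `truth`,
#'   `step` (0-based) and `rel_conc` (`fold^-step`).
#' @export
#' @examples
#' ser <- generate_dilution_series(field_params(seed = 3), fold = 5, steps = 3)
#' sapply(ser, function(s) s$rel_conc)
generate_dilution_series <- function(base, fold = 5, steps = 7) {
  stopifnot(inherits(base, "field_params"))
  check_scalar_num(fold, "fold")
  if (fold <= 1) stop_param("fold", "must be > 1")
  check_scalar_num(steps, "steps")
  if (steps < 2) stop_param("steps", "must be >= 2")
  steps <- as.integer(steps)
  lapply(seq_len(steps) - 1L, function(k) {
    scale <- fold^(-k)
    pk <- base
    pk$lambda_pair <- base$lambda_pair * scale
    pk$lambda_red_only <- base$lambda_red_only * scale
    pk$lambda_blue_only <- base$lambda_blue_only * scale
    pk$seed <- derive_seed(base$seed, k)
    fg <- generate_field(pk, field_id = sprintf("step%d", k))
    c(fg, list(step = k, rel_conc = scale))
  })
}
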