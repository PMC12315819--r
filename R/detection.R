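#' Detection configuration
#'
#' Free parameters of the per-channel particle detectors. The original assay
#' pipeline names its two operators (contour detection and Hough circle
#' detection) but no numeric parameters, so all values here are declared,
#' overridable defaults.
#'
#' @param equalization image enhancement: global histogram equalization or
#'   contrast-limited adaptive ("clahe").
#' @param threshold_method threshold for the contour detector: `"otsu"`
#'   (Otsu's method combined with a robust noise floor, see
#'   [detect_spots_contour()]) or `"fixed"`.
#' @param fixed_threshold threshold value when `threshold_method = "fixed"`.
#' @param min_area_px,max_area_px connected-component area bounds in pixels.
#' @param min_circularity minimum `4*pi*A/P^2` of a component, in (0, 1].
#' @param hough_r_min_px,hough_r_max_px circle radius range for the Hough
#'   detector (integers, `r_min < r_max`).
#' @param hough_vote_threshold minimum accumulator support for a circle,
#'   expressed as a fraction of the full circumference `2*pi*r`.
#' @param merge_dist_px center distance below which detections from the two
#'   operators are considered the same particle.
#' @param noise_floor_k the contour threshold is never below
#'   `median + k * MAD` of the image (guards against threshold collapse on
#'   near-blank fields).
#' @param hough_edge_k edge pixels are gradient magnitudes above
#'   `median + k * MAD`.
#' @param hough_min_intensity minimum mean intensity inside a candidate
#'   circle, on the 8-bit equalized scale: true fluorescent particles sit at
#'   the top of the equalized range, while accumulator peaks arising from
#'   background noise have near-median interiors and are rejected.
#' @param blur_sigma Gaussian pre-smoothing (pixels) before Hough gradients.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(equalization = c("global", "clahe"),
                          threshold_method = c("otsu", "fixed"),
                          fixed_threshold = NULL,
                          min_area_px = 3L, max_area_px = 400L,
                          min_circularity = 0.3,
                          hough_r_min_px = 2L, hough_r_max_px = 8L,
                          hough_vote_threshold = 0.6,
                          merge_dist_px = 3,
                          noise_floor_k = 4,
                          hough_edge_k = 3,
                          hough_min_intensity = 225,
                          blur_sigma = 1) {
  equalization <- match.arg(equalization)
  threshold_method <- match.arg(threshold_method)
  check_scalar_num(min_area_px, "min_area_px", lower = 1)
  check_scalar_num(max_area_px, "max_area_px", lower = 1)
  if (min_area_px >= max_area_px)
    stop_param("min_area_px", "must be < max_area_px")
  check_scalar_num(min_circularity, "min_circularity", lower = 1e-9, upper = 1)
  check_scalar_num(hough_r_min_px, "hough_r_min_px", lower = 1)
  check_scalar_num(hough_r_max_px, "hough_r_max_px", lower = 1)
  if (hough_r_min_px >= hough_r_max_px)
    stop_param("hough_r_min_px", "must be < hough_r_max_px")
  check_scalar_num(hough_vote_threshold, "hough_vote_threshold", lower = 0)
  check_scalar_num(merge_dist_px, "merge_dist_px", lower = 0)
  check_scalar_num(noise_floor_k, "noise_floor_k", lower = 0)
  check_scalar_num(hough_edge_k, "hough_edge_k", lower = 0)
  check_scalar_num(hough_min_intensity, "hough_min_intensity", lower = 0)
  check_scalar_num(blur_sigma, "blur_sigma", lower = 0)
  if (threshold_method == "fixed")
    check_scalar_num(fixed_threshold, "fixed_threshold")
  structure(list(
    equalization = equalization, threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    min_area_px = as.integer(min_area_px),
    max_area_px = as.integer(max_area_px),
    min_circularity = min_circularity,
    hough_r_min_px = as.integer(hough_r_min_px),
    hough_r_max_px = as.integer(hough_r_max_px),
    hough_vote_threshold = hough_vote_threshold,
    merge_dist_px = merge_dist_px,
    noise_floor_k = noise_floor_k,
    hough_edge_k = hough_edge_k,
    hough_min_intensity = hough_min_intensity,
    blur_sigma = blur_sigma
  ), class = "detect_config")
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop_param("image", "must be a non-empty numeric matrix")
  if (any(image < 0)) stop_param("image", "must be nonnegative")
  invisible(TRUE)
}

#' Histogram-equalize an image to 8-bit
#'
#' Global histogram equalization: each intensity level `v` maps to
#' `round(255 * CDF(v))` over the image's empirical distribution, so the
#' output is in `[0, 255]` and the rank order of distinct input levels is
#' preserved. The CLAHE variant delegates to [EBImage::clahe()] and rescales
#' to the same 8-bit range.
#'
#' @param image 2-D nonnegative numeric matrix.
#' @param method `"global"` or `"clahe"`.
#' @return an integer matrix in `[0, 255]` of the same shape.
#' @export
#' @examples
#' m <- matrix(c(rep(10, 1), rep(90, 3)), 2, 2)
#' enhance(m) # 25% at the low level -> 64; top level -> 255
enhance <- function(image, method = c("global", "clahe")) {
  method <- match.arg(method)
  check_image(image)
  if (method == "global") {
    lev <- sort(unique(as.vector(image)))
    cdf <- cumsum(tabulate(match(image, lev), nbins = length(lev))) /
      length(image)
    out <- matrix(as.integer(round(255 * cdf[match(image, lev)])),
                  nrow = nrow(image))
  } else {
    rng <- range(image)
    xs <- if (diff(rng) == 0) image * 0 else (image - rng[1]) / diff(rng)
    biggest_div <- function(n, cap = 8L) max(which(n %% seq_len(min(cap, n)) == 0L))
    eq <- EBImage::clahe(xs, nx = biggest_div(nrow(image)),
                         ny = biggest_div(ncol(image)))
    out <- matrix(as.integer(round(255 * pmin(pmax(as.numeric(eq), 0), 1))),
                  nrow = nrow(image))
  }
  out
}

spot_table <- function(x = numeric(0), y = numeric(0), radius = numeric(0),
                       intensity = numeric(0), method = character(0),
                       channel = NA_character_) {
  data.frame(x_px = x, y_px = y, radius_px = radius,
             mean_intensity = intensity,
             method = method,
             channel = rep_len(channel, length(x)),
             stringsAsFactors = FALSE)
}

# Contour threshold: Otsu on the image's own histogram, floored at
# median + k * MAD so near-blank fields yield no foreground.
contour_threshold <- function(image, cfg) {
  if (cfg$threshold_method == "fixed") return(cfg$fixed_threshold)
  v <- as.vector(image)
  rng <- range(v)
  t_otsu <- if (diff(rng) == 0) rng[1] else {
    lv <- min(65536L, max(256L, diff(floor(rng)) + 1L))
    EBImage::otsu(matrix(v, nrow = nrow(image)), range = rng, levels = lv)
  }
  floor_t <- median(v) + cfg$noise_floor_k * mad(v)
  max(t_otsu, floor_t)
}

# 4-neighbor exposed-edge perimeter per labeled component.
component_perimeter <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- labels
  core <- pad[2:(h + 1), 2:(w + 1)]
  expo <- (core != pad[1:h, 2:(w + 1)]) + (core != pad[3:(h + 2), 2:(w + 1)]) +
    (core != pad[2:(h + 1), 1:w]) + (core != pad[2:(h + 1), 3:(w + 2)])
  keep <- core > 0
  as.vector(rowsum(as.numeric(expo[keep]), group = core[keep]))
}

#' Detect particles by thresholding and contour analysis
#'
#' Threshold (Otsu with a robust noise floor by default), label connected
#' components, filter by area and circularity `4*pi*A/P^2`, and report each
#' surviving component as a spot with sub-pixel centroid and equivalent-disc
#' radius `sqrt(A/pi)`. Output rows are ordered by `(y, x)`.
#'
#' @param image 2-D nonnegative numeric matrix. The threshold is computed on
#'   this image's own intensity histogram; because thresholding is
#'   rank-based, running on the raw or on a monotonically enhanced image
#'   selects the same family of pixel sets.
#' @param cfg a [detect_config()].
#' @param channel optional channel label stored in the result.
#' @return a data.frame of spots (`x_px`, `y_px`, `radius_px`,
#'   `mean_intensity`, `method`, `channel`), 0-based center-of-pixel
#'   coordinates with `x` the column index.
#' @export
detect_spots_contour <- function(image, cfg = detect_config(),
                                 channel = NA_character_) {
  check_image(image)
  stopifnot(inherits(cfg, "detect_config"))
  thr <- contour_threshold(image, cfg)
  bin <- image > thr
  if (!any(bin)) return(spot_table(channel = channel))
  labels <- EBImage::bwlabel(bin + 0)
  labels <- matrix(as.integer(labels), nrow = nrow(image))
  n_lab <- max(labels)
  area <- tabulate(labels[labels > 0], nbins = n_lab)
  perim <- component_perimeter(labels)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  ix <- (idx - 1L) %/% nrow(image)      # 0-based column = x
  iy <- (idx - 1L) %% nrow(image)       # 0-based row = y
  # intensity-weighted sub-pixel centroid (above-threshold excess as weight)
  wts <- pmax(as.numeric(image[idx]) - thr, 1e-9)
  wsum <- as.vector(rowsum(wts, lab_v))
  cx <- as.vector(rowsum(wts * ix, lab_v)) / wsum
  cy <- as.vector(rowsum(wts * iy, lab_v)) / wsum
  inten <- as.vector(rowsum(as.numeric(image[idx]), lab_v)) / area
  circ <- pmin(1, 4 * pi * area / pmax(perim, 1)^2)
  keep <- area >= cfg$min_area_px & area <= cfg$max_area_px &
    circ >= cfg$min_circularity
  if (!any(keep)) return(spot_table(channel = channel))
  ord <- order(cy[keep], cx[keep])
  spot_table(cx[keep][ord], cy[keep][ord],
             sqrt(area[keep][ord] / pi), inten[keep][ord],
             rep("contour", sum(keep)), channel)
}

box3_sum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + pad[(1:h) + dy, (1:w) + dx]
  out
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sz <- 2L * ceiling(2 * sigma) + 1L
  k <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma)
  matrix(as.numeric(EBImage::filter2(m, k, boundary = "replicate")),
         nrow = nrow(m))
}

#' Detect circular particles with a gradient-voting Hough transform
#'
#' After optional Gaussian smoothing, edge pixels (gradient magnitude above a
#' robust threshold) vote along their gradient direction into a per-radius
#' accumulator over radii `[hough_r_min_px, hough_r_max_px]`. Accumulator
#' peaks whose 3x3-pooled support exceeds `hough_vote_threshold * 2*pi*r`
#' become circle detections, deduplicated by greedy non-maximum suppression
#' and refined to sub-pixel centers by the local vote centroid.
#'
#' @inheritParams detect_spots_contour
#' @return a data.frame of spots as in [detect_spots_contour()], with
#'   `method = "hough"`.
#' @export
detect_spots_hough <- function(image, cfg = detect_config(),
                               channel = NA_character_) {
  check_image(image)
  stopifnot(inherits(cfg, "detect_config"))
  h <- nrow(image); w <- ncol(image)
  if (cfg$hough_r_max_px >= min(h, w) / 2)
    stop_param("hough_r_max_px", "must be < half the smallest image dimension")
  m <- gaussian_blur(image, cfg$blur_sigma)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  thr <- median(mag) + cfg$hough_edge_k * mad(mag)
  edge <- which(mag > thr & mag > 1e-9)
  if (length(edge) == 0) return(spot_table(channel = channel))
  ex <- (edge - 1L) %/% h   # 0-based x
  ey <- (edge - 1L) %% h    # 0-based y
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]
  radii <- cfg$hough_r_min_px:cfg$hough_r_max_px
  cand <- list()
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    # bright spots: gradient points toward the center
    cx <- as.integer(round(ex + r * ux))
    cy <- as.integer(round(ey + r * uy))
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    if (!any(ok)) next
    acc <- matrix(tabulate(cy[ok] * w + cx[ok] + 1L, nbins = h * w),
                  nrow = h, byrow = TRUE)
    pooled <- box3_sum(acc)
    need <- cfg$hough_vote_threshold * 2 * pi * r
    peaks <- which(pooled >= need & pooled > 0)
    if (length(peaks) == 0) next
    px <- (peaks - 1L) %/% h
    py <- (peaks - 1L) %% h
    # sub-pixel refinement: centroid of the 3x3 vote neighborhood
    refine <- vapply(seq_along(peaks), function(i) {
      xs <- max(0, px[i] - 1):min(w - 1, px[i] + 1)
      ys <- max(0, py[i] - 1):min(h - 1, py[i] + 1)
      wts <- acc[ys + 1, xs + 1, drop = FALSE]
      s <- sum(wts)
      if (s == 0) return(c(px[i], py[i]))
      c(sum(outer(rep(1, length(ys)), xs) * wts) / s,
        sum(outer(ys, rep(1, length(xs))) * wts) / s)
    }, numeric(2))
    cand[[length(cand) + 1L]] <- data.frame(
      x = refine[1, ], y = refine[2, ], r = r,
      score = pooled[peaks] / (2 * pi * r))
  }
  if (length(cand) == 0) return(spot_table(channel = channel))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
  keep <- integer(0)
  min_sep <- max(cfg$merge_dist_px, 2)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0) { keep <- i; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    if (all(d2 >= min_sep^2)) keep <- c(keep, i)
  }
  kept <- cand[keep, , drop = FALSE]
  inten <- vapply(seq_len(nrow(kept)), function(i) {
    xs <- max(0, round(kept$x[i]) - kept$r[i]):min(w - 1, round(kept$x[i]) + kept$r[i])
    ys <- max(0, round(kept$y[i]) - kept$r[i]):min(h - 1, round(kept$y[i]) + kept$r[i])
    sub <- image[ys + 1, xs + 1, drop = FALSE]
    dm <- outer((ys - kept$y[i])^2, (xs - kept$x[i])^2, "+") <= kept$r[i]^2
    if (!any(dm)) mean(sub) else mean(sub[dm])
  }, numeric(1))
  # center-surround contrast: a genuine particle outshines its surrounding
  # annulus (r .. 2r); displaced "ghost" rings near a bright blob have the
  # blob core in their annulus and fail this check
  annulus <- vapply(seq_len(nrow(kept)), function(i) {
    r2 <- 2 * kept$r[i]
    xs <- max(0, round(kept$x[i]) - r2):min(w - 1, round(kept$x[i]) + r2)
    ys <- max(0, round(kept$y[i]) - r2):min(h - 1, round(kept$y[i]) + r2)
    sub <- image[ys + 1, xs + 1, drop = FALSE]
    dd <- outer((ys - kept$y[i])^2, (xs - kept$x[i])^2, "+")
    dm <- dd > kept$r[i]^2 & dd <= r2^2
    if (!any(dm)) -Inf else mean(sub[dm])
  }, numeric(1))
  bright <- inten >= cfg$hough_min_intensity & inten > annulus
  kept <- kept[bright, , drop = FALSE]
  inten <- inten[bright]
  if (nrow(kept) == 0) return(spot_table(channel = channel))
  ord <- order(kept$y, kept$x)
  spot_table(kept$x[ord], kept$y[ord], kept$r[ord], inten[ord],
             rep("hough", nrow(kept)), channel)
}

#' Detect particles in one channel (combined pipeline)
#'
#' Runs histogram equalization, the contour detector and the Hough circle
#' detector, and merges their outputs: detections from the two operators
#' whose centers lie within `merge_dist_px` are collapsed to one spot,
#' keeping the contour-derived geometry and labeling the spot `"merged"`.
#' The contour threshold is computed on the raw-intensity histogram (where
#' the background/noise structure is preserved; equalization is monotone so
#' the selected pixel sets are of the same family), while the Hough detector
#' consumes the equalized image.
#'
#' @param image raw 2-D nonnegative numeric matrix (16-bit range).
#' @param cfg a [detect_config()].
#' @param channel optional channel label (`"red"` or `"blue"`).
#' @return a data.frame of spots; no two rows are closer than
#'   `merge_dist_px`.
#' @export
#' @examples
#' fg <- generate_field(field_params(lambda_pair = 5, lambda_red_only = 0,
#'                                   lambda_blue_only = 0, seed = 2))
#' nrow(detect_spots(fg$field$red_image, channel = "red"))
detect_spots <- function(image, cfg = detect_config(),
                         channel = NA_character_) {
  check_image(image)
  stopifnot(inherits(cfg, "detect_config"))
  enh <- enhance(image, cfg$equalization)
  cont <- detect_spots_contour(image, cfg, channel = channel)
  hough <- detect_spots_hough(enh, cfg, channel = channel)
  if (nrow(hough) > 0) {
    # raw-scale interior/annulus means per Hough candidate: the equalized
    # scale the Hough detector sees compresses contrast, so the
    # center-surround check is repeated on the raw image, where displaced
    # ghost rings beside a bright particle (annulus brighter than interior)
    # are unambiguous
    con <- vapply(seq_len(nrow(hough)), function(i) {
      r <- max(2, hough$radius_px[i])
      r2 <- 2 * r
      cx <- round(hough$x_px[i]); cy <- round(hough$y_px[i])
      xs <- max(0, cx - r2):min(ncol(image) - 1, cx + r2)
      ys <- max(0, cy - r2):min(nrow(image) - 1, cy + r2)
      sub <- image[ys + 1, xs + 1, drop = FALSE]
      dd <- outer((ys - hough$y_px[i])^2, (xs - hough$x_px[i])^2, "+")
      inner <- dd <= r^2
      ring <- dd > r^2 & dd <= r2^2
      c(if (any(inner)) mean(sub[inner]) else mean(sub),
        if (any(ring)) mean(sub[ring]) else -Inf)
    }, numeric(2))
    hough$mean_intensity <- con[1, ]  # report raw-scale intensity
    hough <- hough[con[1, ] > con[2, ], , drop = FALSE]
  }
  merged <- rbind(cont, hough)
  if (nrow(merged) == 0) return(spot_table(channel = channel))
  # contour first (its geometry wins), then greedy distance NMS
  prio <- order(merged$method != "contour", merged$y_px, merged$x_px)
  merged <- merged[prio, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(merged))) {
    if (length(keep) == 0) { keep <- i; next }
    d2 <- (merged$x_px[keep] - merged$x_px[i])^2 +
      (merged$y_px[keep] - merged$y_px[i])^2
    hit <- which(d2 < cfg$merge_dist_px^2)
    if (length(hit) == 0) keep <- c(keep, i)
    else if (merged$method[i] != merged$method[keep[hit[1]]])
      merged$method[keep[hit[1]]] <- "merged"
  }
  out <- merged[keep, , drop = FALSE]
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}
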