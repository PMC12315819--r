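spot_centers <- function(spots, what) {
  if (is.matrix(spots)) {
    if (ncol(spots) < 2) stop_param(what, "center matrix needs 2 columns (x, y)")
    return(cbind(x = spots[, 1], y = spots[, 2]))
  }
  if (is.data.frame(spots)) {
    if (!all(c("x_px", "y_px") %in% names(spots)))
      stop_param(what, "spot table needs x_px and y_px columns")
    return(cbind(x = spots$x_px, y = spots$y_px))
  }
  stop_param(what, "must be a spot data.frame or a 2-column matrix")
}

#' Match red and blue detections one-to-one
#'
#' Builds the bipartite graph with an edge whenever the center distance is
#' at most `d_max_px` and returns a maximum-cardinality one-to-one matching;
#' among maximum-cardinality matchings, total center distance is minimized.
#' Each matched red/blue pair is one putative co-aggregate. Deterministic
#' for a given input.
#'
#' @param red,blue spot tables from [detect_spots()] (or 2-column `(x, y)`
#'   center matrices) from the same field.
#' @param d_max_px matching radius in pixels (> 0).
#' @return an object of class `coloc_match`: a list with `pairs` (data.frame
#'   `red_index`, `blue_index`, `distance_px`, ordered by `red_index`) and
#'   `d_max_px`.
#' @export
#' @examples
#' red <- cbind(c(10, 50), c(10, 50))
#' blue <- cbind(c(11, 90), c(10, 90))
#' match_spots(red, blue, d_max_px = 3)$pairs
match_spots <- function(red, blue, d_max_px = 3) {
  check_scalar_num(d_max_px, "d_max_px")
  if (d_max_px <= 0) stop_param("d_max_px", "must be > 0")
  rc <- spot_centers(red, "red")
  bc <- spot_centers(blue, "blue")
  nr <- nrow(rc); nb <- nrow(bc)
  empty <- data.frame(red_index = integer(0), blue_index = integer(0),
                      distance_px = numeric(0))
  if (nr == 0 || nb == 0)
    return(structure(list(pairs = empty, d_max_px = d_max_px),
                     class = "coloc_match"))
  d <- sqrt(outer(rc[, 1], bc[, 1], "-")^2 + outer(rc[, 2], bc[, 2], "-")^2)
  edges <- which(d <= d_max_px, arr.ind = TRUE)
  if (nrow(edges) == 0)
    return(structure(list(pairs = empty, d_max_px = d_max_px),
                     class = "coloc_match"))
  # weight C - distance with C large enough that cardinality dominates any
  # total-distance difference, so max-weight matching = max cardinality,
  # then min total distance
  C <- d_max_px * (min(nr, nb) + 2) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nb)),
    edges = as.vector(t(cbind(edges[, 1], nr + edges[, 2]))))
  wt <- C - d[edges]
  mm <- igraph::max_bipartite_match(g, weights = wt, eps = 1e-8)
  mr <- mm$matching[seq_len(nr)]
  matched_red <- which(!is.na(mr))
  if (length(matched_red) == 0)
    return(structure(list(pairs = empty, d_max_px = d_max_px),
                     class = "coloc_match"))
  matched_blue <- as.integer(mr[matched_red]) - nr
  pairs <- data.frame(red_index = matched_red, blue_index = matched_blue,
                      distance_px = d[cbind(matched_red, matched_blue)])
  pairs <- pairs[order(pairs$red_index, pairs$blue_index), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, d_max_px = d_max_px), class = "coloc_match")
}

#' @export
print.coloc_match <- function(x, ...) {
  cat(sprintf("<coloc_match> %d pairs within %.2f px\n",
              nrow(x$pairs), x$d_max_px))
  invisible(x)
}

#' Expected number of coincidental overlaps under spatial randomness
#'
#' Under complete spatial randomness of both channels in the dilute regime,
#' the expected number of red/blue center pairs within `d_max_px` is
#' `n_red * n_blue * pi * d_max_px^2 / area_px2`. Subtracting this from the
#' observed matched count corrects the co-aggregate count for the two
#' targets being merely adjacent by chance.
#'
#' @param n_red,n_blue per-channel detection counts.
#' @param area_px2 field area in pixels^2 (> 0).
#' @param d_max_px matching radius in pixels.
#' @return the expected chance overlap count (nonnegative real).
#' @export
#' @examples
#' expected_chance_coloc(20, 20, 512^2, 3)
expected_chance_coloc <- function(n_red, n_blue, area_px2, d_max_px = 3) {
  check_scalar_num(n_red, "n_red", lower = 0)
  check_scalar_num(n_blue, "n_blue", lower = 0)
  check_scalar_num(area_px2, "area_px2", lower = 1e-12)
  check_scalar_num(d_max_px, "d_max_px", lower = 0)
  n_red * n_blue * pi * d_max_px^2 / area_px2
}

#' Per-field co-localization summary
#'
#' Combines per-channel counts and the matched-pair count into the field's
#' co-aggregate readout: the raw matched count `n_coloc`, the coincidental
#' expectation under spatial randomness, the chance-corrected count
#' `max(0, n_coloc - expected_chance)`, and the co-localization rate
#' `n_coloc / n_red` (the positive rate of co-aggregates out of the red,
#' alpha-synuclein channel; 0 when no red spots).
#'
#' @param match a [match_spots()] result.
#' @param n_red,n_blue per-channel detection counts (must be consistent with
#'   `match`).
#' @param area_px2 field area in pixels^2.
#' @param pixel_size_um pixel pitch, used to report the field area in mm^2.
#' @return an object of class `coloc_summary` (also a one-row data.frame)
#'   with columns `n_red`, `n_blue`, `n_coloc`, `expected_chance`,
#'   `corrected_count`, `coloc_rate`, `field_area_mm2`.
#' @export
coloc_summary <- function(match, n_red, n_blue, area_px2,
                          pixel_size_um = 0.325) {
  stopifnot(inherits(match, "coloc_match"))
  check_scalar_num(n_red, "n_red", lower = 0)
  check_scalar_num(n_blue, "n_blue", lower = 0)
  check_scalar_num(area_px2, "area_px2", lower = 1e-12)
  n_coloc <- nrow(match$pairs)
  if (n_coloc > min(n_red, n_blue))
    stop("internal inconsistency: n_coloc exceeds min(n_red, n_blue)")
  expected <- expected_chance_coloc(n_red, n_blue, area_px2, match$d_max_px)
  out <- data.frame(
    n_red = as.integer(n_red), n_blue = as.integer(n_blue),
    n_coloc = as.integer(n_coloc),
    expected_chance = expected,
    corrected_count = max(0, n_coloc - expected),
    coloc_rate = if (n_red > 0) n_coloc / n_red else 0,
    field_area_mm2 = field_area_mm2(npix = area_px2,
                                    pixel_size_um = pixel_size_um))
  class(out) <- c("coloc_summary", "data.frame")
  out
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf(
    "<coloc_summary> red %d, blue %d, coloc %d (chance %.3f, corrected %.2f, rate %.3f)\n",
    x$n_red, x$n_blue, x$n_coloc, x$expected_chance, x$corrected_count,
    x$coloc_rate))
  invisible(x)
}

#' Co-localization analysis of one dual-channel field
#'
#' Convenience wrapper: detect spots in both channels, match them, and
#' summarize. Channels are detected independently (exposures differ between
#' channels, so intensities are never compared across channels).
#'
#' @param field a `dual_field` object.
#' @param cfg a [detect_config()].
#' @param d_max_px matching radius in pixels.
#' @return a list with `red`, `blue` (spot tables), `match` and `summary`.
#' @export
coloc_field <- function(field, cfg = detect_config(), d_max_px = 3) {
  stopifnot(inherits(field, "dual_field"))
  red <- detect_spots(field$red_image, cfg, channel = "red")
  blue <- detect_spots(field$blue_image, cfg, channel = "blue")
  m <- match_spots(red, blue, d_max_px)
  s <- coloc_summary(m, nrow(red), nrow(blue),
                     area_px2 = length(field$red_image),
                     pixel_size_um = field$pixel_size_um)
  list(red = red, blue = blue, match = m, summary = s)
}

#' Estimate the integer shift between two channel images
#'
#' Whole-pixel translation registration by FFT cross-correlation, provided
#' for acquisitions where the stage drifted between the two sequential
#' exposures. Channels are assumed registered by default and this step is
#' not applied unless requested.
#'
#' @param red_image,blue_image equal-shape numeric matrices.
#' @param max_shift_px largest shift searched in either axis.
#' @return integer vector `c(dx, dy)`: the shift to apply to the blue image
#'   to align it with the red image.
#' @export
register_channels <- function(red_image, blue_image, max_shift_px = 10) {
  check_image(red_image); check_image(blue_image)
  if (!all(dim(red_image) == dim(blue_image)))
    stop_param("blue_image", "must have the same shape as red_image")
  a <- red_image - mean(red_image)
  b <- blue_image - mean(blue_image)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  h <- nrow(cc); w <- ncol(cc)
  sy <- c(0:(h %/% 2), -((h - 1) %/% 2):-1)
  sx <- c(0:(w %/% 2), -((w - 1) %/% 2):-1)
  ok_y <- abs(sy) <= max_shift_px
  ok_x <- abs(sx) <= max_shift_px
  sub <- cc[ok_y, ok_x, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c(dx = sx[ok_x][best[2]], dy = sy[ok_y][best[1]])
}
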