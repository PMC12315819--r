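#' Aggregate field-level co-localization summaries to a well
#'
#' Sums counts and imaged areas over the fields of one well and reports
#' densities per mm^2. Densities (rather than raw counts) make acquisitions
#' from different platforms and magnifications comparable, since the pixel
#' pitch enters through the imaged area. Counts are summed (not averaged)
#' before normalization: they are Poisson-like, and sums preserve the
#' information.
#'
#' @param field_summaries a list of [coloc_summary()] objects (>= 1).
#' @param dilution_factor dilution applied to the analyte (e.g. 100 for
#'   100-fold diluted serum).
#' @param well_id,sample_id identifiers carried through.
#' @return an object of class `well_summary` (one-row data.frame) with
#'   totals, total area, densities per mm^2 and the dilution factor.
#' @export
#' @examples
#' m <- match_spots(cbind(1, 1), cbind(1.5, 1), 3)
#' s <- coloc_summary(m, 1, 1, 512^2, pixel_size_um = 0.977)
#' summarize_well(list(s, s))
summarize_well <- function(field_summaries, dilution_factor = 1,
                           well_id = "well1", sample_id = "sample1") {
  if (!is.list(field_summaries) || length(field_summaries) == 0)
    stop_param("field_summaries", "must be a non-empty list of coloc_summary")
  ok <- vapply(field_summaries, inherits, logical(1), "coloc_summary")
  if (!all(ok))
    stop_param("field_summaries", "all elements must be coloc_summary objects")
  check_scalar_num(dilution_factor, "dilution_factor", lower = 1e-12)
  tab <- do.call(rbind, lapply(field_summaries, as.data.frame))
  total_area <- sum(tab$field_area_mm2)
  out <- data.frame(
    well_id = well_id, sample_id = sample_id,
    n_fields = nrow(tab),
    total_red = sum(tab$n_red), total_blue = sum(tab$n_blue),
    total_coloc = sum(tab$n_coloc),
    total_corrected = sum(tab$corrected_count),
    total_area_mm2 = total_area,
    density_red = sum(tab$n_red) / total_area,
    density_blue = sum(tab$n_blue) / total_area,
    density_coloc = sum(tab$n_coloc) / total_area,
    density_corrected = sum(tab$corrected_count) / total_area,
    mean_coloc_per_field = mean(tab$n_coloc),
    dilution_factor = dilution_factor,
    stringsAsFactors = FALSE)
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Standard dilution series of the validation batch
#'
#' One validation batch: the aggregate standard is diluted from the top
#' concentration in fixed folds (1 ug/mL start, 8 steps of 5-fold in the
#' reference protocol), plus blank wells.
#'
#' @param concentrations standard concentrations in ug/mL, strictly
#'   decreasing.
#' @param red_counts,blue_counts detected particle counts per step.
#' @param standard_type `"alpha_syn_only"` or `"coaggregate"`.
#' @param blank_red,blank_blue blank-well counts.
#' @return an object of class `standard_series`.
#' @export
standard_series <- function(concentrations, red_counts, blue_counts,
                            standard_type = c("alpha_syn_only", "coaggregate"),
                            blank_red = 0, blank_blue = 0) {
  standard_type <- match.arg(standard_type)
  if (!is.numeric(concentrations) || length(concentrations) < 2)
    stop_param("concentrations", "need at least 2 numeric steps")
  if (any(diff(concentrations) >= 0))
    stop_param("concentrations", "must be strictly decreasing")
  if (length(red_counts) != length(concentrations) ||
      length(blue_counts) != length(concentrations))
    stop_param("red_counts", "counts must match the number of steps")
  if (any(red_counts < 0) || any(blue_counts < 0))
    stop_param("red_counts", "counts must be nonnegative")
  check_scalar_num(blank_red, "blank_red", lower = 0)
  check_scalar_num(blank_blue, "blank_blue", lower = 0)
  structure(list(concentrations = as.numeric(concentrations),
                 red_counts = as.numeric(red_counts),
                 blue_counts = as.numeric(blue_counts),
                 standard_type = standard_type,
                 blank_red = blank_red, blank_blue = blank_blue),
            class = "standard_series")
}

#' Dilution linearity of a standard series
#'
#' Fits the least-squares slope of `log(count)` against `log(relative
#' concentration)` over the quantifiable steps; an ideal assay in the
#' dilute regime has slope 1. Also reports whether counts are monotone
#' (non-increasing with dilution).
#'
#' Steps with counts below `min_count` are excluded from the fit: far down
#' the series the true signal falls beneath the detector's residual
#' false-count floor, so sub-quantitation-limit steps measure the detector
#' background rather than the analyte and would flatten the fitted slope.
#' The default (`min_count = 0`, i.e. use every nonzero step) keeps the
#' naive behaviour; pass e.g. `min_count = 1` to fit only steps averaging at
#' least one detected particle per field.
#'
#' @param series a [standard_series()] object.
#' @param channel which channel's counts to use.
#' @param min_count limit of quantitation: steps with counts below this are
#'   excluded from the slope fit (monotonicity still uses all steps).
#' @return a list with `slope`, `intercept`, `r_squared`, `monotone`,
#'   `n_used`.
#' @export
#' @examples
#' s <- standard_series(c(1, 0.2, 0.04), c(500, 100, 20), c(0, 0, 0))
#' dilution_linearity(s)$slope
dilution_linearity <- function(series, channel = c("red", "blue"),
                               min_count = 0) {
  stopifnot(inherits(series, "standard_series"))
  channel <- match.arg(channel)
  check_scalar_num(min_count, "min_count", lower = 0)
  counts <- if (channel == "red") series$red_counts else series$blue_counts
  if (all(counts == 0)) stop_param("series", "all counts are zero")
  rel <- series$concentrations / max(series$concentrations)
  use <- counts > 0 & counts >= min_count
  if (sum(use) < 3)
    stop_param("series", "need at least 3 quantifiable steps")
  if (all(counts[use] == counts[use][1])) {
    fitted <- list(slope = 0, intercept = log(counts[use][1]), r_squared = 1)
  } else {
    fit <- lm(log(counts[use]) ~ log(rel[use]))
    # suppressWarnings: an exactly proportional series triggers lm's
    # "essentially perfect fit" warning, which is the expected case here
    fitted <- list(slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   r_squared = suppressWarnings(summary(fit)$r.squared))
  }
  c(fitted, list(monotone = all(diff(counts) <= 0), n_used = sum(use)))
}

#' QC thresholds for batch validation
#'
#' The reference protocol declares a batch failed when "the standard curve
#' was poor" or when "massive" amylin-channel signal appears in the
#' alpha-synuclein-only validation batch, without quantifying either. These
#' defaults draw the line: a curve is poor when the counts are not monotone
#' over the informative steps, the concentration/count Spearman rank
#' correlation falls below `min_rank_corr`, or the top standard does not
#' exceed the blank; bleed-through is massive when total blue counts exceed
#' `max_bleedthrough_frac` of total red counts.
#'
#' @param min_rank_corr minimum Spearman correlation between concentration
#'   and red count.
#' @param max_bleedthrough_frac maximum tolerated blue/red total count ratio
#'   for an alpha-syn-only standard.
#' @return a list of thresholds.
#' @export
qc_thresholds <- function(min_rank_corr = 0.9, max_bleedthrough_frac = 0.1) {
  check_scalar_num(min_rank_corr, "min_rank_corr", lower = -1, upper = 1)
  check_scalar_num(max_bleedthrough_frac, "max_bleedthrough_frac", lower = 0)
  list(min_rank_corr = min_rank_corr,
       max_bleedthrough_frac = max_bleedthrough_frac)
}

#' Batch QC verdict for a validation standard series
#'
#' Applies the batch-failure rules to one validation series. Monotonicity is
#' assessed over the informative steps (down to the first step at or below
#' the blank count: steps below the blank carry no curve information, so
#' Poisson-level inversions among them do not fail a clean batch).
#'
#' @param series a [standard_series()] object with `standard_type` set.
#' @param thresholds a [qc_thresholds()] list.
#' @return an object of class `qc_verdict`: list with `passed` (logical) and
#'   `reasons` (character vector among `poor_standard_curve`,
#'   `amylin_bleedthrough`; empty iff passed).
#' @export
#' @examples
#' s <- standard_series(c(1, 0.2, 0.04, 0.008), c(800, 160, 32, 6), rep(0, 4))
#' qc_batch(s)$passed
qc_batch <- function(series, thresholds = qc_thresholds()) {
  stopifnot(inherits(series, "standard_series"))
  if (is.null(series$blank_red) || is.null(series$blank_blue))
    stop_param("series", "blank counts are required")
  reasons <- character(0)

  counts <- series$red_counts
  conc <- series$concentrations
  # informative steps: until the curve first reaches the blank floor
  floor_ct <- max(series$blank_red, 0)
  above <- counts > floor_ct
  last_inform <- if (any(!above)) min(which(!above)) else length(counts)
  inform <- seq_len(last_inform)
  monotone <- all(diff(counts[inform]) <= 0)
  rank_corr <- suppressWarnings(cor(conc, counts, method = "spearman"))
  top_ok <- counts[1] > series$blank_red
  if (!monotone || is.na(rank_corr) ||
      rank_corr < thresholds$min_rank_corr || !top_ok)
    reasons <- c(reasons, "poor_standard_curve")

  if (series$standard_type == "alpha_syn_only") {
    tot_red <- sum(series$red_counts)
    tot_blue <- sum(series$blue_counts)
    if (tot_red > 0 && tot_blue > thresholds$max_bleedthrough_frac * tot_red)
      reasons <- c(reasons, "amylin_bleedthrough")
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  if (x$passed) cat("<qc_verdict> PASSED\n")
  else cat("<qc_verdict> FAILED:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
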