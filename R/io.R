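#' Write a dual-channel field as paired 16-bit TIFFs with a JSON sidecar
#'
#' Writes `<basename>_red.tif` and `<basename>_blue.tif` (16-bit grayscale)
#' plus `<basename>.json` carrying pixel size, exposures, identifiers and,
#' when supplied, the simulation ground truth.
#'
#' @param field a `dual_field` object.
#' @param dir output directory (created if needed).
#' @param basename file stem; defaults to the field id.
#' @param truth optional `ground_truth_field` stored in the sidecar.
#' @return the three file paths, invisibly.
#' @export
write_field <- function(field, dir, basename = field$field_id, truth = NULL) {
  stopifnot(inherits(field, "dual_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_red <- file.path(dir, paste0(basename, "_red.tif"))
  p_blue <- file.path(dir, paste0(basename, "_blue.tif"))
  p_json <- file.path(dir, paste0(basename, ".json"))
  tiff::writeTIFF(field$red_image / 65535, p_red, bits.per.sample = 16L)
  tiff::writeTIFF(field$blue_image / 65535, p_blue, bits.per.sample = 16L)
  meta <- list(field_id = field$field_id, well_id = field$well_id,
               sample_id = field$sample_id,
               pixel_size_um = field$pixel_size_um,
               exposure_red_s = field$exposure_red_s,
               exposure_blue_s = field$exposure_blue_s)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ground_truth_field"))
    meta$ground_truth <- list(
      red_centers = unname(apply(truth$red_centers, 1, as.numeric,
                                 simplify = FALSE)),
      blue_centers = unname(apply(truth$blue_centers, 1, as.numeric,
                                  simplify = FALSE)),
      pair_index = unname(apply(truth$pair_index, 1, as.integer,
                                simplify = FALSE)),
      coloc_fraction = truth$coloc_fraction)
  }
  jsonlite::write_json(meta, p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(red = p_red, blue = p_blue, json = p_json))
}

read_one_tiff <- function(path, what) {
  if (!file.exists(path)) stop_param(what, paste("file not found:", path))
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) != 2)
    stop_param(what, sprintf("%s is not single-channel grayscale (dims: %s)",
                             path, paste(dim(img), collapse = "x")))
  bits <- attr(img, "bits.per.sample")
  up <- FALSE
  if (!is.null(bits) && bits == 8) {
    img <- img * 257L  # scale 8-bit to the 16-bit range
    up <- TRUE
  }
  storage.mode(img) <- "integer"
  attr(img, "upscaled_8bit") <- up
  img
}

#' Read a paired red/blue TIFF field
#'
#' Reads two equal-shape single-channel grayscale TIFFs into a `dual_field`.
#' Pixel size must come from the argument or from a `<stem>.json` sidecar
#' next to the red image. 8-bit inputs are accepted and up-scaled to the
#' 16-bit range (flagged with a message).
#'
#' @param path_red,path_blue file paths.
#' @param pixel_size_um pixel pitch; `NULL` to require a sidecar.
#' @param field_id,well_id,sample_id identifiers (sidecar values win).
#' @return a `dual_field` object.
#' @export
read_field_pair <- function(path_red, path_blue, pixel_size_um = NULL,
                            field_id = NULL, well_id = "well1",
                            sample_id = "sample1") {
  red <- read_one_tiff(path_red, "path_red")
  blue <- read_one_tiff(path_blue, "path_blue")
  if (!all(dim(red) == dim(blue)))
    stop_param("path_blue",
               sprintf("image shapes differ: red %s vs blue %s",
                       paste(dim(red), collapse = "x"),
                       paste(dim(blue), collapse = "x")))
  meta <- list()
  sidecar <- sub("_red\\.tiff?$", ".json", path_red)
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop_param("pixel_size_um",
               "missing: supply it or provide a JSON sidecar with pixel_size_um")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  if (isTRUE(attr(red, "upscaled_8bit")) || isTRUE(attr(blue, "upscaled_8bit")))
    message("8-bit input up-scaled to 16-bit range")
  structure(list(
    red_image = red, blue_image = blue,
    pixel_size_um = pixel_size_um,
    exposure_red_s = meta$exposure_red_s %||% 0.5,
    exposure_blue_s = meta$exposure_blue_s %||% 2,
    field_id = field_id %||% meta$field_id %||%
      sub("_red\\.tiff?$", "", basename(path_red)),
    well_id = meta$well_id %||% well_id,
    sample_id = meta$sample_id %||% sample_id
  ), class = "dual_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spot table to CSV
#'
#' Columns: `field_id`, `channel`, `x_px`, `y_px`, `radius_px`,
#' `mean_intensity`, `method`.
#'
#' @param spots a spot data.frame from [detect_spots()].
#' @param path output CSV path.
#' @param field_id field identifier column value.
#' @return `path`, invisibly.
#' @export
write_spots <- function(spots, path, field_id = "field1") {
  out <- cbind(field_id = field_id,
               spots[, c("channel", "x_px", "y_px", "radius_px",
                         "mean_intensity", "method")])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a spot table from CSV
#' @param path CSV path written by [write_spots()].
#' @return a spot data.frame.
#' @export
read_spots <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
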