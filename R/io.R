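# Reading and writing of meibography images, gland/tarsus masks and metrics
# tables. All rasters are held as base R matrices, rows x columns, row 1 at
# the top of the image; masks are co-registered with the image (no geometric
# transforms happen in this package).

#' Read a grayscale meibography image
#'
#' Reads an 8-bit (or 16-bit) PNG or TIFF image as a numeric matrix of
#' intensities on the native integer scale (0-255 for 8-bit, 0-65535 for
#' 16-bit). Multi-channel images are accepted only when all color channels
#' are identical (a gray image stored as RGB); true-color content is
#' rejected. An alpha channel, if present, must be fully opaque.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Numeric matrix of grayscale intensities.
#' @export
read_gray_image <- function(path) {
  arr <- read_raster(path)
  collapse_gray(arr, path)
}

read_raster <- function(path) {
  if (!file.exists(path)) mgm_io_stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    mgm_io_stop(sprintf("unsupported image format '%s' (PNG or TIFF required)", ext))
  )
  rescale_to_depth(arr)
}

# readPNG/readTIFF return values in [0, 1]; recover the native integer
# scale. Values are exact multiples of 1/255 for 8-bit content; anything
# finer is treated as 16-bit.
rescale_to_depth <- function(arr) {
  x8 <- arr * 255
  if (max(abs(x8 - round(x8))) < 1e-9) round(x8) else round(arr * 65535)
}

collapse_gray <- function(arr, path) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) != 3L)
    mgm_io_stop(sprintf("unexpected image dimensions in %s", path))
  nch <- dim(arr)[3]
  if (nch == 2L) {  # gray + alpha
    if (any(arr[, , 2] != max(arr[, , 2])))
      mgm_io_stop(sprintf("image %s has a non-trivial alpha channel", path))
    return(arr[, , 1])
  }
  if (nch %in% c(3L, 4L)) {
    if (nch == 4L && any(arr[, , 4] != max(arr[, , 4])))
      mgm_io_stop(sprintf("image %s has a non-trivial alpha channel", path))
    if (any(arr[, , 1] != arr[, , 2]) || any(arr[, , 1] != arr[, , 3]))
      mgm_io_stop(sprintf("image %s has true-color content; a grayscale image is required", path))
    return(arr[, , 1])
  }
  mgm_io_stop(sprintf("unsupported channel count (%d) in %s", nch, path))
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are clipped to [0, 255] and rounded to integers.
#' @param image Numeric matrix of intensities (0-255 scale).
#' @param path Output PNG path.
#' @export
write_gray_image <- function(image, path) {
  stopifnot_matrix(image, "image")
  img <- pmin(pmax(round(image), 0), 255)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read a gland label map
#'
#' Reads an integer-valued raster identifying each meibomian gland's pixel
#' set (0 = background) and canonicalizes it: labels become the contiguous
#' set `1..K`, ordered by raster-scan position of each component's
#' topmost-leftmost pixel, and each label is checked to be a single
#' 8-connected component. A binary raster (values 0/1, or 0/255 as written
#' by common mask editors) is accepted when `binary_ok` is `TRUE`: its
#' connected components are computed and labeled.
#'
#' @param path Path to a PNG or TIFF label raster.
#' @param binary_ok Accept a binary mask and derive labels from its
#'   8-connected components. Default `TRUE`.
#' @param reference_shape Optional `c(rows, cols)`; a shape mismatch is an
#'   error.
#' @return Integer label matrix (canonical `GlandLabelMap`).
#' @export
read_label_map <- function(path, binary_ok = TRUE, reference_shape = NULL) {
  arr <- read_raster(path)
  lab <- collapse_gray(arr, path)
  as_label_map(lab, binary_ok = binary_ok, reference_shape = reference_shape)
}

#' Coerce a matrix to a canonical gland label map
#'
#' In-memory counterpart of [read_label_map()].
#' @param labels Non-negative integer matrix (or binary matrix when
#'   `binary_ok`).
#' @inheritParams read_label_map
#' @return Integer label matrix with labels `1..K` in canonical order.
#' @export
as_label_map <- function(labels, binary_ok = TRUE, reference_shape = NULL) {
  stopifnot_matrix(labels, "labels")
  if (!is.null(reference_shape) && !identical(dim(labels), as.integer(reference_shape)))
    mgm_stop(sprintf("label map shape %s does not match reference %s",
                     paste(dim(labels), collapse = "x"),
                     paste(reference_shape, collapse = "x")))
  if (any(labels < 0)) mgm_stop("label map contains negative values")
  vals <- unique(as.vector(labels))
  if (binary_ok && all(vals %in% c(0, 1)))
    return(label_components(labels != 0))
  if (binary_ok && all(vals %in% c(0, 255)))
    return(label_components(labels != 0))
  canonicalize_labels(labels)
}

#' Write a gland label map as 8-bit PNG
#'
#' The label integer is stored directly in the 8-bit gray channel, so at
#' most 255 glands per image are supported (far above any clinical count).
#' @param labels Integer label matrix with `max(labels) <= 255`.
#' @param path Output PNG path.
#' @export
write_label_map <- function(labels, path) {
  stopifnot_matrix(labels, "labels")
  if (max(labels) > 255) mgm_io_stop("cannot store more than 255 labels in an 8-bit PNG")
  png::writePNG(labels / 255, target = path)
  invisible(path)
}

#' Read a tarsus region-of-interest mask
#'
#' Any nonzero pixel is part of the tarsal plate. The mask must be
#' non-empty.
#' @param path Path to a PNG or TIFF binary raster.
#' @return Logical matrix (`TarsusMask`).
#' @export
read_tarsus_mask <- function(path) {
  m <- collapse_gray(read_raster(path), path) != 0
  if (!any(m)) mgm_stop(sprintf("tarsus mask %s is empty", path))
  m
}

#' Write a tarsus mask as 8-bit PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_tarsus_mask <- function(mask, path) {
  stopifnot_matrix(mask, "mask")
  png::writePNG((mask != 0) * 1, target = path)
  invisible(path)
}

#' Validate that every gland pixel lies inside the tarsus
#'
#' The density definition (gland area over tarsus area) presumes glands are
#' contained in the tarsal plate; a gland pixel outside the tarsus is a
#' hard error, never silently clipped.
#' @param labels Gland label matrix.
#' @param tarsus Logical tarsus mask of the same shape.
#' @return Invisibly `TRUE`.
#' @export
validate_gland_tarsus <- function(labels, tarsus) {
  check_same_shape(labels, tarsus, "label map and tarsus mask")
  bad <- labels > 0 & !tarsus
  if (any(bad))
    mgm_stop(sprintf("%d gland pixel(s) lie outside the tarsus mask", sum(bad)))
  invisible(TRUE)
}

# Fixed CSV schema shared by per-gland and aggregate metric rows.
metrics_columns <- function() {
  c("subject_id", "eye_role", "eyelid", "gland_id", "height_px", "width_px",
    "tortuosity", "density", "vagueness", "interval_months", "tbut_s", "tmh_mm")
}

#' Write a metrics table to CSV
#'
#' Rows may be per-gland (integer `gland_id`) or eyelid aggregates
#' (`gland_id == "AGGREGATE"`). The column set is fixed; missing fields are
#' written as `NA`. Values round-trip through [read_metrics_table()] beyond
#' 6 significant digits.
#'
#' @param records Data frame of metric rows.
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(records, path) {
  cols <- metrics_columns()
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    records <- as.data.frame(records)
    missing_cols <- setdiff(cols, names(records))
    for (mc in missing_cols) records[[mc]] <- NA
    records <- records[, cols]
  }
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mgm_io_stop(sprintf("cannot write metrics table to %s", path))
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return Data frame with the fixed metrics schema.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) mgm_io_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(metrics_columns(), names(df))
  if (length(missing_cols))
    mgm_io_stop(sprintf("metrics table %s lacks column(s): %s",
                        path, paste(missing_cols, collapse = ", ")))
  df[, metrics_columns()]
}
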