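# Vagueness value: the gland-versus-background grayscale contrast inside
# the tarsus. Background means the tarsus minus the glands; pixels outside
# the tarsus never enter either mean. The value is a signed difference and
# is not clamped: glands darker than the surrounding tarsus give a negative
# value, and higher values mean a clearer image.

#' Vagueness value of an eyelid image
#'
#' Mean grayscale of the gland pixels minus mean grayscale of the non-gland
#' tarsus pixels:
#' \deqn{vagueness = \bar g_{MG} - \frac{\sum_{tarsus} g - \sum_{MG} g}
#'       {n_{tarsus} - n_{MG}}}
#'
#' @param image Numeric grayscale matrix (see [read_gray_image()]).
#' @param labels Gland label matrix, same shape.
#' @param tarsus Logical tarsus mask, same shape; must contain at least one
#'   non-gland pixel.
#' @return List of class `vagueness_result` with `mean_gland_gray`,
#'   `mean_background_gray`, `vagueness`, `n_gland_px`, `n_background_px`.
#'   With no glands the gland mean (and hence the vagueness) is `NA`.
#' @export
vagueness_value <- function(image, labels, tarsus) {
  stopifnot_matrix(image, "image")
  check_same_shape(image, labels, "image and label map")
  check_same_shape(image, tarsus, "image and tarsus mask")
  if (!any(tarsus)) mgm_stop("tarsus mask is empty")
  validate_gland_tarsus(labels, tarsus)
  gland <- labels > 0
  n_gland <- sum(gland)
  n_tarsus <- sum(tarsus)
  n_bg <- n_tarsus - n_gland
  if (n_bg == 0L)
    mgm_degenerate_stop("tarsus is entirely gland: background mean undefined")
  sum_tarsus <- sum(image[tarsus])
  sum_gland <- sum(image[gland])
  mean_bg <- (sum_tarsus - sum_gland) / n_bg
  mean_gland <- if (n_gland > 0L) sum_gland / n_gland else NA_real_
  structure(list(
    mean_gland_gray = mean_gland,
    mean_background_gray = mean_bg,
    vagueness = mean_gland - mean_bg,
    n_gland_px = n_gland, n_background_px = n_bg
  ), class = "vagueness_result")
}

#' @export
print.vagueness_result <- function(x, ...) {
  cat(sprintf("Vagueness %.3f (gland mean %.3f over %d px, background mean %.3f over %d px)\n",
              x$vagueness, x$mean_gland_gray, x$n_gland_px,
              x$mean_background_gray, x$n_background_px))
  invisible(x)
}

# Fixed sequential palette (light yellow -> orange -> dark red); the blue
# channel decreases monotonically along the ramp, which tests rely on.
vagueness_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#FFFFCC", "#FD8D3C", "#800026"))(n)
}

#' Render a vagueness heat map
#'
#' Deterministic, purely presentational rendering of a matrix of vagueness
#' values (e.g. subjects in rows, groups in columns) to an RGB raster with a
#' fixed colormap and a fixed value range, so identical inputs always give
#' byte-identical images. Values outside `range` are clipped. The default
#' range 0-60 covers the contrasts typically seen in clinical meibography.
#'
#' @param values Numeric matrix (or vector, treated as a single row) of
#'   vagueness values; must be non-empty. `NA` cells render as mid-gray.
#' @param path Optional PNG output path.
#' @param range Value range mapped onto the colormap. Default `c(0, 60)`.
#' @param cell_px Edge length of each rendered cell in pixels. Default 24.
#' @return Invisibly, the RGB array (rows x cols x 3, values in \[0, 1\]).
#' @export
vagueness_heatmap <- function(values, path = NULL, range = c(0, 60), cell_px = 24) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || length(values) == 0L)
    mgm_stop("heat map input must be a non-empty numeric matrix")
  if (range[2] <= range[1]) mgm_stop("invalid value range")
  pal <- vagueness_palette(256)
  rel <- (pmin(pmax(values, range[1]), range[2]) - range[1]) / (range[2] - range[1])
  idx <- pmin(255L, as.integer(floor(rel * 256))) + 1L
  cols <- ifelse(is.na(values), "#808080", pal[idx])
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(values) * cell_px, ncol(values) * cell_px, 3))
  for (ch in 1:3) {
    chan <- matrix(rgb[ch, ], nrow(values), ncol(values))
    out[, , ch] <- chan[rep(seq_len(nrow(values)), each = cell_px),
                        rep(seq_len(ncol(values)), each = cell_px)]
  }
  if (!is.null(path)) png::writePNG(out, target = path)
  invisible(out)
}
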