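# Per-gland and per-eyelid morphological indices.
#
# Definitions:
#   height     = inclusive vertical pixel extent, bottom_row - top_row + 1
#   width      = area / height
#   perimeter  = number of gland pixels with at least one 4-neighbor outside
#                the gland (the image border counts as outside)
#   tortuosity = perimeter / (2 * height of the minimum external rectangle) - 1
#   density    = sum of gland pixel areas / tarsus pixel area
#
# The minimum external rectangle is the minimum-area rotated rectangle
# enclosing the pixel-center convex hull; its "height" is the LONGER side,
# since glands are elongated and the rectangle measures length along the
# gland axis.

#' Vertical height of a gland in pixels
#'
#' The inclusive pixel extent between the gland's top and bottom pixels
#' (`bottom_row - top_row + 1`), so a single-pixel gland has height 1 and
#' `width = area / height` is exact for filled rectangles. The exclusive
#' variant (`bottom_row - top_row`) is available for sensitivity checks.
#'
#' @param coords Two-column matrix of (row, col) pixel coordinates.
#' @param inclusive Use the inclusive extent (default) or the bare
#'   top-bottom difference.
#' @return Height in pixels.
#' @export
gland_height <- function(coords, inclusive = TRUE) {
  coords <- as_coords(coords)
  h <- max(coords[, 1]) - min(coords[, 1])
  if (inclusive) h + 1L else h
}

#' Mean width of a gland in pixels
#'
#' Defined as pixel area divided by height.
#' @inheritParams gland_height
#' @export
gland_width <- function(coords, inclusive = TRUE) {
  coords <- as_coords(coords)
  nrow(coords) / gland_height(coords, inclusive = inclusive)
}

#' Boundary-pixel perimeter of a gland
#'
#' Counts gland pixels having at least one 4-neighbor (up/down/left/right)
#' outside the gland. Pixels on the image border always count: off-image
#' positions are outside.
#' @inheritParams gland_height
#' @return Number of boundary pixels.
#' @export
gland_perimeter <- function(coords) {
  nrow(boundary_coords(coords))
}

# Subset of gland pixels that are 4-boundary pixels.
boundary_coords <- function(coords) {
  coords <- as_coords(coords)
  key <- coord_key(coords[, 1], coords[, 2])
  inside <- coord_key(coords[, 1] - 1L, coords[, 2]) %in% key &
    coord_key(coords[, 1] + 1L, coords[, 2]) %in% key &
    coord_key(coords[, 1], coords[, 2] - 1L) %in% key &
    coord_key(coords[, 1], coords[, 2] + 1L) %in% key
  coords[!inside, , drop = FALSE]
}

coord_key <- function(r, c) r * 2097152 + c  # rows/cols far below 2^21

as_coords <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) < 1L)
    mgm_stop("gland pixel coordinates must be a non-empty two-column (row, col) matrix")
  coords
}

#' Minimum external rectangle of a gland
#'
#' Minimum-area rotated rectangle enclosing the convex hull of the gland's
#' pixel centers (a pixel at (r, c) is the point (r, c)), found by rotating
#' calipers over the hull edges. The reported height is the longer side.
#' Degenerate collinear pixel sets return the hull segment length as height
#' (a single pixel returns 1 by convention). Among equal-area rectangles the
#' smallest absolute angle wins, so results are deterministic.
#'
#' @inheritParams gland_height
#' @return List with `height_px` (longer side), `width_px` (shorter side),
#'   `angle_deg` (orientation of the long axis relative to the vertical
#'   image axis, in degrees within \[-90, 90)), and `area` of the rectangle.
#' @export
min_external_rect <- function(coords) {
  coords <- as_coords(coords)
  y <- coords[, 1]; x <- coords[, 2]    # y = row (down), x = col (right)
  if (nrow(coords) == 1L ||
      (max(y) == min(y) && max(x) == min(x)))
    return(list(height_px = 1, width_px = 1, angle_deg = 0, area = 1))
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  if (length(hull) <= 2L || hull_collinear(hx, hy)) {
    d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
    ij <- arrayInd(which.max(d2), dim(d2))
    i <- ij[1]; j <- ij[2]
    ang <- if (i == j) 0 else axis_angle(hy[j] - hy[i], hx[j] - hx[i])
    return(list(height_px = sqrt(max(d2)), width_px = 0, angle_deg = ang, area = 0))
  }
  nh <- length(hull)
  ex <- hx[c(2:nh, 1)] - hx; ey <- hy[c(2:nh, 1)] - hy
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  ex <- ex[keep] / len[keep]; ey <- ey[keep] / len[keep]
  P <- rbind(hx, hy)                       # 2 x H
  MU <- cbind(ex, ey) %*% P                # edge-aligned projections, E x H
  MV <- cbind(-ey, ex) %*% P
  rowrange <- function(M) {
    i <- seq_len(nrow(M))
    M[cbind(i, max.col(M, ties.method = "first"))] -
      M[cbind(i, max.col(-M, ties.method = "first"))]
  }
  du <- rowrange(MU); dv <- rowrange(MV)
  area <- du * dv
  cand <- which(area <= min(area) + 1e-9)
  # long-side direction per candidate edge: u when du >= dv, else v
  ang <- vapply(cand, function(k) {
    if (du[k] >= dv[k]) axis_angle(ey[k], ex[k]) else axis_angle(ex[k], -ey[k])
  }, numeric(1))
  best <- cand[order(abs(ang), ang)][1]
  list(height_px = max(du[best], dv[best]), width_px = min(du[best], dv[best]),
       angle_deg = ang[order(abs(ang), ang)][1], area = area[best])
}

# angle of direction (dy, dx) measured from the vertical (row) axis,
# mapped into [-90, 90)
axis_angle <- function(dy, dx) {
  ang <- atan2(dx, dy) * 180 / pi
  while (ang >= 90) ang <- ang - 180
  while (ang < -90) ang <- ang + 180
  ang
}

hull_collinear <- function(hx, hy) {
  if (length(hx) < 3L) return(TRUE)
  x1 <- hx - hx[1]; y1 <- hy - hy[1]
  j <- which.max(x1^2 + y1^2)
  all(abs(x1[j] * y1 - y1[j] * x1) < 1e-9)
}

#' Tortuosity of a gland
#'
#' Boundary-pixel perimeter divided by twice the height of the minimum
#' external rectangle, minus one. A perfectly straight vertical gland gives
#' a value near 0; meandering glands give larger values.
#' @inheritParams gland_height
#' @export
gland_tortuosity <- function(coords) {
  coords <- as_coords(coords)
  p <- gland_perimeter(coords)
  h <- min_external_rect(coords)$height_px
  if (h <= 0) mgm_degenerate_stop("minimum external rectangle has zero height")
  p / (2 * h) - 1
}

#' Per-gland morphometrics for a label map
#'
#' Computes, for every labeled gland, its area, vertical extent, height,
#' width, boundary perimeter, minimum-external-rectangle height/angle, and
#' tortuosity.
#'
#' @param labels Canonical gland label matrix (see [as_label_map()]).
#' @param height_convention `"inclusive"` (default; extent = bottom - top + 1)
#'   or `"exclusive"` (bottom - top).
#' @return Data frame with one row per gland.
#' @export
gland_metrics <- function(labels, height_convention = c("inclusive", "exclusive")) {
  height_convention <- match.arg(height_convention)
  stopifnot_matrix(labels, "labels")
  n <- nrow(labels)
  idx <- which(labels > 0)
  K <- if (length(idx)) max(labels[idx]) else 0L
  if (K == 0L)
    return(data.frame(gland_id = integer(0), area_px = integer(0),
                      top_row = integer(0), bottom_row = integer(0),
                      height_px = numeric(0), width_px = numeric(0),
                      perimeter_px = integer(0), minrect_height_px = numeric(0),
                      minrect_angle_deg = numeric(0), tortuosity = numeric(0)))
  labs <- as.integer(labels[idx])
  rows <- (idx - 1L) %% n + 1L
  cols <- (idx - 1L) %/% n + 1L

  # boundary pixels for all glands in one vectorized pass over the image
  bmask <- label_boundary_mask(labels)
  perim <- tabulate(labels[bmask], nbins = K)
  bidx <- which(bmask)
  blabs <- as.integer(labels[bidx])
  brows <- (bidx - 1L) %% n + 1L
  bcols <- (bidx - 1L) %/% n + 1L
  bsplit <- split(seq_along(blabs), blabs)

  area <- tabulate(labs, nbins = K)
  rsplit <- split(rows, labs)
  top <- vapply(rsplit, min, integer(1))
  bottom <- vapply(rsplit, max, integer(1))
  extent <- bottom - top + if (height_convention == "inclusive") 1L else 0L
  width <- ifelse(extent > 0, area / extent, NA_real_)

  mr_h <- numeric(K); mr_a <- numeric(K)
  for (k in seq_len(K)) {
    sel <- bsplit[[as.character(k)]]
    mr <- min_external_rect(cbind(brows[sel], bcols[sel]))
    mr_h[k] <- mr$height_px
    mr_a[k] <- mr$angle_deg
  }
  data.frame(
    gland_id = seq_len(K), area_px = area, top_row = top, bottom_row = bottom,
    height_px = as.numeric(extent), width_px = width, perimeter_px = perim,
    minrect_height_px = mr_h, minrect_angle_deg = mr_a,
    tortuosity = perim / (2 * mr_h) - 1
  )
}

# Logical mask of 4-boundary pixels across all labels at once; the image
# border counts as outside.
label_boundary_mask <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  up <- rbind(-1L, labels[-n, , drop = FALSE])
  down <- rbind(labels[-1L, , drop = FALSE], -1L)
  left <- cbind(-1L, labels[, -m, drop = FALSE])
  right <- cbind(labels[, -1L, drop = FALSE], -1L)
  labels > 0 & (labels != up | labels != down | labels != left | labels != right)
}

#' Gland density of an eyelid
#'
#' Ratio of the summed gland pixel areas to the tarsus pixel area, in
#' \[0, 1\]. Glands must lie inside the tarsus and the tarsus must be
#' non-empty.
#' @param labels Gland label matrix.
#' @param tarsus Logical tarsus mask of the same shape.
#' @export
eyelid_density <- function(labels, tarsus) {
  check_same_shape(labels, tarsus, "label map and tarsus mask")
  if (!any(tarsus)) mgm_stop("tarsus mask is empty")
  validate_gland_tarsus(labels, tarsus)
  sum(labels > 0) / sum(tarsus)
}

#' Eyelid-level summary of gland morphology
#'
#' Computes per-gland metrics for all glands and aggregates them to the
#' eyelid level: unweighted means of height, width and tortuosity, the
#' gland density, and (when an image is supplied) the vagueness value.
#' With zero glands the density is 0 and the means are `NA`.
#'
#' @param labels Canonical gland label matrix.
#' @param tarsus Logical tarsus mask.
#' @param eyelid `"upper"` or `"lower"`.
#' @param image Optional grayscale image for the vagueness value.
#' @inheritParams gland_metrics
#' @return List of class `eyelid_metrics` with fields `eyelid`, `n_glands`,
#'   `mean_height_px`, `mean_width_px`, `mean_tortuosity`, `density`,
#'   `vagueness`, `gland_px`, `tarsus_px`, and the per-gland table in
#'   `$glands`.
#' @export
summarize_eyelid <- function(labels, tarsus, eyelid = c("upper", "lower"),
                             image = NULL,
                             height_convention = c("inclusive", "exclusive")) {
  eyelid <- match.arg(eyelid)
  g <- gland_metrics(labels, height_convention = match.arg(height_convention))
  dens <- eyelid_density(labels, tarsus)
  vag <- NA_real_
  if (!is.null(image) && nrow(g) > 0) {
    vag <- vagueness_value(image, labels, tarsus)$vagueness
  }
  K <- nrow(g)
  structure(list(
    eyelid = eyelid, n_glands = K,
    mean_height_px = if (K) mean(g$height_px) else NA_real_,
    mean_width_px = if (K) mean(g$width_px) else NA_real_,
    mean_tortuosity = if (K) mean(g$tortuosity) else NA_real_,
    density = dens, vagueness = vag,
    gland_px = sum(g$area_px), tarsus_px = sum(tarsus),
    glands = g
  ), class = "eyelid_metrics")
}

#' Combine upper- and lower-eyelid summaries
#'
#' The "both eyelids" value of each index is by default the unweighted mean
#' of the upper- and lower-eyelid values; gland counts sum. If either
#' eyelid's value is missing the combined value is missing. A pooled
#' recomputation (gland-count-weighted means, pixel-pooled density) is
#' available via `method = "pooled"`.
#'
#' @param upper,lower `eyelid_metrics` objects from [summarize_eyelid()].
#' @param method `"mean"` (default) or `"pooled"`.
#' @return `eyelid_metrics` object with `eyelid = "both"`.
#' @export
combine_eyelids <- function(upper, lower, method = c("mean", "pooled")) {
  method <- match.arg(method)
  if (is.null(upper) || is.null(lower))
    mgm_stop("both eyelid summaries are required to combine")
  comb2 <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else (a + b) / 2
  pooled_mean <- function(a, b, na_, nb_) {
    if (is.na(a) || is.na(b) || (na_ + nb_) == 0) NA_real_
    else (a * na_ + b * nb_) / (na_ + nb_)
  }
  if (method == "mean") {
    vals <- list(
      mean_height_px = comb2(upper$mean_height_px, lower$mean_height_px),
      mean_width_px = comb2(upper$mean_width_px, lower$mean_width_px),
      mean_tortuosity = comb2(upper$mean_tortuosity, lower$mean_tortuosity),
      density = comb2(upper$density, lower$density),
      vagueness = comb2(upper$vagueness, lower$vagueness)
    )
  } else {
    nu <- upper$n_glands; nl <- lower$n_glands
    vals <- list(
      mean_height_px = pooled_mean(upper$mean_height_px, lower$mean_height_px, nu, nl),
      mean_width_px = pooled_mean(upper$mean_width_px, lower$mean_width_px, nu, nl),
      mean_tortuosity = pooled_mean(upper$mean_tortuosity, lower$mean_tortuosity, nu, nl),
      density = (upper$gland_px + lower$gland_px) / (upper$tarsus_px + lower$tarsus_px),
      vagueness = comb2(upper$vagueness, lower$vagueness)
    )
  }
  structure(c(list(eyelid = "both", n_glands = upper$n_glands + lower$n_glands),
              vals,
              list(gland_px = upper$gland_px + lower$gland_px,
                   tarsus_px = upper$tarsus_px + lower$tarsus_px,
                   glands = NULL)),
            class = "eyelid_metrics")
}

#' @export
print.eyelid_metrics <- function(x, ...) {
  cat(sprintf("Eyelid metrics (%s): %d gland(s)\n", x$eyelid, x$n_glands))
  cat(sprintf("  mean height  %8.2f px\n", x$mean_height_px))
  cat(sprintf("  mean width   %8.2f px\n", x$mean_width_px))
  cat(sprintf("  mean tortuosity %5.3f\n", x$mean_tortuosity))
  cat(sprintf("  density      %8.4f\n", x$density))
  if (!is.na(x$vagueness)) cat(sprintf("  vagueness    %8.2f\n", x$vagueness))
  invisible(x)
}
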