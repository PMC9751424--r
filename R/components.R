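# Connected-component labeling and label canonicalization for gland masks.
#
# Glands are thin, often tilted stripes; 8-connectivity (diagonal neighbours
# join) is used everywhere so that a tilted single-pixel-wide gland remains
# one object. This choice is fixed, not configurable.

#' Label connected components of a binary mask
#'
#' Labels every 8-connected foreground component of a binary mask with a
#' positive integer. Labels are assigned in deterministic raster-scan order
#' of each component's topmost-leftmost pixel (smallest row, then smallest
#' column within that row), so repeated runs and platforms agree.
#'
#' @param mask Logical (or 0/1 numeric) matrix; `TRUE`/nonzero is foreground.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   labeled `1..K`.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[4, 4] <- TRUE
#' table(label_components(m))
#' @export
label_components <- function(mask) {
  stopifnot_matrix(mask, "mask")
  mask <- mask != 0
  n <- nrow(mask); m <- ncol(mask)
  lab <- integer(n * m)
  fg <- which(mask)
  if (length(fg) == 0L) {
    out <- matrix(0L, n, m)
    return(out)
  }
  visited <- logical(n * m)
  comp <- 0L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (seed in fg) {
    if (visited[seed]) next
    comp <- comp + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- comp
    while (length(frontier)) {
      r <- (frontier - 1L) %% n + 1L
      cc <- (frontier - 1L) %/% n + 1L
      nr <- rep(r, times = 8L) + rep(dr, each = length(frontier))
      nc <- rep(cc, times = 8L) + rep(dc, each = length(frontier))
      ok <- nr >= 1L & nr <= n & nc >= 1L & nc <= m
      nidx <- (nc[ok] - 1L) * n + nr[ok]
      nidx <- unique(nidx[mask[nidx] & !visited[nidx]])
      if (length(nidx)) {
        visited[nidx] <- TRUE
        lab[nidx] <- comp
      }
      frontier <- nidx
    }
  }
  lab <- matrix(lab, n, m)
  canonicalize_labels(lab, check_connected = FALSE)
}

#' Canonicalize a gland label map
#'
#' Relabels an integer label map so that label ids form the contiguous set
#' `1..K`, ordered by raster-scan position of each component's
#' topmost-leftmost pixel. Pixel sets are preserved. Optionally verifies that
#' every label is a single 8-connected component.
#'
#' @param labels Integer matrix, 0 = background, positive = gland ids
#'   (not necessarily contiguous).
#' @param check_connected Verify each label forms one 8-connected component
#'   (error otherwise). Default `TRUE`.
#' @return Integer matrix with labels `1..K` in canonical order.
#' @export
canonicalize_labels <- function(labels, check_connected = TRUE) {
  stopifnot_matrix(labels, "labels")
  if (any(labels < 0)) mgm_stop("label map contains negative values")
  if (any(labels != round(labels))) mgm_stop("label map must be integer-valued")
  n <- nrow(labels)
  idx <- which(labels > 0)
  out <- matrix(0L, n, ncol(labels))
  if (length(idx) == 0L) return(out)
  labs <- as.integer(labels[idx])
  rows <- (idx - 1L) %% n + 1L
  cols <- (idx - 1L) %/% n + 1L
  ids <- sort(unique(labs))
  key_row <- integer(length(ids)); key_col <- integer(length(ids))
  for (j in seq_along(ids)) {
    sel <- labs == ids[j]
    r <- rows[sel]; cc <- cols[sel]
    kr <- min(r)
    key_row[j] <- kr
    key_col[j] <- min(cc[r == kr])
    if (check_connected && !is_single_component(r, cc))
      mgm_stop(sprintf("label %d is not a single 8-connected component", ids[j]))
  }
  ord <- order(key_row, key_col)
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  out[idx] <- remap[labs]
  out
}

# TRUE when the pixel set (r, c) forms one 8-connected component.
is_single_component <- function(r, c) {
  np <- length(r)
  if (np <= 1L) return(TRUE)
  r0 <- r - min(r) + 1L; c0 <- c - min(c) + 1L
  sub <- matrix(FALSE, max(r0), max(c0))
  sub[cbind(r0, c0)] <- TRUE
  lab <- label_components(sub)
  max(lab) == 1L
}
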