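# Shared fixtures and independent oracles used across the suite.

# Pixel coordinates of a filled h x w rectangle.
rect_coords <- function(h, w, top = 1L, left = 1L) {
  cbind(row = rep(top:(top + h - 1L), each = w),
        col = rep(left:(left + w - 1L), times = h))
}

# Brute-force 4-neighbor boundary count: explicit loop over every pixel,
# independent of the package's vectorized implementation.
brute_perimeter <- function(coords) {
  keys <- paste(coords[, 1], coords[, 2])
  count <- 0L
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, 1]; c <- coords[i, 2]
    nb <- c(paste(r - 1, c), paste(r + 1, c), paste(r, c - 1), paste(r, c + 1))
    if (any(!nb %in% keys)) count <- count + 1L
  }
  count
}

# Exhaustive-angle enclosing-box oracle: minimum bounding-box area over
# rotations 0..179.5 degrees in 0.5-degree steps.
minrect_oracle_area <- function(coords, step_deg = 0.5) {
  x <- coords[, 2]; y <- coords[, 1]
  best <- Inf
  for (th in seq(0, 180 - step_deg, by = step_deg) * pi / 180) {
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    a <- (max(xr) - min(xr)) * (max(yr) - min(yr))
    if (a < best) best <- a
  }
  best
}

# Random 8-connected blob grown by repeatedly annexing a 4-neighbor of a
# randomly chosen current pixel (connected by construction).
random_blob <- function(n_px, seed) {
  set.seed(seed)
  pts <- matrix(c(50L, 50L), ncol = 2)
  keys <- paste(50, 50)
  while (nrow(pts) < n_px) {
    i <- sample.int(nrow(pts), 1)
    d <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), ncol = 2, byrow = TRUE)[sample.int(4, 1), ]
    cand <- pts[i, ] + d
    k <- paste(cand[1], cand[2])
    if (!k %in% keys && all(cand >= 2) && all(cand <= 99)) {
      pts <- rbind(pts, cand)
      keys <- c(keys, k)
    }
  }
  unname(pts)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (requires no ties among |d| and no zeros).
enum_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Rasterize a rotated bar (length len, half-width hw) by membership test in
# the rotated rectangle; used to probe the minimum external rectangle.
rotated_bar_coords <- function(len, hw, angle_deg, center = c(100, 100)) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))   # long axis (row, col) direction
  v <- c(-sin(th), cos(th))
  rr <- (center[1] - len):(center[1] + len)
  cc <- (center[2] - len):(center[2] + len)
  g <- expand.grid(row = rr, col = cc)
  dy <- g$row - center[1]; dx <- g$col - center[2]
  pu <- dy * u[1] + dx * u[2]
  pv <- dy * v[1] + dx * v[2]
  keep <- abs(pu) <= len / 2 & abs(pv) <= hw
  as.matrix(g[keep, ])
}

# Coordinates -> minimal label matrix with a 1 px empty border.
coords_to_mask <- function(coords) {
  r <- coords[, 1] - min(coords[, 1]) + 2L
  c <- coords[, 2] - min(coords[, 2]) + 2L
  m <- matrix(0L, max(r) + 1L, max(c) + 1L)
  m[cbind(r, c)] <- 1L
  m
}
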