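test_that("filled rectangles obey the closed-form index formulas", {
  for (h in c(20, 50, 100)) {
    for (w in c(2, 5, 10)) {
      co <- rect_coords(h, w, top = 3, left = 4)
      expect_equal(gland_height(co), h)
      expect_equal(gland_width(co), w)
      expect_identical(gland_perimeter(co), as.integer(2 * h + 2 * w - 4))
      mr <- min_external_rect(co)
      expect_equal(mr$height_px, h - 1)
      expect_equal(gland_tortuosity(co),
                   (2 * h + 2 * w - 4) / (2 * (h - 1)) - 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate glands use the documented conventions", {
  px <- matrix(c(5L, 5L), ncol = 2)
  expect_identical(gland_height(px), 1L)
  expect_equal(gland_width(px), 1)
  expect_identical(gland_perimeter(px), 1L)
  expect_equal(min_external_rect(px)$height_px, 1)
  expect_equal(gland_tortuosity(px), 1 / 2 - 1)

  # a vertical line of pixels: collinear hull, segment length as height
  line <- cbind(10:109, 7L)
  expect_identical(gland_height(line), 100L)
  expect_equal(min_external_rect(line)$height_px, 99)

  # exclusive height convention for sensitivity checks
  expect_identical(gland_height(line, inclusive = FALSE), 99L)
  expect_error(gland_height(matrix(numeric(0), ncol = 2)), "non-empty")
})

test_that("width is forced arithmetic: area over row extent", {
  # L-shape: 50-row column plus an arm, area 75 over 50 rows -> 1.5
  col50 <- cbind(1:50, 10L)
  arm <- cbind(50L, 11:35)
  L <- rbind(col50, arm)
  expect_equal(nrow(L), 75)
  expect_equal(gland_width(L), 1.5)
})

test_that("3x3 square perimeter counts all but the center", {
  expect_identical(gland_perimeter(rect_coords(3, 3)), 8L)
})

test_that("perimeter matches brute-force 4-neighbor enumeration on random blobs", {
  for (s in 1:60) {
    blob <- random_blob(n_px = sample(c(8, 20, 60), 1), seed = s)
    expect_identical(gland_perimeter(blob), brute_perimeter(blob))
    # identity: per-gland width x height = area
    expect_equal(gland_width(blob) * gland_height(blob), nrow(blob))
  }
})

test_that("label-map perimeter agrees with the coordinate implementation", {
  lab <- matrix(0L, 100, 100)
  for (s in 1:5) {
    blob <- random_blob(40, seed = 100 + s)
    sub <- coords_to_mask(blob)
    g <- gland_metrics(sub)
    expect_identical(g$perimeter_px, brute_perimeter(blob))
    expect_identical(g$area_px, nrow(blob))
  }
})

test_that("minimum external rectangle is minimal and stable under rotation", {
  # axis-aligned bar
  bar <- rect_coords(50, 2)
  expect_equal(min_external_rect(bar)$height_px, 49)
  # the same bar rotated 30 degrees: height within 2 px of the unrotated one
  rot <- rotated_bar_coords(len = 49, hw = 0.9, angle_deg = 30)
  expect_lt(abs(min_external_rect(rot)$height_px - 49), 2)

  # min-area property: never exceeds the axis-aligned bounding box, and
  # matches the exhaustive-angle oracle
  for (s in 1:10) {
    blob <- random_blob(50, seed = 200 + s)
    mr <- min_external_rect(blob)
    aabb <- (diff(range(blob[, 1]))) * (diff(range(blob[, 2])))
    expect_lte(mr$area, aabb + 1e-9)
    oracle <- minrect_oracle_area(blob)
    expect_lte(mr$area, oracle + 1e-9)
    expect_gte(mr$area, oracle * 0.99 - 1e-9)
  }

  # equal-area tie (square): smallest absolute angle wins, deterministically
  sq <- rect_coords(5, 5)
  expect_equal(min_external_rect(sq)$angle_deg, 0)
})

test_that("indices are invariant under horizontal mirroring", {
  for (s in 1:10) {
    blob <- random_blob(45, seed = 300 + s)
    mir <- cbind(blob[, 1], max(blob[, 2]) + min(blob[, 2]) - blob[, 2])
    expect_identical(gland_height(mir), gland_height(blob))
    expect_equal(gland_width(mir), gland_width(blob))
    expect_identical(gland_perimeter(mir), gland_perimeter(blob))
    expect_equal(min_external_rect(mir)$height_px,
                 min_external_rect(blob)$height_px, tolerance = 1e-9)
    expect_equal(gland_tortuosity(mir), gland_tortuosity(blob), tolerance = 1e-9)
  }
})

test_that("tortuosity responds monotonically to sinusoidal distortion", {
  # Boundary-pixel perimeters only grow once the lateral slope approaches
  # 1 px/row, so the response is probed at amplitudes above that threshold.
  straight <- render_gland(gland_spec(50, 2, amp_px = 0, center_col = 30, top_row = 3),
                           c(60, 60))
  t_prev <- gland_tortuosity(straight)
  for (amp in c(5, 6, 8)) {
    wavy <- render_gland(gland_spec(50, 2, amp_px = amp, n_periods = 2,
                                    center_col = 30, top_row = 3), c(60, 60))
    t_amp <- gland_tortuosity(wavy)
    expect_gt(t_amp, t_prev)
    t_prev <- t_amp
  }
})

test_that("density is a pixel ratio with the expected invariances", {
  lab <- matrix(0L, 80, 80)
  lab[11:60, 11:20] <- 1L  # 500 px
  # tarsus of exactly 5000 px containing the gland -> density 0.10
  tarA <- matrix(FALSE, 80, 80)
  tarA[11:60, 1:80] <- TRUE   # 4000
  tarA[61:72, 1:80] <- TRUE   # +960
  tarA[73, 1:40] <- TRUE      # +40 = 5000
  expect_equal(sum(tarA), 5000)
  expect_equal(eyelid_density(lab, tarA), 0.10)

  # empty label map -> 0; glands tiling the tarsus -> 1
  expect_equal(eyelid_density(matrix(0L, 80, 80), tarA), 0)
  tiled <- matrix(0L, 80, 80); tiled[tarA] <- 1L
  tiled2 <- canonicalize_labels(tiled, check_connected = FALSE)
  expect_equal(eyelid_density(tiled2, tarA), 1)

  # relabeling invariance
  lab_swapped <- matrix(0L, 80, 80)
  lab_swapped[11:35, 11:20] <- 2L
  lab_swapped[37:60, 11:20] <- 1L
  expect_equal(eyelid_density(canonicalize_labels(lab_swapped), tarA),
               eyelid_density(lab_swapped, tarA))

  # joint translation invariance (masks kept clear of the border)
  labT <- matrix(0L, 80, 80); labT[11:40, 11:20] <- 1L
  tarT <- matrix(FALSE, 80, 80); tarT[5:70, 5:70] <- TRUE
  sh <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(eyelid_density(sh(labT, 3, 2), sh(tarT * 1L, 3, 2) > 0),
               eyelid_density(labT, tarT))
  expect_error(eyelid_density(lab, matrix(FALSE, 80, 80)), "empty")
})

test_that("eyelid summaries aggregate per-gland metrics", {
  lab <- matrix(0L, 70, 40)
  lab[6:55, 5:6] <- 1L    # 50 x 2
  lab[11:40, 20:21] <- 2L # 30 x 2
  tar <- matrix(TRUE, 70, 40)
  s <- summarize_eyelid(lab, tar, "upper")
  expect_identical(s$n_glands, 2L)
  expect_equal(s$mean_height_px, 40)
  expect_equal(s$mean_width_px, 2)
  expect_equal(s$density, (100 + 60) / (70 * 40))

  # zero glands: density 0, means missing
  s0 <- summarize_eyelid(matrix(0L, 10, 10), matrix(TRUE, 10, 10), "lower")
  expect_identical(s0$n_glands, 0L)
  expect_equal(s0$density, 0)
  expect_true(is.na(s0$mean_height_px))
})

test_that("both-eyelid combination averages the per-eyelid values", {
  mk <- function(density, height = 100, vagueness = 25, n = 5) {
    structure(list(eyelid = "upper", n_glands = n, mean_height_px = height,
                   mean_width_px = 20, mean_tortuosity = 0.5, density = density,
                   vagueness = vagueness, gland_px = 1000, tarsus_px = 5000,
                   glands = NULL), class = "eyelid_metrics")
  }
  both <- combine_eyelids(mk(0.19), mk(0.16))
  expect_equal(both$density, 0.175)
  expect_equal(both$n_glands, 10)

  # idempotence: identical eyelids combine to themselves
  same <- combine_eyelids(mk(0.2), mk(0.2))
  expect_equal(same$density, 0.2)
  expect_equal(same$mean_height_px, 100)

  # missing value in one eyelid propagates
  u <- mk(0.2); u$mean_height_px <- NA_real_
  expect_true(is.na(combine_eyelids(u, mk(0.2))$mean_height_px))
  expect_false(is.na(combine_eyelids(u, mk(0.2))$density))

  # pooled recomputation weights by gland count / pixel sums
  a <- mk(0.2, height = 100, n = 10); b <- mk(0.2, height = 50, n = 5)
  pooled <- combine_eyelids(a, b, method = "pooled")
  expect_equal(pooled$mean_height_px, (100 * 10 + 50 * 5) / 15)
  expect_equal(pooled$density, 2000 / 10000)
})
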