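# Synthetic meibography generator.
#
# A gland is modeled as a sinusoid-displaced vertical stripe: the simplest
# shape family spanning straight, twisted and (via the fragmentation flag)
# fragmented gland morphologies. The tarsus is a rectangle inset from the
# image border; real tarsal curvature is presentational and irrelevant to
# the index definitions. Images are a two-level intensity field (background
# vs gland) plus clipped additive Gaussian noise. All masks are exact by
# construction, so every rendered eyelid carries exact ground truth for
# density and per-gland vertical extents.

#' Specify a synthetic gland
#'
#' The rendered pixel set is
#' \deqn{\{(r, c): |c - (c_0 + a \sin(2\pi p (r - r_0)/L))| \le w_{1/2},\;
#'        r_0 \le r < r_0 + L\}}
#' so the vertical extent equals `length_px` exactly by construction, and
#' `amp_px = 0` renders a straight vertical stripe.
#'
#' @param length_px Positive integer vertical extent.
#' @param half_width_px Positive real half-width of the stripe.
#' @param amp_px Non-negative sinusoidal lateral amplitude.
#' @param n_periods Non-negative number of sine periods along the gland.
#' @param center_col Column of the stripe's central axis.
#' @param top_row Topmost row of the gland.
#' @return List of class `gland_spec`.
#' @export
gland_spec <- function(length_px, half_width_px, amp_px = 0, n_periods = 0,
                       center_col = 1, top_row = 1) {
  if (length_px < 1) mgm_stop("length_px must be a positive integer")
  if (half_width_px <= 0) mgm_stop("half_width_px must be positive")
  if (amp_px < 0 || n_periods < 0) mgm_stop("amp_px and n_periods must be non-negative")
  structure(list(length_px = as.integer(round(length_px)),
                 half_width_px = half_width_px, amp_px = amp_px,
                 n_periods = n_periods, center_col = center_col,
                 top_row = as.integer(round(top_row))),
            class = "gland_spec")
}

#' Render a gland specification to a pixel set
#'
#' Rendering is deterministic (seed-free). The result is validated to fit
#' inside the canvas, to occupy every row of its vertical extent, and to be
#' 8-connected; parameter combinations violating these are rejected.
#'
#' @param spec A [gland_spec()].
#' @param canvas_shape `c(rows, cols)` of the target canvas.
#' @return Two-column (row, col) integer matrix of gland pixels.
#' @export
render_gland <- function(spec, canvas_shape) {
  r <- spec$top_row + seq_len(spec$length_px) - 1L
  phase <- if (spec$length_px > 1) (r - spec$top_row) / spec$length_px else 0
  ctr <- spec$center_col + spec$amp_px * sin(2 * pi * spec$n_periods * phase)
  lo <- ceiling(ctr - spec$half_width_px)
  hi <- floor(ctr + spec$half_width_px)
  if (any(hi < lo))
    mgm_stop("half_width_px too small: gland has empty rows")
  if (min(r) < 1 || max(r) > canvas_shape[1] || min(lo) < 1 || max(hi) > canvas_shape[2])
    mgm_stop("gland does not fit inside the canvas")
  # 8-connectivity between consecutive rows: column ranges must touch
  nr <- length(r)
  if (nr > 1) {
    gap <- lo[-1] > hi[-nr] + 1L | hi[-1] < lo[-nr] - 1L
    if (any(gap)) mgm_stop("gland is disconnected: lateral slope too steep for its width")
  }
  counts <- hi - lo + 1L
  cbind(row = rep(r, counts),
        col = rep(lo, counts) + sequence(counts) - 1L)
}

#' Render a synthetic eyelid
#'
#' Builds the grayscale image, gland label map, tarsus mask and ground-truth
#' record for a list of gland specifications. The image is `g_bg` on the
#' tarsus, `g_fg` on glands, 0 outside the tarsus, plus (inside the tarsus)
#' additive Gaussian noise of standard deviation `noise_sd` clipped to
#' \[0, 255\]. Glands are labeled `1..K` in specification order. Overlapping
#' glands or glands outside the tarsus are errors.
#'
#' @param specs List of [gland_spec()] objects.
#' @param image_shape `c(rows, cols)`.
#' @param tarsus_margin_px Inset of the rectangular tarsus from the image
#'   border, in pixels.
#' @param g_fg,g_bg Gland and background intensities (0-255).
#' @param noise_sd Noise standard deviation; 0 disables noise.
#' @param noise_seed Optional seed for the noise draw; when given, the
#'   caller's RNG state is left untouched.
#' @return List with `image`, `labels`, `tarsus` and `truth` (per-gland
#'   `length_px`/`area_px`/`extent_px`, exact `density`, intensities used).
#' @export
render_eyelid <- function(specs, image_shape, tarsus_margin_px = 14,
                          g_fg = 148, g_bg = 120, noise_sd = 0,
                          noise_seed = NULL) {
  nrows <- image_shape[1]; ncols <- image_shape[2]
  m <- tarsus_margin_px
  if (nrows - 2 * m < 3 || ncols - 2 * m < 3)
    mgm_stop("tarsus margin leaves no interior region")
  tarsus <- matrix(FALSE, nrows, ncols)
  tarsus[(m + 1):(nrows - m), (m + 1):(ncols - m)] <- TRUE
  labels <- matrix(0L, nrows, ncols)
  areas <- integer(length(specs)); extents <- integer(length(specs))
  for (k in seq_along(specs)) {
    coords <- render_gland(specs[[k]], c(nrows, ncols))
    idx <- (coords[, 2] - 1L) * nrows + coords[, 1]
    if (any(!tarsus[idx])) mgm_stop(sprintf("gland %d extends outside the tarsus", k))
    if (any(labels[idx] != 0L))
      mgm_stop(sprintf("gland %d overlaps a previously placed gland", k))
    labels[idx] <- k
    areas[k] <- length(idx)
    extents[k] <- max(coords[, 1]) - min(coords[, 1]) + 1L
  }
  image <- matrix(0, nrows, ncols)
  image[tarsus] <- g_bg
  image[labels > 0] <- g_fg
  if (noise_sd > 0) {
    add_noise <- function() {
      nt <- sum(tarsus)
      image[tarsus] <<- pmin(pmax(image[tarsus] + stats::rnorm(nt, 0, noise_sd), 0), 255)
    }
    if (is.null(noise_seed)) add_noise() else with_seed(noise_seed, add_noise())
  }
  truth <- list(
    n_glands = length(specs),
    specs = specs,
    area_px = areas,
    extent_px = extents,
    density = sum(areas) / sum(tarsus),
    g_fg = g_fg, g_bg = g_bg, noise_sd = noise_sd
  )
  list(image = image, labels = labels, tarsus = tarsus, truth = truth)
}

#' Split a gland specification into vertical fragments
#'
#' Emulates the fragmented gland morphology seen after eyelid inflammation:
#' the stripe is cut into `n_fragments` pieces separated by `gap_px` empty
#' rows. Each fragment is an independent [gland_spec()] (and hence a
#' separately labeled gland when rendered).
#'
#' @param spec A [gland_spec()].
#' @param n_fragments Number of pieces (>= 2).
#' @param gap_px Vertical gap between consecutive pieces, in pixels.
#' @return List of `gland_spec` objects.
#' @export
fragment_spec <- function(spec, n_fragments = 2, gap_px = 3) {
  if (n_fragments < 2) mgm_stop("n_fragments must be at least 2")
  total_gap <- (n_fragments - 1) * gap_px
  if (spec$length_px <= total_gap + n_fragments)
    mgm_stop("gland too short to fragment with this gap")
  piece <- floor((spec$length_px - total_gap) / n_fragments)
  lens <- rep(piece, n_fragments)
  lens[n_fragments] <- spec$length_px - total_gap - piece * (n_fragments - 1)
  tops <- spec$top_row + cumsum(c(0, (lens + gap_px)[-n_fragments]))
  lapply(seq_len(n_fragments), function(k)
    gland_spec(lens[k], spec$half_width_px, spec$amp_px,
               spec$n_periods * lens[k] / spec$length_px,
               spec$center_col, tops[k]))
}

#' Cohort generator configuration
#'
#' Defines the paired research/control study conditions emulated by the
#' generator: each subject contributes upper and lower eyelids for both a
#' research eye and a contralateral control eye. Control-eye gland
#' parameters are drawn per subject and eyelid; each eye then receives its
#' own independent lognormal jitter, and the research eye's parameters are
#' additionally multiplied by the `effects` factors, so that with all
#' effects equal to 1 the two eyes are draws from identical distributions.
#'
#' Geometry defaults are expressed at `scale = 1` as a full-resolution
#' meibography crop (image 380 x 480, upper-lid glands about 150 px long
#' and 21 px wide); `scale` shrinks all linear dimensions proportionally
#' while keeping density, tortuosity and vagueness in the same ranges, which
#' is how large replicate simulations are kept tractable.
#'
#' @param n_subjects Number of subjects (paired eyes). Default 26.
#' @param scale Linear geometry scale factor. Default 1.
#' @param image_shape,tarsus_margin_px Canvas geometry (derived from
#'   `scale` when omitted).
#' @param glands_per_lid Integer vector of admissible gland counts per
#'   eyelid; the per-subject count is drawn uniformly from it.
#' @param upper_length,lower_length `c(mean, sd)` of gland vertical extents
#'   per lid type, in px at `scale = 1`.
#' @param upper_half_width,lower_half_width `c(mean, sd)` of gland
#'   half-widths at `scale = 1`.
#' @param amp `c(mean, sd)` of the sinusoidal amplitude at `scale = 1`.
#' @param wiggle_freq `c(min, max)` spatial frequency of the sinusoid in
#'   cycles per pixel at `scale = 1`.
#' @param g_fg,g_bg Gland/background intensities. Defaults 148/120 give a
#'   vagueness near 28, typical of clear clinical images.
#' @param contrast_sd Per-eye additive jitter (sd) on the gland-background
#'   contrast.
#' @param noise_sd Pixel noise sd. Default 10.
#' @param jitter_sd Named list of per-eye lognormal jitter sds on `length`,
#'   `width` and `amp`.
#' @param effects Named list of multiplicative research-group effects on
#'   `length`, `width`, `amplitude`, `count` and `contrast`; all default 1
#'   (null).
#' @param interval_probs Probabilities of the four follow-up interval bins
#'   (0-3, 3-6, 6-12, >12 months).
#' @param tbut_research,tbut_control,tmh_research,tmh_control `c(mean, sd)`
#'   of the clinical covariates per group.
#' @param seed Root seed; the entire cohort is a deterministic function of
#'   the configuration.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 26, scale = 1,
                          image_shape = NULL, tarsus_margin_px = NULL,
                          glands_per_lid = 8:11,
                          upper_length = c(150, 30), lower_length = c(90, 18),
                          upper_half_width = c(10.5, 1.2),
                          lower_half_width = c(13, 1.2),
                          amp = c(8, 2), wiggle_freq = c(0.030, 0.042),
                          g_fg = 148, g_bg = 120, contrast_sd = 6,
                          noise_sd = 10,
                          jitter_sd = list(length = 0.06, width = 0.05, amp = 0.12),
                          effects = list(length = 1, width = 1, amplitude = 1,
                                         count = 1, contrast = 1),
                          interval_probs = c(0.25, 0.25, 0.25, 0.25),
                          tbut_research = c(5.76, 2.86), tbut_control = c(7.68, 4.92),
                          tmh_research = c(0.22, 0.06), tmh_control = c(0.19, 0.05),
                          seed = 1L) {
  if (n_subjects < 1) mgm_stop("n_subjects must be at least 1")
  if (scale <= 0) mgm_stop("scale must be positive")
  eff_def <- list(length = 1, width = 1, amplitude = 1, count = 1, contrast = 1)
  eff_def[names(effects)] <- effects
  if (any(unlist(eff_def) <= 0)) mgm_stop("effect factors must be positive")
  jit_def <- list(length = 0.06, width = 0.05, amp = 0.12)
  jit_def[names(jitter_sd)] <- jitter_sd
  cfg <- list(
    n_subjects = as.integer(n_subjects), scale = scale,
    image_shape = if (is.null(image_shape)) pmax(round(c(380, 480) * scale), 24)
                  else as.integer(image_shape),
    tarsus_margin_px = if (is.null(tarsus_margin_px)) max(round(14 * scale), 2)
                       else as.integer(tarsus_margin_px),
    glands_per_lid = as.integer(glands_per_lid),
    upper_length = upper_length * scale, lower_length = lower_length * scale,
    upper_half_width = upper_half_width * scale,
    lower_half_width = lower_half_width * scale,
    amp = amp * scale, wiggle_freq = wiggle_freq / scale,
    g_fg = g_fg, g_bg = g_bg, contrast_sd = contrast_sd,
    noise_sd = noise_sd, jitter_sd = jit_def, effects = eff_def,
    interval_probs = interval_probs / sum(interval_probs),
    tbut = list(research = tbut_research, control = tbut_control),
    tmh = list(research = tmh_research, control = tmh_control),
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#' @param path YAML file whose keys are [cohort_config()] arguments.
#' @return `cohort_config` object.
#' @export
cohort_config_from_yaml <- function(path) {
  if (!file.exists(path)) mgm_io_stop(sprintf("config file not found: %s", path))
  args <- yaml::read_yaml(path)
  if (is.null(args)) args <- list()
  for (nm in c("upper_length", "lower_length", "upper_half_width",
               "lower_half_width", "amp", "wiggle_freq", "image_shape",
               "interval_probs", "tbut_research", "tbut_control",
               "tmh_research", "tmh_control", "glands_per_lid"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(cohort_config, args)
}

rtrunc_norm <- function(n, mean, sd, lo, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Sample base gland parameters for one subject eyelid (shared by both eyes).
sample_lid_base <- function(cfg, lid) {
  len_par <- if (lid == "upper") cfg$upper_length else cfg$lower_length
  hw_par <- if (lid == "upper") cfg$upper_half_width else cfg$lower_half_width
  rows <- cfg$image_shape[1] - 2 * cfg$tarsus_margin_px
  count <- cfg$glands_per_lid[sample.int(length(cfg$glands_per_lid), 1)]
  list(
    count = count,
    length = rtrunc_norm(count, len_par[1], len_par[2],
                         lo = max(4, 0.4 * len_par[1]), hi = rows - 2),
    half_width = rtrunc_norm(count, hw_par[1], hw_par[2], lo = max(1, 0.5 * hw_par[1])),
    amp = rtrunc_norm(count, cfg$amp[1], cfg$amp[2], lo = 0),
    freq = stats::runif(count, cfg$wiggle_freq[1], cfg$wiggle_freq[2]),
    top_frac = stats::runif(count)
  )
}

# Realize one eye's gland specs from the shared base: apply the eye's
# jitter (and, for the research eye, the group effects), then place glands
# left to right with at least a 2 px gap between lateral footprints. If the
# tarsus cannot hold all requested glands the trailing ones are dropped.
realize_eye <- function(cfg, base, role) {
  eff <- if (role == "research") cfg$effects
         else list(length = 1, width = 1, amplitude = 1, count = 1, contrast = 1)
  jit <- cfg$jitter_sd
  mul_len <- exp(stats::rnorm(1, 0, jit$length)) * eff$length
  mul_wid <- exp(stats::rnorm(1, 0, jit$width)) * eff$width
  mul_amp <- exp(stats::rnorm(1, 0, jit$amp)) * eff$amplitude
  count <- max(1L, as.integer(round(base$count * eff$count)))
  count <- min(count, base$count)
  rows <- cfg$image_shape[1]; m <- cfg$tarsus_margin_px
  tar_top <- m + 1L; tar_bot <- rows - m
  tar_left <- m + 1L; tar_right <- cfg$image_shape[2] - m

  len <- pmax(4, pmin(round(base$length[seq_len(count)] * mul_len), tar_bot - tar_top - 1))
  hw <- pmax(1, base$half_width[seq_len(count)] * mul_wid)
  amp <- pmax(0, base$amp[seq_len(count)] * mul_amp)
  n_per <- base$freq[seq_len(count)] * len
  # cap the lateral slope so the stripe stays 8-connected
  slope <- amp * 2 * pi * base$freq[seq_len(count)]
  cap <- slope > 2 * hw
  amp[cap] <- 2 * hw[cap] / (2 * pi * base$freq[seq_len(count)][cap])

  foot <- hw + amp  # max lateral half-extent
  specs <- list()
  pos <- tar_left
  gapjit <- stats::runif(count, 0, 2)
  for (k in seq_len(count)) {
    center <- pos + foot[k] + gapjit[k]
    if (center + foot[k] > tar_right) break
    top <- tar_top + floor(base$top_frac[k] * max(1, tar_bot - tar_top + 1 - len[k]))
    specs[[length(specs) + 1L]] <- gland_spec(
      length_px = len[k], half_width_px = hw[k], amp_px = amp[k],
      n_periods = n_per[k], center_col = center, top_row = top)
    pos <- center + foot[k] + 2
  }
  if (!length(specs)) mgm_stop("infeasible placement: no gland fits the tarsus")
  contrast <- (cfg$g_fg - cfg$g_bg) *
    (if (role == "research") cfg$effects$contrast else 1) +
    stats::rnorm(1, 0, cfg$contrast_sd)
  list(specs = specs, g_fg = cfg$g_bg + max(2, contrast))
}

# All four eyelids of one subject plus metadata; deterministic given cfg
# and the subject index.
render_subject <- function(cfg, i) {
  out <- list()
  for (lid in c("upper", "lower")) {
    with_seed(derive_seed(cfg$seed, 11, i, if (lid == "upper") 1 else 2), {
      base <- sample_lid_base(cfg, lid)
      eyes <- list(control = realize_eye(cfg, base, "control"),
                   research = realize_eye(cfg, base, "research"))
    })
    for (role in c("research", "control")) {
      e <- eyes[[role]]
      out[[paste(role, lid, sep = "_")]] <- render_eyelid(
        e$specs, cfg$image_shape, cfg$tarsus_margin_px,
        g_fg = e$g_fg, g_bg = cfg$g_bg, noise_sd = cfg$noise_sd,
        noise_seed = derive_seed(cfg$seed, 13, i,
                                 if (lid == "upper") 1 else 2,
                                 if (role == "research") 1 else 2))
    }
  }
  out$meta <- with_seed(derive_seed(cfg$seed, 17, i), {
    bin <- sample.int(4, 1, prob = cfg$interval_probs)
    lo <- c(0, 3, 6, 12)[bin]; hi <- c(3, 6, 12, 24)[bin]
    list(subject_id = sprintf("S%03d", i),
         interval_months = round(stats::runif(1, lo, hi), 2),
         tbut_s = list(research = rtrunc_norm(1, cfg$tbut$research[1], cfg$tbut$research[2], 0.5),
                       control = rtrunc_norm(1, cfg$tbut$control[1], cfg$tbut$control[2], 0.5)),
         tmh_mm = list(research = rtrunc_norm(1, cfg$tmh$research[1], cfg$tmh$research[2], 0.02),
                       control = rtrunc_norm(1, cfg$tmh$control[1], cfg$tmh$control[2], 0.02)))
  })
  out
}

#' Simulate a paired cohort and analyze it in memory
#'
#' Generates every subject's four eyelids (research/control x upper/lower),
#' runs the full morphometry and vagueness pipeline on the rendered masks
#' and images, and returns the aggregate metrics table without touching the
#' filesystem. This is the fast path used for replicate simulations; the
#' metrics are identical to analyzing a cohort written by
#' [generate_cohort()].
#'
#' @param config A [cohort_config()].
#' @return List with `metrics` (aggregate rows in the standard metrics
#'   schema) and `truth` (per subject/role/lid ground-truth summaries).
#' @export
simulate_study <- function(config) {
  n_units <- config$n_subjects * 4L
  out <- list(subject_id = character(n_units), eye_role = character(n_units),
              eyelid = character(n_units), gland_id = rep("AGGREGATE", n_units),
              height_px = numeric(n_units), width_px = numeric(n_units),
              tortuosity = numeric(n_units), density = numeric(n_units),
              vagueness = numeric(n_units), interval_months = numeric(n_units),
              tbut_s = numeric(n_units), tmh_mm = numeric(n_units))
  truth <- list()
  j <- 0L
  for (i in seq_len(config$n_subjects)) {
    subj <- render_subject(config, i)
    meta <- subj$meta
    for (role in c("research", "control")) {
      for (lid in c("upper", "lower")) {
        key <- paste(role, lid, sep = "_")
        ey <- subj[[key]]
        s <- summarize_eyelid(ey$labels, ey$tarsus, lid, image = ey$image)
        j <- j + 1L
        out$subject_id[j] <- meta$subject_id
        out$eye_role[j] <- role
        out$eyelid[j] <- lid
        out$height_px[j] <- s$mean_height_px
        out$width_px[j] <- s$mean_width_px
        out$tortuosity[j] <- s$mean_tortuosity
        out$density[j] <- s$density
        out$vagueness[j] <- s$vagueness
        out$interval_months[j] <- meta$interval_months
        out$tbut_s[j] <- meta$tbut_s[[role]]
        out$tmh_mm[j] <- meta$tmh_mm[[role]]
        truth[[paste(meta$subject_id, key, sep = ".")]] <- c(
          ey$truth[c("n_glands", "density")],
          list(mean_extent_px = mean(ey$truth$extent_px)))
      }
    }
  }
  list(metrics = as.data.frame(out, stringsAsFactors = FALSE), truth = truth)
}

#' Generate a synthetic cohort directory
#'
#' Writes, for every subject, the four eyelid images with their gland label
#' maps and tarsus masks as PNG files, plus `metadata.csv` and
#' `ground_truth.json`. Re-running with the same configuration (including
#' the seed) reproduces byte-identical outputs.
#'
#' Layout: `subjects/<id>/<eye_role>_<eyelid>_{image,labels,tarsus}.png`.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
generate_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_rows <- list(); gt <- list()
  for (i in seq_len(config$n_subjects)) {
    subj <- render_subject(config, i)
    meta <- subj$meta
    sdir <- file.path(dir, "subjects", meta$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (role in c("research", "control")) {
      for (lid in c("upper", "lower")) {
        key <- paste(role, lid, sep = "_")
        ey <- subj[[key]]
        write_gray_image(ey$image, file.path(sdir, paste0(key, "_image.png")))
        write_label_map(ey$labels, file.path(sdir, paste0(key, "_labels.png")))
        write_tarsus_mask(ey$tarsus, file.path(sdir, paste0(key, "_tarsus.png")))
        gt[[meta$subject_id]][[key]] <- list(
          n_glands = ey$truth$n_glands,
          area_px = ey$truth$area_px,
          extent_px = ey$truth$extent_px,
          density = ey$truth$density,
          g_bg = ey$truth$g_bg,
          specs = lapply(ey$truth$specs, unclass))
      }
      meta_rows[[paste(meta$subject_id, role)]] <- data.frame(
        subject_id = meta$subject_id, eye_role = role,
        interval_months = meta$interval_months,
        tbut_s = meta$tbut_s[[role]], tmh_mm = meta$tmh_mm[[role]],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, meta_rows), file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Analyze a cohort directory into a metrics table
#'
#' Reads every eyelid's image and masks from a directory written by
#' [generate_cohort()] (or hand-assembled in the same layout), computes
#' per-gland and aggregate metrics, and joins the subject metadata.
#'
#' @param dir Cohort directory.
#' @param per_gland Include per-gland rows in addition to aggregate rows.
#'   Default `TRUE`.
#' @return Data frame in the standard metrics schema.
#' @export
analyze_cohort <- function(dir, per_gland = TRUE) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) mgm_io_stop(sprintf("no metadata.csv in %s", dir))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  rows <- list()
  for (sid in unique(meta$subject_id)) {
    sdir <- file.path(dir, "subjects", sid)
    for (role in c("research", "control")) {
      mrow <- meta[meta$subject_id == sid & meta$eye_role == role, ][1, ]
      for (lid in c("upper", "lower")) {
        key <- paste(role, lid, sep = "_")
        img_p <- file.path(sdir, paste0(key, "_image.png"))
        if (!file.exists(img_p)) next
        image <- read_gray_image(img_p)
        labels <- read_label_map(file.path(sdir, paste0(key, "_labels.png")),
                                 binary_ok = FALSE)
        tarsus <- read_tarsus_mask(file.path(sdir, paste0(key, "_tarsus.png")))
        s <- summarize_eyelid(labels, tarsus, lid, image = image)
        if (per_gland && s$n_glands > 0) {
          g <- s$glands
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, eye_role = role, eyelid = lid,
            gland_id = as.character(g$gland_id),
            height_px = g$height_px, width_px = g$width_px,
            tortuosity = g$tortuosity, density = NA_real_,
            vagueness = NA_real_,
            interval_months = mrow$interval_months,
            tbut_s = mrow$tbut_s, tmh_mm = mrow$tmh_mm,
            stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, eye_role = role, eyelid = lid,
          gland_id = "AGGREGATE",
          height_px = s$mean_height_px, width_px = s$mean_width_px,
          tortuosity = s$mean_tortuosity, density = s$density,
          vagueness = s$vagueness,
          interval_months = mrow$interval_months,
          tbut_s = mrow$tbut_s, tmh_mm = mrow$tmh_mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) mgm_stop("cohort directory contains no eyelid images")
  do.call(rbind, rows)
}

#' Analyze one eyelid from image and mask files
#'
#' Single-image entry point: reads a grayscale image, a gland label (or
#' binary) mask and a tarsus mask, and returns per-gland plus aggregate
#' metric rows.
#'
#' @param image_path,labels_path,tarsus_path Raster file paths.
#' @param eyelid `"upper"` or `"lower"`.
#' @param subject_id,eye_role Metadata for the output rows.
#' @param binary_ok Passed to [read_label_map()].
#' @return Data frame in the standard metrics schema.
#' @export
analyze_eyelid_files <- function(image_path, labels_path, tarsus_path,
                                 eyelid = "upper", subject_id = "subject",
                                 eye_role = "research", binary_ok = TRUE) {
  image <- read_gray_image(image_path)
  labels <- read_label_map(labels_path, binary_ok = binary_ok,
                           reference_shape = dim(image))
  tarsus <- read_tarsus_mask(tarsus_path)
  s <- summarize_eyelid(labels, tarsus, eyelid, image = image)
  g <- s$glands
  per <- if (nrow(g)) data.frame(
    subject_id = subject_id, eye_role = eye_role, eyelid = eyelid,
    gland_id = as.character(g$gland_id), height_px = g$height_px,
    width_px = g$width_px, tortuosity = g$tortuosity, density = NA_real_,
    vagueness = NA_real_, interval_months = NA_real_, tbut_s = NA_real_,
    tmh_mm = NA_real_, stringsAsFactors = FALSE) else NULL
  agg <- data.frame(
    subject_id = subject_id, eye_role = eye_role, eyelid = eyelid,
    gland_id = "AGGREGATE", height_px = s$mean_height_px,
    width_px = s$mean_width_px, tortuosity = s$mean_tortuosity,
    density = s$density, vagueness = s$vagueness,
    interval_months = NA_real_, tbut_s = NA_real_, tmh_mm = NA_real_,
    stringsAsFactors = FALSE)
  rbind(per, agg)
}
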