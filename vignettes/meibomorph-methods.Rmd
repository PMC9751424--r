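---
title: "Meibomian gland morphometry: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meibomian gland morphometry: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Infrared meibography images the everted eyelid; meibomian glands (MGs)
appear as bright, roughly vertical stripes against the darker tarsal plate.
Gland dropout, shortening and distortion are early markers of meibomian
gland dysfunction, a principal cause of evaporative dry eye, and are also
seen after ocular surface inflammation such as herpes zoster ophthalmicus.
`meibomorph` quantifies these changes from a grayscale image plus two
segmentation masks — an integer gland label map and a binary tarsus
region of interest — which the package deliberately takes as *inputs*: how
the glands and tarsus were segmented (manual tracing, a CNN, anything else)
is outside its scope, and no geometric registration is performed.

All rasters use one convention: matrices are rows × columns, row 1 is the
top of the image, "vertical" runs along rows, coordinates are 0-free
R-style `(row, col)` pairs, and masks are co-registered with the image.

## Per-gland indices

For a gland with pixel set $G$:

* **Height** $h = r_{\max} - r_{\min} + 1$, the inclusive vertical pixel
  extent. The bare top–bottom difference would assign a single-pixel gland
  height 0 and make `width = area / height` undefined; the inclusive
  convention gives height 1 there and makes width exact for filled
  rectangles. The exclusive variant remains available
  (`gland_height(..., inclusive = FALSE)`) for sensitivity analyses.
* **Width** $w = |G| / h$: the mean number of gland pixels per occupied
  row band, a robust width proxy for stripes of varying cross-section.
* **Perimeter** $P$: the number of gland pixels with at least one
  4-neighbor outside the gland. The image border counts as outside, so
  glands touching the border are included rather than dropped. This is a
  boundary-*pixel count*, not a contour length (no Crofton or
  marching-squares estimate), matching the index definitions the package
  implements.
* **Minimum external rectangle**: the minimum-area rotated rectangle
  enclosing the convex hull of the gland's pixel centers, computed by
  rotating calipers over hull edges (the minimum over all orientations is
  attained with a side collinear to a hull edge). Its *height* is the
  **longer** side: glands are elongated, and the rectangle is there to
  measure length along the gland axis even when the gland is tilted.
  Conventions for degenerate inputs: a single pixel has rectangle height 1;
  collinear pixel sets use the hull segment length. Among equal-area
  rectangles (e.g. squares) the smallest absolute angle wins, so results
  are deterministic across platforms.
* **Tortuosity** $\tau = P / (2\,h_{\mathrm{rect}}) - 1$, with
  $h_{\mathrm{rect}}$ the rectangle height. For a straight gland the
  boundary consists of two sides of about $h_{\mathrm{rect}}$ pixels each,
  so $\tau \approx 0$; meandering increases boundary pixels at fixed
  rectangle height.

Because geometry is done on pixel centers, an axis-aligned $h \times w$
rectangle has rectangle height $h - 1$, one less than its pixel-extent
height. This ±1 px center-versus-extent discrepancy is inherent to the
pixel-center convention, is documented here once, and is absorbed by the
closed-form expressions used in the tests
($\tau = (2h + 2w - 4)/(2(h-1)) - 1$ for filled rectangles).

A property worth knowing before interpreting small tortuosity differences:
the boundary-pixel count is insensitive to *sub-pixel* lateral slopes. A
sinusoidal displacement whose slope never reaches about 1 px/row adds no
boundary pixels (and discretization can even remove one), so tortuosity
responds to distortion only once the lateral slope crosses that threshold.
The test suite probes monotonicity at amplitudes above it.

## Eyelid-level indices

* **Density** = (Σ gland areas) / (tarsus area) ∈ [0, 1]. Gland pixels
  outside the tarsus are a *hard error*, never clipped silently — the
  definition presumes glands ⊆ tarsus, and a violation means the masks are
  misregistered.
* **Eyelid means** of height, width and tortuosity are unweighted means
  over glands; with zero glands they are missing and density is 0.
* **Vagueness** = mean gland grayscale − mean non-gland tarsus grayscale,
  computed strictly inside the tarsus. It is a *signed* contrast: glands
  darker than their surround give negative values, and higher values mean
  a clearer image. It is exactly invariant to adding a constant to the
  image and scales linearly with intensity rescaling; the raw grayscale
  input is used, with no preprocessing.
* **Both-eyelid values** are the unweighted mean of the upper- and
  lower-eyelid values (missing if either is missing), with gland counts
  summed. Published per-lid summaries of this kind lie between the two
  per-lid values, which pooled recomputation does not guarantee when the
  lids contribute unequal gland counts; the pooled variant
  (count-weighted means, pixel-pooled density) stays available via
  `combine_eyelids(..., method = "pooled")`.

Connected components use 8-connectivity throughout (diagonal pixels join),
fixed rather than configurable: thin tilted glands fragment under
4-connectivity. Label maps are canonicalized to ids `1..K` ordered by each
component's topmost-leftmost pixel in raster-scan order, so repeated runs
and platforms agree; partially imaged glands at the eyelid margin are
included.

## The synthetic generator

Real meibography with expert masks is not freely available at scale, so
validation rests on a generator whose ground truth is exact by
construction. A gland is a sinusoid-displaced vertical stripe

$$\{(r, c) : |c - (c_0 + a \sin(2\pi p (r - r_0)/L))| \le w_{1/2}\},$$

the simplest family spanning straight, twisted and (via
`fragment_spec()`) fragmented morphologies. The vertical extent is $L$
exactly, rendering is seed-free, and connectivity is validated. The tarsus
is a rectangle inset from the border — tarsal curvature is presentational
and irrelevant to any index. Images are two-level intensity fields plus
clipped additive Gaussian noise (no blur or speckle model).

Defaults describe a full-resolution meibography crop: 380 × 480 px canvas,
8–11 glands per lid, upper-lid gland length ~150 ± 30 px and width ~21 px,
lower-lid length ~90 ± 18 px, amplitudes ~8 px with 0.030–0.042 cycles/px,
foreground/background intensities 148/120 (vagueness ≈ 28, per-eye contrast
jitter sd 6), pixel noise sd 10. These place every index in the ranges
reported for clinical cohorts (upper-lid density ≈ 0.2, tortuosity
0.4–0.6). The `scale` parameter shrinks all linear dimensions
proportionally — areas scale with scale², so density, tortuosity and
vagueness stay in range. Replicate simulations in the test suite and the
acceptance script run at `scale = 1/3` (a 127 × 160 px canvas), the size at
which hundreds of 26-subject replicates are a routine desk computation;
single-cohort examples run at any scale.

**Paired design.** Each subject contributes upper and lower eyelids for a
research eye and a contralateral control eye. Base gland parameters are
drawn per subject and lid; each eye then receives its own independent
lognormal jitter (sd 0.06/0.05/0.12 on length/width/amplitude), and the
research eye's parameters are additionally multiplied by the configured
`effects`. With all effects at 1 the two eyes are draws from *identical*
distributions — which is what makes the null calibration test meaningful. A
one-sided jitter applied to the research eye alone would inflate its
expected values (a lognormal has mean > its median) and bias the type-I
error, which is why the jitter is symmetric by design. Glands are placed
left-to-right with ≥ 2 px gaps between lateral footprints; when a
requested gland does not fit the tarsus it is dropped, a truncation that
acts identically (in distribution) on both eyes.

Follow-up intervals are drawn uniformly within one of four bins (0–3, 3–6,
6–12, > 12 months, equal probabilities by default); tear break-up time and
tear meniscus height covariates are drawn per eye from group-specific
normal distributions truncated at plausibility bounds.

What the generator does **not** emulate: optical blur, vignetting,
illumination gradients, specular reflections, conjunctival edema optics
(contrast loss is represented only by lowering the foreground/background
gap), eyelash occlusion, and segmentation error — the masks are perfect.
Passing tests therefore demonstrate that the *index computations and
statistics* are correct and calibrated, not that any segmentation method
works on real images.

## Statistics

The pipeline mirrors a paired clinical comparison:

* **Normality gate.** Differences (research − control) are tested with the
  Kolmogorov–Smirnov test corrected for estimated parameters — the
  Lilliefors test (`nortest::lillie.test`); the naive KS against
  $N(\bar x, s)$ is anticonservative and available only by flag. Samples
  with fewer than 5 values or zero variance are non-testable and routed to
  the rank test.
* **Paired test.** Normal-looking differences use the paired *t*-test;
  otherwise the Wilcoxon signed-rank test, with the exact null
  distribution up to 25 non-zero differences and the normal approximation
  with continuity correction above, zeros dropped per the standard
  convention. All-zero differences report p = 1 with a degenerate flag.
  The exact route is verified against full $2^n$ sign-assignment
  enumeration for $n \le 10$.
* **Stratification.** Follow-up bins are right-closed: (0, 3], (3, 6],
  (6, 12], (12, ∞) months, so a 3.0-month interval falls in the first bin.
  Bins with < 3 pairs are summarized without a p-value. Each record is
  treated as one subject-visit.
* **Correlations** with TBUT/TMH use Spearman ranks (several indices are
  typically reported as median/IQR, i.e. non-normal); Pearson by flag.
* **Multiplicity.** No correction by default, matching customary reporting
  of these tables; Benjamini–Hochberg is available in the report stage.

## Validation strategy and problem sizes

The suite is oracle-driven: perimeter against brute-force 4-neighbor
enumeration on 200 random blobs; the minimum rectangle against an
exhaustive 0.5°-step rotation search (agreement within 1% enclosing area);
exact Wilcoxon p-values against sign-assignment enumeration; generator
ground truth against pipeline output as exact pixel-count identities.
Statistical calibration uses 200 null replicates of a 26-subject cohort at
`scale = 1/3` (empirical type-I error within [0.01, 0.10] per index) and
100 replicates with injected effects (gland length ×0.85, gland count
×0.85), where the direction of the group difference must be recovered in
≥ 95% of replicates and reach p < 0.05 in the majority.

## Known limitations

* Tortuosity is scale-dependent through the pixel grid and insensitive to
  sub-pixel meander, as discussed above; it is not an arc-length/chord
  ratio of the gland centerline.
* Density, height and width depend on the tarsus delimitation, which the
  package requires as an input and does not infer.
* Label maps written as 8-bit PNG support at most 255 glands per image.
* The generator's intensity model is two-level; vagueness on real images
  integrates texture the model does not produce.
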