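Package: meibomorph
Title: Meibomian Gland Morphometry from Meibography Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of meibomian gland (MG) morphology from
    infrared meibography images of the everted eyelid. Given a grayscale
    image together with a gland label mask and a tarsus region-of-interest
    mask, the package computes per-gland height, width and tortuosity (via
    the minimum-area external rectangle of each gland), eyelid-level gland
    density, and the vagueness value (gland-versus-background grayscale
    contrast within the tarsus). A synthetic meibography generator produces
    images with exact ground-truth masks and paired research/control
    cohorts with configurable effect sizes, and a statistics pipeline
    performs normality-gated paired comparisons (paired t-test or Wilcoxon
    signed-rank), follow-up-interval stratification, clinical-covariate
    correlations and report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
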