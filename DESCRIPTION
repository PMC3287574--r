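Package: mammoseg
Title: Automatic Mass Segmentation for Mammographic Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automatic two-stage segmentation of masses in
    mammographic regions of interest: edge-preserving noise reduction
    (Perona-Malik anisotropic diffusion), marker-controlled watershed
    flooding of the Sobel gradient for a coarse mass mask, and Chan-Vese
    region-based level-set refinement of the mass boundary. Includes an
    overlap-based evaluation suite (Hitting, Missing, OverHitting,
    RelativeHitting, RelativeMissing, Kappa), and a deterministic
    synthetic-phantom generator with known ground-truth masks for
    testing the pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
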