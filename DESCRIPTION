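Package: hookmorph
Title: Elliptic Fourier Outline Morphometrics of Parasitic Isopod Attachment Hooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outline-based geometric morphometrics for the hook-shaped dactyli
    that cymothoid isopods use to attach to their fish hosts. Reads Freeman
    chain-code (.chc) and normalized elliptic Fourier descriptor (.nef) files,
    traces binary raster masks, canonicalizes and resamples closed outlines,
    computes Kuhl-Giardina elliptic Fourier descriptors with
    size/rotation/start-point normalization, runs covariance PCA of the
    coefficient matrix (morphospace), reconstructs eigen-shapes, quantifies
    per-group morphospace occupation via convex hulls and overlaps, and
    measures ontogenetic shape-change vectors. Includes a synthetic
    hook-outline generator with controlled centerline curvature and relative
    thickness so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    png,
    tiff
Config/testthat/edition: 3
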