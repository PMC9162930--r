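Package: biofilmz
Title: Biofilm Thickness from Confocal Z-Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies biofilm thickness from confocal laser scanning
    microscopy (CLSM) xz-sections and their exported fluorescence line
    profiles. Each region of interest (ROI) yields an intensity-versus-depth
    profile that is segmented by side-specific background thresholding
    (default three times the mean background intensity, estimated separately
    on the electrode and the buffer side of the intensity maximum); the
    biofilm end is taken as the edge of the contiguous above-threshold run
    containing the maximum, which rejects spurious signal from planktonic
    cells floating above the biofilm. Per-ROI thicknesses are aggregated into
    per-image and per-electrode summaries, spatial homogeneity reports and
    correlations with reactor performance indicators. Includes a reader for
    microscope CSV exports that auto-detects encoding, delimiter and decimal
    mark, a TIFF-based profile extractor, and a synthetic-data generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
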