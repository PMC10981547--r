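Package: tonguecolor
Title: Positional Tongue Color Difference Analysis with CIEDE2000
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the effect of patient position (sitting versus supine)
    on tongue color as used in Kampo/TCM tongue diagnosis. Converts tongue
    photographs from sRGB to CIE L*a*b*, partitions the tongue into edge,
    posterior, middle and apex regions by an extended ratio-based (Chiu-style)
    scheme, computes CIEDE2000 (dE00) color differences between paired
    sitting/supine edge colors, classifies them against the 50:50%
    acceptability threshold (AT = 4.1), and relates color differences to
    biometric covariates via Pearson correlation and the correlation ratio
    (eta squared). Includes a synthetic paired-image generator with known
    ground truth for end-to-end validation, and a bundled 18-patient example
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    farver,
    withr
Config/testthat/edition: 3
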