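Package: leafasym
Title: Elliptic Fourier Analysis of Leaf Outline Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outline morphometrics for studies of leaf shape asymmetry along a
    shoot. Extracts closed contours and Freeman chain codes from binary leaf
    silhouettes, computes normalized elliptic Fourier descriptors that preserve
    chirality, decomposes shape variance into bilaterally symmetric (a, d) and
    asymmetric (b, c) harmonic coefficients, fits principal component models of
    each subspace with +/-2 SD outline reconstructions, and tests how node
    position, phyllotactic direction and leaf face modulate asymmetry, shape
    and size via factorial ANOVA with backward single-term model selection and
    loess trend summaries. Includes a synthetic generator of two-sided
    (abaxial-top / adaxial-bottom) leaf silhouettes with known developmental
    and asymmetry structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
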