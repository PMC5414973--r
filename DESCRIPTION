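Package: fluorquant
Title: Whole-Specimen Fluorescence Quantification and Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies externally expressed fluorescence of whole specimens
    from 12-bit grayscale image pairs (white-light and fluorescence), using
    polygonal areas of interest, mean pixel intensity, a ten-category
    brightness histogram, and the percent of area in the brightest category.
    Includes photon-equivalent exposure calibration from absolute-irradiance
    spectra, nonparametric group comparisons (Kruskal-Wallis omnibus tests
    with Dunn's post-hoc pairwise tests) across sexes and life stages,
    reflectance and emission spectrum processing, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
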