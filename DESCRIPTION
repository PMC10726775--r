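Package: paindraw
Title: Pixel-Level Analysis of Template Pain Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digitizing and analysing pen-and-paper template pain
    drawings at the pixel level. Scanned sheets are registered to a body-outline
    template via three fiducial markers, pen marks are binarized and clipped to
    the drawable region, and cohorts of drawings are compared through group pain
    profiles (per-pixel marking proportions) using the Ruzicka similarity index,
    a generalization of the Jaccard index to non-binary rasters. Significance of
    group differences is assessed with a label-permutation test (Monte-Carlo or
    exhaustive), pairwise-similarity structure is summarized as heatmaps and
    boxplots, marked-pixel counts are compared with rank-sum and t tests, and
    questionnaire contingency tables are analysed with Fisher's exact test
    (conditional maximum-likelihood odds ratio and exact confidence interval),
    chi-squared and Welch t tests. A synthetic-data module generates body
    templates, pain-drawing cohorts with controllable group effects, and noisy
    scan renders with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
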