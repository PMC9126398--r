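Package: adcroi
Title: Reference ADC Computation and Multi-Reader Agreement Analysis for
    Prostate Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes observer-independent reference apparent diffusion
    coefficient (ADC) values for prostate lesions from 3D ADC maps and lesion
    masks, using exhaustive sliding 2D region-of-interest (ROI) minimum-mean
    filtering over a family of square and near-circular kernel footprints,
    whole-lesion percentile statistics, and peripheral-zone parenchyma medians.
    Provides the multi-reader agreement statistics used to compare free-hand
    and instructed ROI measurement protocols (multi-rater Bland-Altman limits
    of agreement, intraclass correlation against the computed reference,
    Friedman omnibus tests with Holm-adjusted Wilcoxon post-hocs, and unpaired
    group contrasts), together with a synthetic ADC phantom generator and a
    virtual-reader simulator so the full pipeline can be exercised and
    validated without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    ggplot2
Config/testthat/edition: 3
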