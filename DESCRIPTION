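Package: scarq
Title: Myocardial Scar Extent Quantification from LGE-CMR Contours and Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies left-ventricular scar burden from late gadolinium
    enhancement cardiovascular magnetic resonance (LGE-CMR) segmentations.
    Takes per-slice endocardial and epicardial contours plus a co-registered
    binary scar raster, and computes global percent scar and scar mass together
    with per-segment transmural scar extent on the AHA 17-segment model by four
    estimators: area-based (STAB), radial chord-based (STLB), intensity-weighted
    mass-based (WIT) and maximal-chord (SMST), with quartile binning of the
    transmural extent. Includes synthetic annular phantoms with wedge-shaped
    scars and closed-form ground truth for validation, a toy cohort simulator,
    and median-dichotomization 2x2 diagnostic statistics (sensitivity,
    specificity, predictive values, Fisher's exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
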