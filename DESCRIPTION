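Package: steatoCT
Title: Opportunistic Hepatic Steatosis Quantification from Contrast-Enhanced CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hepatic steatosis from routine CT scans,
    including those acquired with intravenous contrast. Extracts liver and
    spleen mean attenuation from labeled volumes or circular regions of
    interest, converts post-contrast liver attenuation to a non-contrast
    equivalent via phase-specific increasing exponential-decay correction
    equations, estimates an MR-PDFF-equivalent fat fraction, classifies
    moderate-to-severe steatosis at standard thresholds, and evaluates
    candidate thresholds with confusion-matrix metrics, trapezoidal AUROC,
    paired DeLong tests and Spearman correlation. Ships synthetic phantom and
    cohort simulators so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
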