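Package: cranioflow
Title: Intracranial Hemodynamics and Compliance from Velocity-Encoded Cine MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cerebral arterial inflow, primary and secondary venous
    outflow and craniospinal CSF flow from retrospectively gated velocity-encoded
    cine phase-contrast MRI, and derives the intracranial volume-change waveform,
    CSF pressure gradient, compliance index and an MR-based estimate of
    intracranial pressure. Includes pulsatility-based lumen segmentation, an
    analytic Womersley flow phantom generator for end-to-end validation, a
    synthetic cohort generator, and the rank-transform mixed-effects statistics
    used for matched-cohort comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
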