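Package: fusbbbo
Title: Quantification Pipelines for Focused-Ultrasound Blood-Brain Barrier Opening Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification procedures for focused-ultrasound microbubble
    blood-brain barrier opening (FUS-BBBO) experiments: per-pulse passive
    cavitation detection spectra decomposed into stable harmonic,
    stable ultraharmonic and inertial cavitation doses; contrast-enhanced
    T1 MRI opening-volume estimation by contralateral-ROI thresholding;
    confocal vessel segmentation, caliber classification, tracer-leakage
    colocalization and tight-junction gap morphometry; and single-cell QC
    filtering, signed gene scoring and preranked gene-set enrichment with a
    permutation FDR. Synthetic generators with exact ground truth emulate
    each input modality for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
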