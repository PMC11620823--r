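Package: pulsevessel
Title: Data-Driven Segmentation of Cerebral Vessels from fMRI Pulsatility
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments large cerebral arteries and the superior sagittal sinus
    directly in fMRI space by exploiting the cardiac-locked pulsatility of
    voxel time series. Implements retrospective cardiac alignment of BOLD
    signals to a finger-plethysmography reference, randomized split-half
    correlation mapping, data-driven thresholding and iterative
    template-correlation refinement of vessel masks, together with
    photoplethysmography and motion quality control, segmentation
    reproducibility statistics (Dice, percent overlap, ICC, total least
    squares, Bland-Altman) and spectral verification of cardiac-band
    amplification. A fully synthetic pulsatile phantom generator provides
    ground-truth test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Segmentation, Preprocessing, QualityControl
RoxygenNote: 7.3.3
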