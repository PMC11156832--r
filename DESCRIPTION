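Package: angioqa
Title: Quality Assessment and Cross-Modality Similarity for Intracranial Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative quality assessment of time-of-flight MR
    angiography (TOF-MRA) and for its comparison against reference angiograms
    such as digital subtraction angiography (DSA). Implements the two-acquisition
    difference method for signal-to-noise ratio, paired-ROI contrast-to-noise
    ratio, rigid mutual-information registration with nearest-neighbour ROI
    propagation, Canny edge-pixel quantification of angiogram quality, qualitative
    vessel-visibility score aggregation, and a complex-wavelet structural
    similarity index computed on Otsu-segmented images. A digital vascular
    phantom generator (tubular vessel trees with graded calibers, repeat
    acquisitions with independent noise, DSA-like projections) makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
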