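Package: bbgrowcut
Title: GrowCut and Band-Based GrowCut Cellular-Automaton Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded image segmentation with the GrowCut cellular automaton and
    its band-based extension, in which each cell's Moore neighbourhood is
    augmented with k remote neighbours sampled uniformly from a distant
    Chebyshev annulus at every iteration. Includes algorithmic vertical-line
    seed generation from ground-truth masks, supervised and unsupervised
    segmentation quality metrics (Dice, Jaccard, over- and under-segmentation
    entropy, region uniformity, discrepancy, Hausdorff distance), win-source
    instrumentation of label propagation (local, remote, remote-override),
    slice-wise and fully volumetric 3D segmentation, synthetic scene
    generators for testing, and readers and writers for PNG, TIFF and NIfTI
    images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    tiff,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
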