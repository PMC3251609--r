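Package: thalatract
Title: Connectivity-Based Thalamic Target Mapping on Digital Fibre Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies inter-individual variability of tractography-defined
    thalamotomy targets (the putative Vop and Vim nuclei). Provides simplified
    probabilistic multi-fibre streamline tractography from a thalamic seed
    mask to cortical target masks, connectivity-based winner-take-all
    parcellation, 10-percent-of-maximum thresholding, AC-fixed six
    degree-of-freedom landmark normalisation, and peak-distance and Tanimoto
    overlap statistics. A digital fibre-phantom generator produces synthetic
    cohorts with known ground-truth peak locations so that the full pipeline
    can be validated against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
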