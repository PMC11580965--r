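Package: varimap
Title: Image-Varifold Representation and Diffeomorphic Mapping of Spatial Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents spatial-omics detections (mRNA transcripts, typed cells) and
    labeled tissue atlases as particle measures ("image varifolds"): weighted point
    masses in physical space, each carrying a probability distribution over a discrete
    feature space.  Provides reproducing-kernel (varifold) norms between such measures,
    rigid serial-section alignment, diffeomorphic registration by Hamiltonian geodesic
    shooting of particles, cross-modality mapping that jointly estimates per-region
    latent feature laws with a Kullback-Leibler prior, spatial censoring functions for
    partial-volume targets, optimization-based scale-space resampling to fixed particle
    complexity, and mutual-information scoring of spatially variable features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
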