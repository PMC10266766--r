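Package: stabscan
Title: Rapid Protein Stability-Change Prediction from Voxelized Structure
    Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage prediction of protein stability changes (ddG, in
    kcal/mol) for single amino-acid substitutions. A self-supervised 3D
    convolutional network is trained to recover the identity of a masked
    residue from the voxelized atomic environment around its C-alpha; the
    100-dimensional latent representation then feeds a supervised
    fully-connected regressor trained on Fermi-transformed ddG targets.
    Includes saturation-mutagenesis scanning with solvent-accessibility
    based burial annotation, variant-table joining, allele-frequency
    binning, bootstrap median-difference statistics, and seeded generators
    for toy structures and synthetic ddG landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
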