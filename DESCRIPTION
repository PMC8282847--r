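Package: emrestore
Title: Learned Post-Processing of Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric restoration of cryo-EM density maps by a 3D U-net
    trained to perform masking-like and local-sharpening-like operations in a
    single step. Provides MRC/CCP4 map input/output, resampling to a fixed
    1 Angstrom/voxel working grid, noise-statistics normalization, cube
    chunking with overlap-averaged reassembly, a from-scratch 3D U-net
    (group normalization, PReLU, strided/transposed convolutions) with SGD
    training under a plateau learning-rate schedule and mean-absolute-error
    loss, a synthetic map simulator (Gaussian-atom models, B-factor contrast
    degradation, independent half-map noise, tight masks), and an evaluation
    suite based on Fourier shell correlation and real-space correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
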