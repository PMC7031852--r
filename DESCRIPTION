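Package: smFISHcoloc
Title: 3D Single-Molecule FISH Transcript Colocalization Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies transcript colocalization in 3D multi-channel
    confocal z-stacks from single-molecule fluorescence in situ
    hybridization (smFISH/RNAscope) experiments. Segments cell nuclei from
    the DAPI channel (Gaussian smoothing, adaptive thresholding and
    watershed splitting of oversized objects), detects diffraction-limited
    transcript puncta per probe channel (intensity threshold plus
    watershed splitting of merged clusters), assigns each punctum to a
    nucleus by its 3D position, calls per-cell gene positivity, and
    compares genotype groups with Student's t test. Includes a synthetic
    confocal-stack generator with exhaustive ground truth for validation,
    blinded-analysis bookkeeping, and formula-level gene-set
    over-representation statistics (hypergeometric and Fisher exact tests
    with Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Spatial, Transcriptomics, Visualization
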