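Package: sptarget
Title: Tripartite Signal-Peptide Profiling and Organelle Targeting-Efficiency
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing dual mitochondrial/ER targeting determinants
    of bacterial signal peptides in plant cells. Provides tripartite (n/h/c)
    region annotation, sliding-window Eisenberg hydrophobic-moment and
    hydrophobicity profiles, helical-wheel projections, consensus-motif
    scanners (Tom20 phi-x-beta-phi-phi, twin-arginine TAT, AxA signal-peptidase
    site), programmatic construction of substitution/deletion mutant panels,
    a synthetic two-channel confocal-field generator with ground-truth masks,
    and a targeting-efficiency statistic based on Yen-threshold segmentation
    of mitochondrial puncta with a Mann-Whitney two-group comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
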