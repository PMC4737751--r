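Package: denfit
Title: Density-Guided Integrative Assembly of Coarse-Grained Protein
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pseudo-atomic models of multi-subunit protein
    complexes by fitting coarse-grained, partially flexible components
    into low-resolution electron density maps. Provides MRC2014/CCP4 map
    input and output, map simulation from bead models, thresholded
    envelope masks, masked cross-correlation and Fourier shell
    correlation with resolution estimation; spatial restraints
    (proximity, contact, connectivity) combined into a composite fit
    score; Metropolis Monte Carlo simulated annealing with a geometric
    cooling schedule and multi-run ensemble generation; rigid-body
    docking by deterministic rotational sampling with FFT translation
    scans; ensemble reduction by RMSD clustering, solvent-exposure
    filtering and representative selection with model-to-map
    correlation; and synthetic ground-truth benchmark generators so the
    whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
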