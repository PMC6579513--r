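Package: hdxscreen
Title: Differential Hydrogen-Deuterium Exchange Mass Spectrometry Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for differential hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) screening of protein-ligand libraries: conversion
    of mass-spectral centroids to percent deuterium incorporation with
    empirical Dmax back-exchange correction, ligand-versus-vehicle
    perturbation statistics with Benjamini-Hochberg false-discovery control,
    a two-timepoint screening filter, residue-level consolidation of
    overlapping peptic peptides with length weighting, structure-activity
    correlation, peptide-peptide covariation, and Ward clustering of
    compound perturbation signatures. A forward simulator of
    protection-factor exchange kinetics with planted ligand effects and
    linearly coupled functional-assay readouts provides ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
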