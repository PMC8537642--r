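Package: nbrank
Title: Machine-Learning Re-Ranking of Nanobody-Antigen Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-ranks rigid-body docking poses of nanobody-antigen complexes.
    Refined poses are labelled by docking quality (DockQ: Fnat, interface RMSD
    and ligand RMSD combined), described by a 248-column profile of contact,
    interface-energy and interface-property features, and scored by a
    gradient-boosted binary nativeness classifier trained under grouped
    (per-complex) cross-validation.  Parent poses are then re-ranked by the
    averaged predicted nativeness of their refined children.  Includes a
    synthetic two-chain complex and decoy generator spanning all DockQ quality
    classes, parsers for Rosetta InterfaceAnalyzer and FoldX AnalyseComplex
    energy tables, rank-percentile and precision-recall evaluation, and
    additive (SHAP-style) per-feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
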