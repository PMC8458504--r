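Package: wasscreen
Title: Machine-Learning-Enhanced Virtual Screening for Degradation-Site
    Targeting Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale structure-based virtual screening pipeline for
    small molecules that bind a degradation-regulating protein pocket, such
    as the WASp WH1 domain surface carrying ubiquitylation lysines K76/K81.
    Provides a molecular graph model with SMILES and SDF V2000 input/output
    and a SwissADME-style drug-likeness descriptor panel (Ertl TPSA,
    Wildman-Crippen logP, ESOL logS, Lipinski rules, Abbott bioavailability
    score); PDB structure preparation with virtual point mutagenesis and
    component deletion; torsion-sampled 3D conformer generation with
    force-field minimization; rigid patch-style docking with pose clustering
    and refinement; interaction-fingerprint featurization with a seeded
    random-forest binder classifier; degradation-site proximity filtering
    and clash verification; closed-form assay models (1:1 binding isotherm
    Kd fitting over serial dilutions, FRET efficiency, gelatin degradation,
    tumor volume, TD50, plasma protein binding); and deterministic synthetic
    benchmark generators so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest
Config/testthat/edition: 3
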