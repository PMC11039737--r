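Package: phorescreen
Title: Ligand-Based Pharmacophore Modeling, Screening and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based pharmacophore analysis of small
    molecules: a five-kind feature model (aromatic, hydrophobic, H-bond
    acceptor, H-bond donor, metal ligator) with typed boolean feature
    expressions and spherical tolerance radii; rule-based perception of
    pharmacophoric features from 3D structures (SDF or SMILES embedded
    via Open Babel); partial-match fitting of candidate molecules by
    least-squares rigid superposition with per-feature tolerance
    containment and n-of-m fitting scores; consensus model generation
    from aligned ligand ensembles; Lipinski and Veber drug-likeness
    filtration; actives/decoys validation statistics (sensitivity,
    specificity, false-positive rate, accuracy, predictive values); and
    a seeded synthetic actives/decoys benchmark generator. Ships a
    built-in dual hIDO1/hTDO2 inhibitor pharmacophore model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    methods,
    ChemmineR,
    ChemmineOB,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
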