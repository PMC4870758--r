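Package: opsinsites
Title: Candidate Spectral-Tuning-Site Analysis for Duplicated Insect Opsins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening duplicated insect opsin paralogs for candidate
    spectral-tuning sites. Classifies amino-acid substitutions by structural and
    chemical significance (side-chain size, polarity, charge, disulfide
    potential, backbone rigidity), computes paralog percent similarity under
    BLOSUM62, maps query positions onto bovine-rhodopsin site numbering with
    insertion codes, detects chromophore-binding-pocket residues within a
    distance cutoff of the retinal ligand in atomic-coordinate models, and
    integrates branch-site positive-selection results and literature evidence
    at homologous sites into a combined candidate-site screen. Includes
    seed-deterministic synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
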