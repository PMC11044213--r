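Package: fodm
Title: Fuzzy Oil Drop and Environment-Modified Hydrophobicity Analysis of
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how closely the hydrophobicity distribution of a
    protein structure follows the micelle-like ideal of a hydrophobic core
    with a polar surface. The fuzzy oil drop (FOD) model compares the
    observed per-residue hydrophobicity profile, obtained from pairwise
    Levitt-function interactions of intrinsic residue hydrophobicities,
    against a theoretical profile given by a 3D Gaussian envelope fitted to
    the molecule, summarised by the relative distance statistic RD built
    from Kullback-Leibler divergences. The environment-modified extension
    (FOD-M) mixes the Gaussian field with its complement, weighted by a
    parameter K fitted by divergence minimisation, to score non-aqueous
    folding environments such as membranes or chaperonin chambers. Includes
    residue elimination to a target RD, hydrophobicity excess/deficit
    segment detection, layer classification, protein-protein interface
    scoring, synthetic micelle fixtures, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
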