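Package: smigen
Title: Character-Level SMILES Generation and Generator Biasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a character-level recurrent (GRU) language model on
    SMILES strings and biases it toward a target chemical space by either
    REINFORCE policy gradients or conditional reduction of the
    cross-entropy loss value (CRLV), in which the training loss is scaled
    down as the fraction of generated molecules that already satisfy the
    objective grows. Ships the evaluation funnel used to benchmark
    generative chemistry models (validity, novelty, uniqueness, internal
    diversity, desirability), five built-in drug-likeness objectives, a
    structural-variance difficulty statistic for SMILES, and cross-model
    comparison tools (set intersection, property-distribution extraction,
    Morgan fingerprint export). Molecule handling (validity,
    canonicalization, descriptors, fingerprints) is delegated to RDKit
    through a batched Python bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' (used for SMILES validity, canonicalization, descriptors and
    fingerprints)
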