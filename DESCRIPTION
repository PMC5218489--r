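Package: pcrfidelity
Title: Single-Molecule Analysis of PCR Error Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of the distinct error classes that arise during PCR
    amplification as seen by strand-specific single-molecule consensus
    sequencing: polymerase base substitutions and indels (raw,
    composition-averaged and per-doubling-normalized rates with mutational
    spectra), thermocycling-induced cytosine-deamination damage,
    template-switching at inverted-repeat (cruciform) elements detected by
    classification against four constructed references, and PCR-mediated
    recombination between co-amplified marker-bearing homologs. A
    branching-process / closed-form PCR simulator generates consensus-like
    reads with full ground truth, so every estimator is verifiable by
    parameter recovery without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
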