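Package: toxkit
Title: Quantitative Characterization of Dual-Function Kunitz-Type Toxins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for BPTI-Kunitz-type peptides that both inhibit
    serine proteases and block voltage-gated potassium (Kv) channels. Implements
    tight-binding inhibition kinetics (the quadratic Morrison model, active-site
    titration, substrate correction of apparent Ki, reversibility assessment),
    concentration-response analysis of channel block (Hill equation IC50),
    conductance-voltage gating analysis (Boltzmann V1/2 fits, voltage dependence
    of block), detection of the six-cysteine Kunitz framework in multiple
    sequence alignments with extraction of the cysteine-flanking sequence
    windows, physicochemical class profiling with compensated-substitution
    detection and specificity grouping, and solvent accessibility from
    coordinates (Shrake-Rupley algorithm, relative accessible surface area,
    interatomic contacts). A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
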