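Package: aspenselect
Title: Molecular Population Genetics of Wound-Induced Defense Genes in Aspen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene molecular population genetics of candidate defense
    genes: site-frequency-spectrum summaries and neutrality tests (Tajima's
    D, normalized Fay and Wu's H), Nei-Gojobori synonymous/replacement site
    partitioning, Jukes-Cantor corrected divergence, McDonald-Kreitman
    tests with the neutrality index and likelihood-ratio G, sliding-window
    scans of diversity, SFS skew and KA/KS, and a Hudson-style coalescent
    simulator (fixed-S and theta mutation modes, piecewise-constant
    bottleneck demography) providing null distributions, empirical p-values
    and per-window confidence bands. Includes a synthetic coding-alignment
    generator with outgroup, codon structure and neutral, sweep-like and
    balancing-like genealogies so the whole pipeline is testable without
    sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
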