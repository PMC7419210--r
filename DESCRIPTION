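Package: dupliconevo
Title: Permutation Enrichment and Molecular Evolution of Core-Duplicon Segmental Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the evolutionary genomics of interspersed
    segmental duplications seeded by a core duplicon. Provides a BED-style
    interval algebra (merging, masking, unique-flank extraction, repeat
    overlap counting), a permutation engine testing enrichment of GC, SINE
    and LINE content at duplication donor, acceptor and pre-integration
    regions (enrichment coefficients, Kolmogorov-Smirnov and Z-score
    empirical p-values, Bonferroni correction and binomial standard errors),
    breakpoint-junction repeat classification and pre-integration deletion
    accounting, clone-library copy-number estimation, and a molecular
    evolution suite: modified Nei-Gojobori dN/dS with pathway averaging and
    one-tailed Z-tests, Kimura two-parameter distances, neighbor-joining
    trees with bootstrap supports, Tajima relative rate tests and
    rate-calibrated duplication timing. Seeded synthetic-data generators
    produce repeat-annotated genome landscapes, duplication histories and
    codon paralog families with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
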