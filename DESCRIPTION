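Package: edcrp
Title: Repeat Architecture and Convergent Evolution of Cysteine-Rich Epidermal Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing cysteine-rich cornification proteins of
    feathers and hair. Decomposes epidermal differentiation cysteine-rich
    protein (EDCRP) and keratin-associated protein (KRTAP) sequences into an
    amino-terminal segment, typed tandem repeat units anchored on the CCDPCQ
    core hexapeptide, and a carboxy-terminal segment; profiles cross-linking
    relevant amino-acid composition and the periodicity of consecutive-cysteine
    (CC) dipeptide sites; classifies proximal promoters by canonical TATA box
    versus the TATA-like element AATAAAA; and scores homology versus convergent
    evolution from exon-intron structure and gene-neighborhood (synteny)
    concordance. Includes a seeded synthetic-sequence generator with recorded
    ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
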