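Package: mtp9
Title: Mitochondrial tRNA p9-Site Methylation Analysis from RNA-Seq
Version: 0.1.0
Authors@R:
    person("mtp9", "Maintainers", email = "mtp9@example.org", role = c("aut", "cre"))
Description: Quantifies m1A/m1G methylation at the ninth position (p9) of
    mitochondrial tRNAs from aligned RNA-seq reads as the proportion of
    non-reference alleles, and relates it to polycistronic transcript
    cleavage, mitochondria-normalized gene expression, paired tumor-normal
    differences, genotype-by-disease-state interactions, and patient
    survival. Ships a seeded synthetic-data generator (reads, genotypes,
    expression, clinical tables) with known ground truth so the full
    pipeline is testable without controlled-access data, plus a
    command-line driver for each stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
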