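Package: fastdr
Title: Detection of Insecticide Resistance Markers from RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects the two major classes of insecticide-resistance markers
    from RNA-Seq alignments of pooled insect population samples. The
    target-site branch builds CIGAR-aware base pileups over target-gene cDNA
    references (voltage-gated sodium channel, acetylcholinesterase, ryanodine
    receptor, nicotinic acetylcholine receptor subunits), calls SNPs at
    covered positions, compares pooled allele frequencies between resistant
    and susceptible samples, translates differential sites into amino-acid
    substitutions, and annotates them against a catalog of published
    resistance mutations using canonical cross-species residue numbering
    obtained by pairwise protein alignment. The metabolic branch counts reads
    per detoxification gene (P450s, GSTs, CCEs), normalizes by
    median-of-ratios size factors, and tests for overexpression with a
    negative-binomial Wald test. Seeded simulators (uniform-coverage read
    simulation, variant spike-in with known allele fractions, negative
    binomial count simulation at set fold changes) and evaluation metrics
    (sensitivity, precision, ROC/AUC, frequency and fold-change R-squared)
    support validation against truth-tagged data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    DESeq2
Config/testthat/edition: 3
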