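# Regenerates the bundled plain-text fixtures under inst/extdata from the
# package's own deterministic generators. Run from the package root.
pkgload::load_all(".", quiet = TRUE)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

write_fasta(synthetic_target_genes(), "inst/extdata/synthetic_targets.fa")
write_fasta(synthetic_canonical_proteins(),
            "inst/extdata/synthetic_canonical_proteins.fa")

catalog <- data.frame(
  target = c("RyR", "nAChR-beta1", "VGSC"),
  canonical_accession = c("AET09964.1", "AFH00994.1", "AAB47604.1"),
  residue = c(4946L, 81L, 1014L),
  ref_aa = c("G", "R", "L"),
  alt_aa = c("E", "T", "F"))
write.table(catalog, "inst/extdata/resistance_catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
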