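test_that("call_snps applies the coverage and two-base rules", {
  ref <- c(g = strrep("C", 10))

  # 23 C (ref) / 24 T at one position
  p <- make_pileup(5, C = 23, T = 24)
  s <- call_snps(p, ref, min_coverage = 30)
  expect_equal(s$variant, "T")
  expect_equal(s$variant_count, 24L)
  expect_equal(round(s$frequency, 2), 51.06)

  # all reads carry the reference base: no SNP, queried frequency 0
  p <- make_pileup(5, C = 62)
  expect_equal(nrow(call_snps(p, ref, 30)), 0L)
  expect_equal(frequency_at(p, 5, "T"), 0)

  # coverage 29 with two bases: below threshold
  p <- make_pileup(5, C = 15, T = 14)
  expect_equal(nrow(call_snps(p, ref, 30)), 0L)
  # exactly 30 qualifies (threshold is >=)
  p <- make_pileup(5, C = 15, T = 15)
  expect_equal(nrow(call_snps(p, ref, 30)), 1L)

  # multi-allelic: most frequent non-reference base wins, rest diagnosed
  p <- make_pileup(5, C = 10, T = 12, A = 12, G = 3)
  s <- call_snps(p, ref, 30)
  expect_equal(s$variant, "A")         # alphabetical tie-break A over T
  expect_equal(s$other_bases, "G:3,T:12")

  # reference N positions are skipped with a warning
  refN <- c(g = paste0(strrep("C", 4), "N", strrep("C", 5)))
  p <- make_pileup(5, C = 20, T = 20)
  expect_warning(s <- call_snps(p, refN, 30), "reference base N")
  expect_equal(nrow(s), 0L)
})

test_that("call_snps agrees with a brute-force recount on random pileups", {
  ref <- c(g = random_cds(20, seed = 41))
  withr::with_seed(42, {
    for (k in 1:8) {
      starts <- sample.int(nchar(ref) - 10L, 10L, replace = TRUE)
      seqs <- vapply(starts, function(s) {
        paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
              collapse = "")
      }, character(1))
      reads <- make_reads(starts, seqs)
      mine <- call_snps(build_pileup(reads, ref), ref, min_coverage = 3)
      oracle <- brute_snps(reads, ref, min_coverage = 3)
      expect_equal(as.data.frame(mine[, .(pos, ref, variant, variant_count,
                                          coverage, frequency)]),
                   as.data.frame(oracle), ignore_attr = TRUE)
    }
  })
})

test_that("frequency_at distinguishes absent variant from absent coverage", {
  p <- make_pileup(c(10, 11), C = c(18, 45), T = c(20, 0))
  expect_equal(round(frequency_at(p, 10, "T"), 2), 52.63)
  expect_equal(frequency_at(p, 11, "T"), 0)
  expect_true(is.na(frequency_at(p, 99, "T")))
})

test_that("differential SNPs require both-sample coverage and a 40-point gap", {
  ref <- c(g = strrep("G", 20))
  case <- make_pileup(c(5, 9, 12), G = c(105, 10, 70), A = c(1895, 25, 70))
  ctrl <- make_pileup(c(5, 9, 12), G = c(1910, 20, 50), A = c(50, 0, 50))

  ds <- differential_snps(case, ctrl, ref)
  expect_equal(ds$differential$pos, 5L)
  expect_equal(round(ds$differential$case_frequency, 2), 94.75)
  expect_equal(ds$differential$delta,
               abs(ds$differential$case_frequency -
                     ds$differential$control_frequency))
  # position 12 sits at 50% vs 50%: excluded; position 9 is a SNP in the
  # case sample but the control has coverage 20 < 30: incomparable, kept
  # in its own section rather than dropped
  expect_true(9 %in% ds$incomparable$pos)
  expect_false(9 %in% ds$differential$pos)
  expect_false(12 %in% ds$differential$pos)

  # swapping case and control keeps the retained set, negates the sign
  sw <- differential_snps(ctrl, case, ref)
  expect_equal(sw$differential$pos, ds$differential$pos)
  expect_equal(sw$differential$diff, -ds$differential$diff)
  expect_equal(sw$differential$delta, ds$differential$delta)
})

test_that("positions map to codons and residues in frame from base 1", {
  expect_equal(position_to_residue(14837L), 4946L)
  expect_equal(position_to_residue(3040L), 1014L)
  expect_equal(position_to_residue(3L), 1L)
  expect_equal(codon_offset(c(1L, 2L, 3L, 14837L)), c(0L, 1L, 2L, 1L))
  expect_error(position_to_residue(0L), ">= 1")
})

test_that("variants translate through the standard genetic code", {
  refs <- synthetic_target_genes()

  tv <- translate_variant(refs["RyR_synthetic"], 14837L, "A")
  expect_equal(tv$ref_codon, "GGA")
  expect_equal(tv$alt_codon, "GAA")
  expect_equal(tv$label, "G4946E")
  expect_false(tv$synonymous)

  # CTG -> TTG is Leu -> Leu: synonymous, no label
  ref <- c(g = "CTG")
  tv <- translate_variant(ref, 1L, "T")
  expect_true(tv$synonymous)
  expect_true(is.na(tv$label))

  # AGA -> ACA is Arg -> Thr
  ref <- c(g = "AGA")
  tv <- translate_variant(ref, 2L, "C")
  expect_equal(tv$label, "R1T")

  # substitution to a stop codon is retained and flagged nonsense
  ref <- c(g = "TAC")
  tv <- translate_variant(ref, 3L, "A")
  expect_true(tv$nonsense)
  expect_equal(tv$alt_aa, "*")

  ref <- c(g = "ANG")
  expect_warning(tv <- translate_variant(ref, 1L, "C"), "contains N")
  expect_true(is.na(tv$label))

  expect_error(translate_variant(c(g = "ACGT"), 9L, "A"), "beyond")
})

test_that("scan_known reports catalog mutations without a control sample", {
  refs <- synthetic_target_genes()
  catalog <- load_catalog()
  vgsc <- refs["VGSC_synthetic"]

  # L1014F lives at position 3040 (C>T); build 8 variant / 30 reference
  reads <- make_reads(rep(3031L, 38),
                      c(rep(substring(vgsc, 3031, 3080), 30),
                        rep(paste0(substring(vgsc, 3031, 3039), "T",
                                   substring(vgsc, 3041, 3080)), 8)),
                      rname = "VGSC_synthetic")
  p <- build_pileup(reads, vgsc)
  sc <- scan_known(p, vgsc, catalog[catalog$target == "VGSC"])
  expect_equal(sc$label, "L1014F")
  expect_equal(sc$pos, 3040L)
  expect_equal(sc$variant, "T")
  expect_equal(sc$variant_count, 8L)
  expect_equal(sc$coverage, 38L)
  expect_equal(round(sc$frequency, 1), 21.1)
  expect_equal(sc$status, "ok")

  # empty pileup: entry reported with zero coverage, undefined frequency
  empty <- build_pileup(reads[0], vgsc)
  sc <- scan_known(empty, vgsc, catalog[catalog$target == "VGSC"])
  expect_equal(sc$coverage, 0L)
  expect_true(is.na(sc$frequency))

  # unmappable canonical residue
  nm <- align_proteins("MKL", "MKLVR")
  sc <- scan_known(p, vgsc, catalog[catalog$target == "VGSC"],
                   numbering = nm)
  expect_equal(sc$status, "not_mappable")
})

test_that("replicate frequencies aggregate by arithmetic mean", {
  mk <- function(f) data.table(label = "R81T", frequency = f)
  agg <- aggregate_replicates(list(mk(100 * 24 / 47), mk(100 * 16 / 31),
                                   mk(100 * 15 / 32)))
  expect_equal(round(agg$summary$mean_frequency, 2), 49.85)
  expect_equal(nrow(agg$per_replicate), 3L)

  one <- aggregate_replicates(list(mk(51.06)))
  expect_equal(one$summary$mean_frequency, 51.06)

  zeros <- aggregate_replicates(list(mk(0), mk(0), mk(0)))
  expect_equal(zeros$summary$mean_frequency, 0)
})

test_that("base-frequency rows are proportions that sum to one", {
  p <- make_pileup(c(3, 7), A = c(50, 23), G = c(50, 0), T = c(0, 24))
  m <- base_frequency_matrix(p, c(3, 7, 99))
  expect_equal(m[pos == 3, .(A, C, G, T)],
               data.table(A = 0.5, C = 0, G = 0.5, T = 0))
  expect_equal(rowSums(m[covered == TRUE, .(A, C, G, T)]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(round(m[pos == 7, T], 3), 0.511)
  expect_false(m[pos == 99, covered])
  expect_true(is.na(m[pos == 99, A]))
})
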