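test_that("read simulation is uniform, exact at zero error, and seeded", {
  ref <- c(g = random_cds(1000, seed = 81)) # 3 kb

  reads <- simulate_reads(ref, coverage = 100, read_length = 150,
                          error_rate = 0, seed = 82)
  expect_equal(nrow(reads), 2000L) # coverage * L / read_length

  # error-free reads are exact substrings at their reported positions
  expect_true(all(reads$seq ==
                    substring(ref, reads$pos, reads$pos + 149L)))
  expect_true(all(reads$cigar == "150M"))

  # same seed, byte-identical SAM; the caller's RNG state is untouched
  s1 <- tempfile(fileext = ".sam")
  s2 <- tempfile(fileext = ".sam")
  rng_before <- withr::with_seed(1, runif(1))
  write_sam(simulate_reads(ref, 10, 50, 0.01, seed = 9), ref, s1)
  write_sam(simulate_reads(ref, 10, 50, 0.01, seed = 9), ref, s2)
  expect_identical(readLines(s1), readLines(s2))
  expect_equal(withr::with_seed(1, runif(1)), rng_before)

  expect_error(simulate_reads(ref, coverage = 0, seed = 1), "positive")
  expect_error(simulate_reads(c(g = "ACGT"), 10, read_length = 150,
                              seed = 1), "read length")
})

test_that("exact-count spiking realizes round(f * coverage) variant reads", {
  ref <- c(g = random_cds(200, seed = 83))
  reads <- simulate_reads(ref, coverage = 100, read_length = 50,
                          error_rate = 0, seed = 84)

  sp <- withr::with_seed(85, spike_at(reads, "g", 300L, "A", 0.5))
  expect_equal(sp$realized_count, as.integer(round(0.5 * sp$coverage)))
  p <- build_pileup(sp$reads, ref)
  expect_equal(p[pos == 300, A], sp$realized_count)

  # a tiny frequency rounds to zero altered reads: not inserted
  sp0 <- withr::with_seed(86, spike_at(reads, "g", 300L, "A", 0.001))
  expect_equal(sp0$realized_count, 0L)

  sv <- spike_variants(reads, ref, n_variants = 40, seed = 87)
  expect_equal(sv$truth$inserted, sv$truth$realized_count > 0L)
  expect_equal(sv$truth$realized_count,
               as.integer(round(sv$truth$true_frequency *
                                  sv$truth$coverage)))

  # at zero error rate the caller recovers every realized frequency exactly
  p <- build_pileup(sv$reads, ref)
  for (i in seq_len(nrow(sv$truth))) {
    with(sv$truth[i], expect_equal(
      frequency_at(p, pos, alt), 100 * realized_frequency))
  }

  # determinism and over-asking
  sv2 <- spike_variants(reads, ref, n_variants = 40, seed = 87)
  expect_identical(sv$truth, sv2$truth)
  expect_error(spike_variants(reads, ref, n_variants = 10000, seed = 1),
               "covered positions")
})

test_that("count simulation matches its declared design", {
  sim <- simulate_counts(seed = 88)
  expect_equal(dim(sim$counts), c(172L, 6L))
  expect_equal(sim$groups, rep(c("case", "control"), each = 3))
  expect_equal(sim$truth$log2_fold_change, log2(sim$truth$fold_change))

  sim2 <- simulate_counts(seed = 88)
  expect_identical(sim$counts, sim2$counts)

  # unit fold changes: no systematic case/control shift
  null <- simulate_counts(n_genes = 300, fold_changes = rep(1, 300),
                          dispersion = 0.02, seed = 89)
  lfc <- log2(rowMeans(null$counts[, 1:3]) / rowMeans(null$counts[, 4:6]))
  expect_lt(abs(median(lfc)), 0.1)
})

test_that("variant-detection metrics behave at the extremes", {
  truth <- data.table(
    rname = "g", pos = c(10L, 20L, 30L), ref = "C", alt = "T",
    true_frequency = c(0.5, 0.4, 0.3), coverage = 100L,
    realized_count = c(50L, 40L, 0L),
    realized_frequency = c(0.5, 0.4, 0),
    inserted = c(TRUE, TRUE, FALSE))
  perfect <- data.table(
    rname = "g", pos = c(10L, 20L), ref = "C", variant = "T",
    variant_count = c(50L, 40L), coverage = 100L,
    frequency = c(50, 40))

  ev <- evaluate_tr(perfect, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$frequency_r2, 1)

  ev0 <- evaluate_tr(perfect[0], truth)
  expect_equal(ev0$sensitivity, 0)

  # false candidates with lower scores than every true positive: AUC 1;
  # interleaved scores push it below 1
  fp <- data.table(rname = "g", pos = c(40L, 50L), ref = "C",
                   variant = "T", variant_count = c(2L, 45L),
                   coverage = 100L, frequency = c(2, 45))
  ev2 <- evaluate_tr(rbind(perfect, fp[1]), truth)
  expect_equal(ev2$auc, 1)
  ev3 <- evaluate_tr(rbind(perfect, fp), truth)
  expect_lt(ev3$auc, 1)
  expect_equal(ev3$specificity, 2 / 4)

  expect_error(evaluate_tr(perfect, truth[inserted == FALSE]),
               "empty truth")
})

test_that("an uninformative score gives a near-chance AUC", {
  # equal scores for true and false candidates: trapezoid over the single
  # diagonal segment, AUC 0.5
  truth <- data.table(rname = "g", pos = 1:50, ref = "C", alt = "T",
                      true_frequency = 0.5, coverage = 100L,
                      realized_count = 50L, realized_frequency = 0.5,
                      inserted = TRUE)
  detected <- data.table(rname = "g", pos = 1:100, ref = "C",
                         variant = "T", variant_count = 10L,
                         coverage = 100L, frequency = 10)
  ev <- evaluate_tr(detected, truth)
  expect_equal(ev$auc, 0.5)
})

test_that("fold-change evaluation reports R^2 or signals degeneracy", {
  truth <- data.table(gene = c("a", "b", "c"),
                      fold_change = c(2, 1, 0.5),
                      log2_fold_change = c(1, 0, -1),
                      baseline_mean = 100, dispersion = 0.05)
  res <- data.table(gene = c("a", "b", "c"), log2FC = c(1, 0, -1),
                    tested = TRUE)
  expect_equal(evaluate_mr(res, truth)$log2fc_r2, 1)

  const <- data.table::copy(truth)[, log2_fold_change := 1]
  expect_warning(ev <- evaluate_mr(res, const), "constant")
  expect_true(is.na(ev$log2fc_r2))

  expect_warning(ev1 <- evaluate_mr(res[1], truth), "fewer than two")
  expect_true(is.na(ev1$log2fc_r2))
})
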