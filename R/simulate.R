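#' Simulate uniform-coverage RNA-Seq reads over cDNA references
#'
#' Single-end reads with uniformly distributed start positions and
#' independent per-base substitution errors; each read aligns full-length
#' (`<len>M` CIGAR) at its true position, emulating the output of mapping
#' error-free except for the substitutions themselves. Deterministic under
#' a fixed seed.
#'
#' @param references Named character vector of reference cDNAs.
#' @param coverage Target mean coverage; the read count per reference is
#'   `round(coverage * ref_length / read_length)`.
#' @param read_length Read length in bp (default 150).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Alignment `data.table` (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`) suitable for [build_pileup()] and [write_sam()].
#' @export
simulate_reads <- function(references, coverage, read_length = 150L,
                           error_rate = 0.001, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  if (any(read_length > nchar(references))) {
    stop("read length exceeds a reference length")
  }
  withr::with_seed(seed, {
    per_ref <- lapply(names(references), function(id) {
      L <- nchar(references[[id]])
      n <- max(1L, as.integer(round(coverage * L / read_length)))
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
      seqs <- substring(references[[id]], starts, starts + read_length - 1L)
      if (error_rate > 0) {
        nerr <- stats::rbinom(1L, n * read_length, error_rate)
        if (nerr > 0L) {
          at <- sample.int(n * read_length, nerr)
          ri <- (at - 1L) %/% read_length + 1L
          off <- (at - 1L) %% read_length + 1L
          for (k in seq_len(nerr)) {
            cur <- substring(seqs[ri[k]], off[k], off[k])
            substring(seqs[ri[k]], off[k], off[k]) <-
              sample(setdiff(.BASES, cur), 1L)
          }
        }
      }
      data.table::data.table(
        qname = sprintf("%s_r%06d", id, seq_len(n)), flag = 0L, rname = id,
        pos = starts, mapq = 60L,
        cigar = paste0(read_length, "M"), seq = seqs)
    })
    data.table::rbindlist(per_ref)
  })
}

#' Spike a variant of known frequency at one position
#'
#' Targeted helper behind [spike_variants()]: rewrites the base at `pos`
#' to `alt` in a chosen subset of the reads covering it.
#'
#' @param reads Alignment table of full-match (`M`-only CIGAR) reads.
#' @param ref_id Reference id.
#' @param pos 1-based position.
#' @param alt Alternate base.
#' @param frequency Target allele fraction in `[0, 1]`.
#' @param mode `"exact"`: alter `round(frequency * coverage)` reads;
#'   `"binomial"`: alter each covering read independently with probability
#'   `frequency`.
#' @return List: modified `reads`, `coverage` (reads covering `pos`) and
#'   `realized_count` (reads actually altered).
#' @export
spike_at <- function(reads, ref_id, pos, alt, frequency,
                     mode = c("exact", "binomial")) {
  mode <- match.arg(mode)
  read_len <- nchar(reads$seq)
  idx <- which(reads$rname == ref_id & reads$pos <= pos &
                 reads$pos + read_len - 1L >= pos)
  cov <- length(idx)
  if (cov == 0L) {
    return(list(reads = reads, coverage = 0L, realized_count = 0L))
  }
  pick <- if (mode == "exact") {
    k <- as.integer(round(frequency * cov))
    if (k > 0L) sample(idx, k) else integer(0)
  } else {
    idx[stats::runif(cov) < frequency]
  }
  if (length(pick)) {
    off <- pos - reads$pos[pick] + 1L
    s <- reads$seq[pick]
    substring(s, off, off) <- alt
    reads$seq[pick] <- s
  }
  list(reads = reads, coverage = cov, realized_count = length(pick))
}

#' Spike random single-nucleotide variants into simulated alignments
#'
#' Draws variant positions without replacement from the covered coding
#' positions of the references, assigns each a frequency uniform on
#' `[freq_min, freq_max]` and a random alternate base, and rewrites reads
#' accordingly. In exact-count mode `round(f * coverage)` covering reads
#' are altered, so the realized fraction is known exactly; a variant whose
#' realized count is 0 (low coverage times low frequency) is recorded as
#' not inserted — requesting n variants can therefore yield fewer
#' successful insertions. Deterministic under a fixed seed.
#'
#' @param reads Alignment table from [simulate_reads()].
#' @param references Named character vector of reference CDSs.
#' @param n_variants Number of variants to attempt.
#' @param freq_min,freq_max Bounds of the uniform frequency distribution
#'   (defaults 0.05 and 0.95).
#' @param mode `"exact"` (default, deterministic realized counts) or
#'   `"binomial"`.
#' @param seed Integer seed.
#' @return List: `reads` (modified) and `truth`, a `data.table` with
#'   `rname`, `pos`, `ref`, `alt`, `true_frequency` (drawn), `coverage`,
#'   `realized_count`, `realized_frequency` and `inserted`.
#' @export
spike_variants <- function(reads, references, n_variants,
                           freq_min = 0.05, freq_max = 0.95,
                           mode = c("exact", "binomial"), seed = 1L) {
  mode <- match.arg(mode)
  read_len <- nchar(reads$seq[1L])
  covered <- data.table::rbindlist(lapply(names(references), function(id) {
    r <- reads[reads$rname == id]
    if (nrow(r) == 0L) return(NULL)
    lo <- min(r$pos)
    hi <- max(r$pos + read_len - 1L)
    data.table::data.table(rname = id, pos = seq.int(lo, hi))
  }))
  if (n_variants > nrow(covered)) {
    stop("requested ", n_variants, " variants but only ", nrow(covered),
         " covered positions are available")
  }
  withr::with_seed(seed, {
    sel <- covered[sample.int(nrow(covered), n_variants)]
    data.table::setorderv(sel, c("rname", "pos"))
    freqs <- stats::runif(n_variants, freq_min, freq_max)
    refbase <- substring(references[sel$rname], sel$pos, sel$pos)
    altbase <- vapply(refbase, function(b) sample(setdiff(.BASES, b), 1L),
                      character(1L), USE.NAMES = FALSE)
    cov <- integer(n_variants)
    realized <- integer(n_variants)
    for (i in seq_len(n_variants)) {
      sp <- spike_at(reads, sel$rname[i], sel$pos[i], altbase[i], freqs[i],
                     mode)
      reads <- sp$reads
      cov[i] <- sp$coverage
      realized[i] <- sp$realized_count
    }
    truth <- data.table::data.table(
      rname = sel$rname, pos = sel$pos, ref = refbase, alt = altbase,
      true_frequency = freqs, coverage = cov, realized_count = realized,
      realized_frequency = ifelse(cov > 0L, realized / cov, NA_real_),
      inserted = realized > 0L)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a negative-binomial count matrix at set fold changes
#'
#' Two groups (case/control) with a shared per-gene baseline mean; case
#' means are baseline times the true fold change. Counts are drawn NB with
#' the given dispersion (Poisson when dispersion is 0), scaled per sample
#' by library-size factors. Deterministic under a fixed seed.
#'
#' @param n_genes Number of genes (default 172).
#' @param fold_changes True case/control fold changes; default
#'   `2^U[-3, 3]`, redrawn each call from the seed.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.05.
#' @param reps_per_group Replicates per group (default 3).
#' @param lib_sizes Per-sample library-size factors, recycled over the
#'   `2 * reps_per_group` samples (default 1).
#' @param baseline_means Per-gene control-group means; default log-normal
#'   around a few hundred counts.
#' @param seed Integer seed.
#' @return List: `counts` (matrix genes x samples, case columns first),
#'   `groups` (column labels) and `truth` (`gene`, `fold_change`,
#'   `log2_fold_change`, `baseline_mean`, `dispersion`).
#' @export
simulate_counts <- function(n_genes = 172L, fold_changes = NULL,
                            dispersion = 0.05, reps_per_group = 3L,
                            lib_sizes = 1, baseline_means = NULL,
                            seed = 1L) {
  if (n_genes < 1L || reps_per_group < 1L || dispersion < 0 ||
      any(lib_sizes <= 0)) {
    stop("all simulation parameters must be positive")
  }
  n_samples <- 2L * reps_per_group
  lib <- rep_len(lib_sizes, n_samples)
  withr::with_seed(seed, {
    if (is.null(fold_changes)) {
      fold_changes <- 2^stats::runif(n_genes, -3, 3)
    }
    if (any(fold_changes <= 0)) stop("fold changes must be positive")
    if (is.null(baseline_means)) {
      baseline_means <- exp(stats::rnorm(n_genes, log(300), 0.7))
    }
    groups <- rep(c("case", "control"), each = reps_per_group)
    mu <- outer(baseline_means, lib)
    mu[, groups == "case"] <- mu[, groups == "case"] * fold_changes
    draw <- function(m) {
      if (dispersion == 0) stats::rpois(length(m), m)
      else stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
    }
    counts <- matrix(draw(mu), n_genes, n_samples)
    rownames(counts) <- sprintf("gene%03d", seq_len(n_genes))
    colnames(counts) <- paste0(groups, rep(seq_len(reps_per_group), 2L))
    truth <- data.table::data.table(
      gene = rownames(counts), fold_change = fold_changes,
      log2_fold_change = log2(fold_changes),
      baseline_mean = baseline_means, dispersion = dispersion)
    list(counts = counts, groups = groups, truth = truth)
  })
}

#' Evaluate variant detection against spike-in truth
#'
#' Sensitivity is the fraction of successfully inserted variants that were
#' detected; "specificity" follows the precision-style definition used for
#' this validation design — detected inserted variants over all detected
#' variants — and is reported under that name with the precision alias
#' alongside. The ROC sweeps a variant-read-count threshold over all
#' detected candidates (score = alternate-base read count), and the AUC is
#' the trapezoidal area. Frequency accuracy is the squared Pearson
#' correlation between detected and realized frequencies over true
#' positives.
#'
#' @param detected SNP calls ([call_snps()] output, possibly row-bound over
#'   references).
#' @param truth Spike-in truth from [spike_variants()].
#' @return List: `sensitivity`, `specificity` (precision, as defined
#'   above), `precision` (alias), `auc`, `roc` (`threshold`, `tpr`, `fpr`),
#'   `frequency_r2`, `n_inserted`, `n_detected`, `n_true_positive`.
#' @export
evaluate_tr <- function(detected, truth) {
  inserted <- truth[truth$inserted == TRUE]
  if (nrow(inserted) == 0L) {
    stop("empty truth set: no successfully inserted variants")
  }
  key <- function(d) paste(d$rname, d$pos, sep = ":")
  vkey <- function(d, alt) paste(d$rname, d$pos, alt, sep = ":")
  hit <- vkey(detected, detected$variant) %in% vkey(inserted, inserted$alt)
  n_tp <- sum(hit)
  sens <- n_tp / nrow(inserted)
  spec <- if (nrow(detected) > 0L) n_tp / nrow(detected) else NA_real_

  # ROC over detected candidates, scored by alternate-base read count
  roc <- NULL
  auc <- NA_real_
  if (nrow(detected) > 0L && n_tp > 0L && any(!hit)) {
    score <- detected$variant_count
    thr <- sort(unique(score))
    tpr <- vapply(thr, function(t) sum(hit & score >= t), 0) / nrow(inserted)
    fpr <- vapply(thr, function(t) sum(!hit & score >= t), 0) / sum(!hit)
    roc <- data.table::data.table(threshold = c(thr, Inf),
                                  tpr = c(tpr, 0), fpr = c(fpr, 0))
    data.table::setorderv(roc, "fpr")
    xs <- c(roc$fpr, 1)
    ys <- c(roc$tpr, max(roc$tpr))
    o <- order(xs, ys)
    auc <- sum(diff(xs[o]) * (utils::head(ys[o], -1) + ys[o][-1]) / 2)
  } else if (nrow(detected) > 0L && n_tp > 0L) {
    auc <- 1 # no false candidates at any threshold
  }

  r2 <- NA_real_
  tp <- detected[hit]
  if (nrow(tp) >= 2L) {
    m <- merge(tp, inserted, by.x = c("rname", "pos", "variant"),
               by.y = c("rname", "pos", "alt"))
    if (nrow(m) >= 2L && stats::var(m$realized_frequency) > 0) {
      r2 <- stats::cor(m$frequency / 100, m$realized_frequency)^2
    }
  }
  list(sensitivity = sens, specificity = spec, precision = spec, auc = auc,
       roc = roc, frequency_r2 = r2, n_inserted = nrow(inserted),
       n_detected = nrow(detected), n_true_positive = n_tp)
}

#' Evaluate fold-change estimation against count-simulation truth
#'
#' Coefficient of determination (squared Pearson correlation) between
#' estimated and true log2 fold changes over tested genes.
#'
#' @param results [nb_wald_test()] output.
#' @param truth `truth` component of [simulate_counts()].
#' @return List: `log2fc_r2`, `n_genes` (tested genes entering the
#'   correlation). `log2fc_r2` is `NA` (with a warning) when fewer than two
#'   genes are tested or the truth is constant.
#' @export
evaluate_mr <- function(results, truth) {
  m <- merge(results[results$tested == TRUE], truth, by = "gene")
  if (nrow(m) < 2L) {
    warning("fewer than two tested genes; R^2 undefined")
    return(list(log2fc_r2 = NA_real_, n_genes = nrow(m)))
  }
  if (stats::var(m$log2_fold_change) == 0) {
    warning("true fold changes are constant; R^2 undefined")
    return(list(log2fc_r2 = NA_real_, n_genes = nrow(m)))
  }
  list(log2fc_r2 = stats::cor(m$log2FC, m$log2_fold_change)^2,
       n_genes = nrow(m))
}
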