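#' Count primary-mapped reads per gene for one sample
#'
#' Each primary mapped record adds 1 to its reference gene; secondary and
#' supplementary alignments are excluded so a multi-mapped read is counted
#' once, at its primary alignment. An optional fractional mode instead
#' splits 1/k over the k reported alignments of each query.
#'
#' @param reads Alignment table from [parse_sam()] (unmapped records are
#'   already dropped there).
#' @param gene_ids Character vector of detoxification gene ids (the
#'   reference set); reads aligned elsewhere are skipped with a message.
#' @param fractional If `TRUE`, count 1/k per reported alignment of a
#'   query with k alignments (counts are then non-integer).
#' @return Named numeric vector over `gene_ids` (zeros included).
#' @export
count_reads <- function(reads, gene_ids, fractional = FALSE) {
  known <- reads$rname %chin% gene_ids
  if (any(!known)) {
    message(sum(!known), " record(s) aligned to ids outside the gene set ",
            "were skipped")
    reads <- reads[known]
  }
  out <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  if (nrow(reads) == 0L) return(out)
  if (fractional) {
    k <- table(reads$qname)
    w <- 1 / as.numeric(k[reads$qname])
    tab <- tapply(w, reads$rname, sum)
  } else {
    primary <- reads[bitwAnd(reads$flag, 0x900L) == 0L]
    tab <- table(primary$rname)
  }
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: for each sample, the median over genes of
#' the ratio of its count to the gene's geometric mean across samples,
#' taken over genes whose geometric mean is positive (no zero in any
#' sample) and whose count in that sample is positive.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  loggeo <- rowMeans(log(counts))
  if (!any(is.finite(loggeo))) {
    stop("no gene has a nonzero count in every sample; ",
         "size factors are undefined")
  }
  apply(counts, 2L, function(cnts) {
    exp(stats::median((log(cnts) - loggeo)[is.finite(loggeo) & cnts > 0]))
  })
}

#' Negative-binomial Wald test for case/control differential expression
#'
#' Counts are normalized by [size_factors()]; per-gene group means are
#' compared on the log2 scale. The gene-wise dispersion is estimated by
#' method of moments on normalized counts (within-group variance pooled
#' across groups), floored at `1e-8`. The standard error of the log2 fold
#' change follows from the NB variance of each group mean by the delta
#' method, giving a two-sided normal (Wald) p-value and a 95% CI of
#' `log2FC +/- 1.96 SE`. When either group mean is zero, a continuity
#' adjustment of 0.5 normalized counts is added to both means in the
#' fold-change and SE computation only — never in dispersion estimation.
#' Genes with zero counts in all samples are reported untested.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param groups Character/factor vector over samples with values
#'   `"case"` and `"control"`. The fold change is case over control.
#' @return `data.table` with one row per gene: `gene`, `base_mean`,
#'   `case_mean`, `control_mean`, `dispersion`, `FC`, `log2FC`, `SE`,
#'   `CI95_low`, `CI95_high`, `pvalue`, `padj`
#'   (Benjamini-Hochberg over tested genes) and `tested`.
#' @export
nb_wald_test <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must label every sample (column)")
  }
  if (!all(groups %in% c("case", "control"))) {
    stop('groups must be "case" or "control"')
  }
  nA <- sum(groups == "case")
  nB <- sum(groups == "control")
  if (nA < 1L || nB < 1L) stop("both groups need at least one sample")
  if (nA < 2L || nB < 2L) {
    warning("a group has a single sample: dispersion cannot be estimated; ",
            "falling back to the Poisson (dispersion floor) variance")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  A <- norm[, groups == "case", drop = FALSE]
  B <- norm[, groups == "control", drop = FALSE]
  muA <- rowMeans(A)
  muB <- rowMeans(B)
  tested <- (muA + muB) > 0

  rowvar <- function(m) {
    if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
  }
  vA <- rowvar(A)
  vB <- rowvar(B)
  wvar <- if (nA >= 2L && nB >= 2L) {
    ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
  } else if (nA >= 2L) vA else if (nB >= 2L) vB else rep(NA_real_, nrow(norm))
  mbar <- (muA + muB) / 2
  disp <- rep(1e-8, nrow(norm))
  hasvar <- is.finite(wvar) & mbar > 0
  disp[hasvar] <- pmax((wvar[hasvar] - mbar[hasvar]) / mbar[hasvar]^2, 1e-8)

  zero <- (muA == 0 | muB == 0) & tested
  muA2 <- muA + 0.5 * zero
  muB2 <- muB + 0.5 * zero
  log2fc <- log2(muA2 / muB2)
  se <- sqrt((1 / muA2 + disp) / nA + (1 / muB2 + disp) / nB) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  out <- data.table::data.table(
    gene = rownames(counts),
    base_mean = rowMeans(norm),
    case_mean = muA, control_mean = muB, dispersion = disp,
    FC = 2^log2fc, log2FC = log2fc, SE = se,
    CI95_low = log2fc - 1.96 * se, CI95_high = log2fc + 1.96 * se,
    pvalue = p, tested = tested)
  out[!tested, c("dispersion", "FC", "log2FC", "SE", "CI95_low", "CI95_high",
                 "pvalue") := NA_real_]
  out[, `:=`(padj = {
    padj <- rep(NA_real_, .N)
    padj[out$tested] <- stats::p.adjust(out$pvalue[out$tested], "BH")
    padj
  })]
  out[]
}

#' Filter overexpressed genes
#'
#' Retains genes overexpressed in the case group beyond a log2 fold-change
#' threshold at a raw p-value cutoff (the published criterion; adjusted
#' p-values are available in the results for stricter use). Setting
#' `two_sided = TRUE` filters on `|log2FC|` instead, keeping strong
#' underexpression too.
#'
#' @param results Output of [nb_wald_test()].
#' @param lfc_threshold log2 fold-change threshold (default 1, i.e.
#'   twofold).
#' @param p_threshold Raw p-value cutoff (default 0.01).
#' @param two_sided Filter on absolute log2 fold change.
#' @return Subset of `results`, ordered by decreasing `log2FC`.
#' @export
filter_overexpressed <- function(results, lfc_threshold = 1,
                                 p_threshold = 0.01, two_sided = FALSE) {
  lfc <- if (two_sided) abs(results$log2FC) else results$log2FC
  keep <- results$tested & !is.na(lfc) & lfc > lfc_threshold &
    results$pvalue < p_threshold
  out <- results[keep]
  data.table::setorderv(out, "log2FC", order = -1L)
  out[]
}

#' Genes overexpressed in every comparison
#'
#' @param gene_sets List (length >= 2) of character vectors or
#'   [filter_overexpressed()] results.
#' @return Character vector of gene ids common to all sets.
#' @export
intersect_comparisons <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2L)
  ids <- lapply(gene_sets, function(g) {
    if (is.data.frame(g)) g$gene else as.character(g)
  })
  Reduce(intersect, ids)
}
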