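library(data.table)

# minimal aligned-read row(s); all-match CIGAR unless given
make_reads <- function(pos, seq, rname = "g", flag = 0L, cigar = NULL,
                       qname = NULL) {
  n <- max(length(pos), length(seq))
  data.table(
    qname = if (is.null(qname)) sprintf("r%d", seq_len(n)) else qname,
    flag = rep_len(as.integer(flag), n),
    rname = rep_len(rname, n),
    pos = rep_len(as.integer(pos), n),
    mapq = 60L,
    cigar = if (is.null(cigar)) paste0(nchar(rep_len(seq, n)), "M") else
      rep_len(cigar, n),
    seq = rep_len(seq, n))
}

# naive per-position recount: loops every read and every base, the slow way
brute_pileup <- function(reads, reference) {
  ref_id <- names(reference)
  counts <- matrix(0L, nchar(reference[[1]]), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i]
    if (r$rname != ref_id || bitwAnd(r$flag, 0x904L) != 0L) next
    for (k in seq_len(nchar(r$seq))) {
      b <- substring(r$seq, k, k)
      p <- r$pos + k - 1L
      if (b %in% c("A", "C", "G", "T") && p <= nrow(counts)) {
        counts[p, b] <- counts[p, b] + 1L
      }
    }
  }
  counts
}

# naive SNP caller over the brute-force counts
brute_snps <- function(reads, reference, min_coverage = 30L) {
  counts <- brute_pileup(reads, reference)
  out <- list()
  for (p in seq_len(nrow(counts))) {
    cov <- sum(counts[p, ])
    if (cov < min_coverage || sum(counts[p, ] > 0L) < 2L) next
    refb <- substring(reference[[1]], p, p)
    nonref <- setdiff(c("A", "C", "G", "T"), refb)
    vb <- nonref[which.max(counts[p, nonref])]
    out[[length(out) + 1L]] <- data.table(
      pos = p, ref = refb, variant = vb,
      variant_count = counts[p, vb], coverage = cov,
      frequency = 100 * counts[p, vb] / cov)
  }
  rbindlist(out)
}

# a pileup container built directly from counts (for worked examples where
# only the column totals matter)
make_pileup <- function(pos, A = 0L, C = 0L, G = 0L, T = 0L, rname = "g") {
  dt <- data.table(rname = rname, pos = as.integer(pos),
                   A = as.integer(A), C = as.integer(C),
                   G = as.integer(G), T = as.integer(T))
  dt[, coverage := A + C + G + T]
  setkeyv(dt, "pos")
  setattr(dt, "ref_id", rname)
  dt
}

tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fa")
  writeLines(text, f)
  f
}

tmp_sam <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  f
}

# random sense-codon CDS for property tests
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    b <- c("T", "C", "A", "G")
    all <- as.vector(outer(outer(b, b, paste0), b, paste0))
    sense <- setdiff(all, c("TAA", "TAG", "TGA"))
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}
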