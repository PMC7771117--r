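#' Map a cDNA position to its codon's residue index
#'
#' The reference cDNA is assumed to be a coding sequence in frame from base
#' 1, so nucleotide position `p` (1-based) falls in codon
#' `floor((p - 1) / 3) + 1`.
#'
#' @param position 1-based cDNA position(s).
#' @return Integer residue indices.
#' @seealso [codon_offset()]
#' @export
position_to_residue <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) {
    stop("positions must be integers >= 1")
  }
  (position - 1L) %/% 3L + 1L
}

#' @describeIn position_to_residue 0-based offset of the position within its
#'   codon (0, 1 or 2).
#' @export
codon_offset <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) {
    stop("positions must be integers >= 1")
  }
  (position - 1L) %% 3L
}

#' Variant allele frequency at a position
#'
#' Frequency (in percent) of a given base among counted reads at one pileup
#' position. Returns 0 when the position is covered but the base is absent,
#' and `NA` when the position has no coverage at all, so "not observed" and
#' "not observable" stay distinct.
#'
#' @param pileup Pileup from [build_pileup()].
#' @param position 1-based position.
#' @param base Variant base, one of `"A","C","G","T"`.
#' @return Percentage in `[0, 100]`, or `NA_real_` for zero coverage.
#' @export
frequency_at <- function(pileup, position, base) {
  stopifnot(base %in% .BASES)
  row <- pileup[pileup$pos == position]
  if (nrow(row) == 0L || row$coverage == 0L) return(NA_real_)
  100 * row[[base]] / row$coverage
}

#' Call SNPs from a pileup
#'
#' A position is called when its counted coverage reaches `min_coverage`
#' and at least two distinct bases are observed. The variant is the most
#' frequent non-reference base (alphabetical tie-break); any further
#' non-reference bases are summarised in `other_bases`. Positions whose
#' reference base is `N` are skipped with a warning.
#'
#' @param pileup Pileup from [build_pileup()].
#' @param reference Length-1 named character vector: the reference the
#'   pileup was built over.
#' @param min_coverage Minimum counted coverage (default 30).
#' @return `data.table` with columns `rname`, `pos`, `ref`, `variant`,
#'   `variant_count`, `coverage`, `frequency` (percent, exact — rounding
#'   happens at report time) and `other_bases`.
#' @export
call_snps <- function(pileup, reference, min_coverage = 30L) {
  empty <- data.table::data.table(
    rname = character(), pos = integer(), ref = character(),
    variant = character(), variant_count = integer(), coverage = integer(),
    frequency = numeric(), other_bases = character())
  p <- pileup[pileup$coverage >= min_coverage]
  if (nrow(p) == 0L) return(empty)
  m <- as.matrix(p[, .BASES, with = FALSE])
  p <- p[rowSums(m > 0L) >= 2L]
  if (nrow(p) == 0L) return(empty)
  m <- as.matrix(p[, .BASES, with = FALSE])
  refbase <- substring(reference[[1L]], p$pos, p$pos)
  isN <- refbase == "N"
  if (any(isN)) {
    warning(sum(isN), " candidate position(s) skipped: reference base N")
    p <- p[!isN]
    m <- m[!isN, , drop = FALSE]
    refbase <- refbase[!isN]
  }
  if (nrow(p) == 0L) return(empty)
  masked <- m
  masked[cbind(seq_len(nrow(m)), match(refbase, .BASES))] <- -1L
  vi <- max.col(masked, ties.method = "first")
  variant <- .BASES[vi]
  vcount <- m[cbind(seq_len(nrow(m)), vi)]
  other <- vapply(seq_len(nrow(m)), function(i) {
    o <- setdiff(which(m[i, ] > 0L), c(vi[i], match(refbase[i], .BASES)))
    if (length(o) == 0L) "" else
      paste(sprintf("%s:%d", .BASES[o], m[i, o]), collapse = ",")
  }, character(1L))
  data.table::data.table(
    rname = p$rname, pos = p$pos, ref = refbase, variant = variant,
    variant_count = as.integer(vcount), coverage = p$coverage,
    frequency = 100 * vcount / p$coverage, other_bases = other)
}

#' Differential-SNP test applied to a pair of frequencies
#'
#' The decision rule of the case/control comparison: an absolute
#' case-minus-control allele-frequency difference of at least
#' `delta` percentage points (in either direction).
#'
#' @param case_freq,control_freq Allele frequencies in percent.
#' @param delta Threshold in percentage points (default 40).
#' @return Logical vector.
#' @export
is_differential <- function(case_freq, control_freq, delta = 40) {
  abs(case_freq - control_freq) >= delta
}

#' Identify differential SNPs between case and control pileups
#'
#' Candidate (position, variant) pairs are SNP calls in either sample.
#' Pairs where both samples reach `min_coverage` are comparable; of those,
#' pairs whose allele-frequency difference is at least `delta_threshold`
#' percentage points (either direction) are differential. Candidates where
#' the other sample lacks coverage are not dropped silently: they are
#' returned in the `incomparable` component.
#'
#' @param case_pileup,control_pileup Pileups over the same reference
#'   (resistant = case, susceptible = control).
#' @param reference Length-1 named character vector.
#' @param min_coverage Minimum coverage in each sample (default 30).
#' @param delta_threshold Frequency-difference threshold in percentage
#'   points (default 40).
#' @return List with `differential` and `incomparable` `data.table`s; both
#'   carry case/control counts, coverages and frequencies, the signed
#'   difference `diff` (case - control) and `delta = |diff|`.
#' @export
differential_snps <- function(case_pileup, control_pileup, reference,
                              min_coverage = 30L, delta_threshold = 40) {
  cs <- call_snps(case_pileup, reference, min_coverage)
  ks <- call_snps(control_pileup, reference, min_coverage)
  cand <- unique(data.table::rbindlist(list(
    cs[, c("pos", "ref", "variant")], ks[, c("pos", "ref", "variant")])))
  empty <- data.table::data.table(
    rname = character(), pos = integer(), ref = character(),
    variant = character(), case_count = integer(), case_coverage = integer(),
    case_frequency = numeric(), control_count = integer(),
    control_coverage = integer(), control_frequency = numeric(),
    diff = numeric(), delta = numeric())
  if (nrow(cand) == 0L) {
    return(list(differential = empty, incomparable = empty))
  }
  data.table::setorderv(cand, c("pos", "variant"))
  at <- function(pileup, pos, base) {
    i <- match(pos, pileup$pos)
    cnt <- ifelse(is.na(i), 0L,
                  as.matrix(pileup[, .BASES, with = FALSE])[
                    cbind(i, match(base, .BASES))])
    cov <- ifelse(is.na(i), 0L, pileup$coverage[i])
    list(count = as.integer(cnt), coverage = as.integer(cov))
  }
  ca <- at(case_pileup, cand$pos, cand$variant)
  co <- at(control_pileup, cand$pos, cand$variant)
  out <- data.table::data.table(
    rname = names(reference), pos = cand$pos, ref = cand$ref,
    variant = cand$variant,
    case_count = ca$count, case_coverage = ca$coverage,
    case_frequency = ifelse(ca$coverage > 0L, 100 * ca$count / ca$coverage,
                            NA_real_),
    control_count = co$count, control_coverage = co$coverage,
    control_frequency = ifelse(co$coverage > 0L,
                               100 * co$count / co$coverage, NA_real_))
  out[, `:=`(diff = out$case_frequency - out$control_frequency)]
  out[, `:=`(delta = abs(out$diff))]
  comparable <- out$case_coverage >= min_coverage &
    out$control_coverage >= min_coverage
  list(
    differential = out[comparable &
                         is_differential(out$case_frequency,
                                         out$control_frequency,
                                         delta_threshold)],
    incomparable = out[!comparable])
}

#' Translate a single-nucleotide variant into an amino-acid substitution
#'
#' The alternate codon is the reference codon with the variant base
#' substituted at its offset; the other two bases are taken from the
#' reference (co-codon variants are translated independently). Standard
#' genetic code. Substitutions to a stop codon are retained and flagged
#' `nonsense`; synonymous changes carry an `NA` label.
#'
#' @param reference Length-1 named character vector, a CDS in frame from
#'   base 1.
#' @param position 1-based variant position.
#' @param variant_base Variant base.
#' @return One-row `data.table`: `pos`, `residue`, `offset`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`, `nonsense`, `label`.
#' @export
translate_variant <- function(reference, position, variant_base) {
  seq <- reference[[1L]]
  if (position > nchar(seq)) {
    stop("position ", position, " beyond reference length ", nchar(seq))
  }
  res <- position_to_residue(position)
  off <- codon_offset(position)
  p1 <- 3L * (res - 1L) + 1L
  ref_codon <- substring(seq, p1, p1 + 2L)
  if (nchar(ref_codon) < 3L) {
    stop("position ", position, " falls in an incomplete terminal codon")
  }
  if (grepl("N", ref_codon, fixed = TRUE)) {
    warning("codon at residue ", res, " contains N; call skipped")
    return(data.table::data.table(
      pos = position, residue = res, offset = off, ref_codon = ref_codon,
      alt_codon = NA_character_, ref_aa = NA_character_,
      alt_aa = NA_character_, synonymous = NA, nonsense = NA,
      label = NA_character_))
  }
  alt_codon <- ref_codon
  substring(alt_codon, off + 1L, off + 1L) <- variant_base
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  syn <- ref_aa == alt_aa
  data.table::data.table(
    pos = position, residue = res, offset = off, ref_codon = ref_codon,
    alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
    synonymous = syn, nonsense = alt_aa == "*",
    label = ifelse(syn, NA_character_, paste0(ref_aa, res, alt_aa)))
}

#' Targeted scan for published mutations (no control sample needed)
#'
#' For each catalog entry on the reference's target, locates the codon
#' whose canonical residue matches (through a numbering map when the query
#' species differs from the canonical one), enumerates the single-base
#' changes of the reference codon that realize the published amino-acid
#' substitution, and reports the variant-base frequency of the best
#' supported one — even when far below the differential threshold, since
#' the scan is a surveillance readout, not a discovery filter.
#'
#' @param pileup Pileup over `reference`.
#' @param reference Length-1 named character vector (CDS).
#' @param catalog Catalog entries for this reference's target.
#' @param numbering Optional `numbering_map` from the reference's protein
#'   (query) to the canonical protein; `NULL` means the reference already
#'   uses canonical numbering.
#' @param min_coverage Coverage below which `status` is `"low_coverage"`
#'   (default 30). Frequencies are still reported when computable.
#' @return `data.table`, one row per catalog entry: `label`, `target`,
#'   `canonical_residue`, `species_residue`, `pos` (of the scanned base),
#'   `ref_codon`, `variant`, `variant_count`, `coverage`, `frequency`
#'   (percent; `NA` when coverage is 0) and `status` (`"ok"`,
#'   `"low_coverage"`, `"not_mappable"`, `"ref_mismatch"`).
#' @export
scan_known <- function(pileup, reference, catalog, numbering = NULL,
                       min_coverage = 30L) {
  seq <- reference[[1L]]
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    e <- catalog[i]
    base_row <- data.table::data.table(
      label = e$label, target = e$target, canonical_residue = e$residue,
      species_residue = NA_integer_, pos = NA_integer_,
      ref_codon = NA_character_, variant = NA_character_,
      variant_count = NA_integer_, coverage = NA_integer_,
      frequency = NA_real_, status = "not_mappable")
    sres <- if (is.null(numbering)) e$residue else
      canonical_to_query(numbering, e$residue)
    if (is.na(sres) || 3L * sres > nchar(seq)) return(base_row)
    p1 <- 3L * (sres - 1L) + 1L
    ref_codon <- substring(seq, p1, p1 + 2L)
    base_row[, `:=`(species_residue = sres, ref_codon = ref_codon)]
    if (unname(Biostrings::GENETIC_CODE[ref_codon]) != e$ref_aa) {
      base_row[, `:=`(status = "ref_mismatch")]
      return(base_row)
    }
    # single-base edits of the codon realizing the published substitution
    cands <- list()
    for (off in 0:2) {
      for (b in setdiff(.BASES, substring(ref_codon, off + 1L, off + 1L))) {
        alt <- ref_codon
        substring(alt, off + 1L, off + 1L) <- b
        if (unname(Biostrings::GENETIC_CODE[alt]) == e$alt_aa) {
          cands[[length(cands) + 1L]] <- list(pos = p1 + off, base = b)
        }
      }
    }
    if (length(cands) == 0L) {
      base_row[, `:=`(status = "ref_mismatch")]
      return(base_row)
    }
    best <- NULL
    for (cd in cands) {
      i <- match(cd$pos, pileup$pos)
      cnt <- if (is.na(i)) 0L else pileup[[cd$base]][i]
      cov <- if (is.na(i)) 0L else pileup$coverage[i]
      if (is.null(best) || cnt > best$cnt) {
        best <- list(pos = cd$pos, base = cd$base, cnt = cnt, cov = cov)
      }
    }
    base_row[, `:=`(
      pos = best$pos, variant = best$base,
      variant_count = as.integer(best$cnt), coverage = as.integer(best$cov),
      frequency = if (best$cov > 0L) 100 * best$cnt / best$cov else NA_real_,
      status = if (best$cov >= min_coverage) "ok" else "low_coverage")]
    base_row
  })
  data.table::rbindlist(rows)
}

#' Aggregate per-replicate mutation scans
#'
#' Arithmetic mean of replicate frequencies per mutation label, with the
#' per-replicate values retained. Frequencies are kept exact; rounding is a
#' report-time concern.
#'
#' @param scans List of [scan_known()] results (one per replicate),
#'   optionally named.
#' @return List with `per_replicate` (row-bound scans with a `replicate`
#'   column) and `summary` (`label`, `n_replicates`, `mean_frequency`).
#' @export
aggregate_replicates <- function(scans) {
  stopifnot(length(scans) >= 1L)
  if (is.null(names(scans))) {
    names(scans) <- paste0("rep", seq_along(scans))
  }
  per <- data.table::rbindlist(scans, idcol = "replicate")
  frequency <- NULL # data.table NSE
  summary <- per[, list(n_replicates = .N,
                        mean_frequency = mean(frequency)), by = "label"]
  list(per_replicate = per, summary = summary)
}

#' Per-position base-frequency matrix
#'
#' Relative base frequencies at selected positions, e.g. for sequence-logo
#' rendering of allele distributions at mutation sites. Rows at covered
#' positions sum to 1; uncovered positions are flagged and filled with
#' `NA`.
#'
#' @param pileup Pileup from [build_pileup()].
#' @param positions 1-based positions.
#' @return `data.table` with `pos`, fractional `A`, `C`, `G`, `T`, and
#'   `covered`.
#' @export
base_frequency_matrix <- function(pileup, positions) {
  i <- match(positions, pileup$pos)
  cov <- ifelse(is.na(i), 0L, pileup$coverage[i])
  out <- data.table::data.table(pos = as.integer(positions))
  for (b in .BASES) {
    out[, (b) := ifelse(cov > 0L, pileup[[b]][i] / cov, NA_real_)]
  }
  out[, `:=`(covered = cov > 0L)]
  out[]
}
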