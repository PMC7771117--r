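#' Read cDNA reference sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Position indexing
#' throughout the package is 1-based over the cDNA.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of nucleotide sequences (alphabet
#'   `A,C,G,T,N`), names taken from the first word of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide alphabet in FASTA record: ", ids[which(bad)[1L]])
  }
  names(seqs) <- ids
  seqs
}

#' Write reference sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a SAM alignment file
#'
#' Reads the mandatory fields of a SAM text file (with or without header).
#' Unmapped records (FLAG 0x4) are dropped. If `references` is supplied,
#' records aligned to reference ids not present in it are dropped and their
#' count reported via [message()].
#'
#' @param path Path to a SAM file.
#' @param references Optional named character vector of reference sequences
#'   (as from [read_fasta()]) used to filter records by reference id.
#' @return A [data.table::data.table] with columns `qname`, `flag`, `rname`,
#'   `pos` (1-based leftmost), `mapq`, `cigar`, `seq`.
#' @export
parse_sam <- function(path, references = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "@")
  lineno <- which(body)
  lines <- lines[body]
  empty <- data.table::data.table(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(), seq = character()
  )
  if (length(lines) == 0L) {
    warning("no alignment records in ", path)
    return(empty)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11L
  if (any(short)) {
    stop("malformed SAM record (fewer than 11 fields) at line ",
         lineno[which(short)[1L]], " of ", path)
  }
  fld <- function(i) vapply(f, `[[`, character(1L), i)
  flag <- suppressWarnings(as.integer(fld(2L)))
  pos <- suppressWarnings(as.integer(fld(4L)))
  mapq <- suppressWarnings(as.integer(fld(5L)))
  bad <- is.na(flag) | is.na(pos)
  if (any(bad)) {
    stop("malformed SAM mandatory field (FLAG/POS) at line ",
         lineno[which(bad)[1L]], " of ", path)
  }
  dt <- data.table::data.table(
    qname = fld(1L), flag = flag, rname = fld(3L), pos = pos,
    mapq = mapq, cigar = fld(6L), seq = toupper(fld(10L))
  )
  dt <- dt[bitwAnd(flag, 4L) == 0L]
  if (nrow(dt) && any(dt$pos < 1L)) {
    stop("mapped SAM record with POS < 1 in ", path)
  }
  if (!is.null(references)) {
    known <- dt$rname %chin% names(references)
    if (any(!known)) {
      message(sum(!known), " record(s) aligned to references absent from the ",
              "loaded set were skipped")
      dt <- dt[known]
    }
  }
  if (nrow(dt) == 0L) warning("no usable alignment records in ", path)
  dt[]
}

#' Write alignments to a SAM file
#'
#' Emits a minimal valid SAM with `@HD`/`@SQ` header lines for the given
#' references.
#'
#' @param reads Alignment table as returned by [parse_sam()] or
#'   [simulate_reads()].
#' @param references Named character vector of reference sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, references, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(references), nchar(references))
  )
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  if (is.null(reads$mapq)) 60L else reads$mapq,
                  reads$cigar, reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.BASES <- c("A", "C", "G", "T")

#' Build a per-position base-count pileup over one reference
#'
#' Projects reads onto the reference with full CIGAR awareness: `M`, `=` and
#' `X` operations consume query and reference and contribute base counts;
#' `I` and `S` consume query only; `D` and `N` consume reference only and
#' contribute neither counts nor coverage. `N` bases in reads are not
#' counted. Secondary and supplementary alignments (FLAG 0x100/0x800) are
#' excluded so each sequenced read contributes at most once.
#'
#' @param reads Alignment table (see [parse_sam()]).
#' @param reference Length-1 named character vector: the reference sequence
#'   the pileup is built over.
#' @return A `data.table` with one row per covered position: `rname`, `pos`,
#'   counts `A`, `C`, `G`, `T` and `coverage` (= their sum). Reads whose
#'   CIGAR query length disagrees with the sequence length, or whose
#'   projection extends past the reference end, are skipped; the skip count
#'   is available as `attr(x, "skipped_reads")`.
#' @export
build_pileup <- function(reads, reference) {
  stopifnot(length(reference) == 1L, !is.null(names(reference)))
  ref_id <- names(reference)
  ref_len <- nchar(reference[[1L]])
  empty <- data.table::data.table(
    rname = character(), pos = integer(), A = integer(), C = integer(),
    G = integer(), T = integer(), coverage = integer()
  )
  r <- reads[reads$rname == ref_id & bitwAnd(reads$flag, 0x900L) == 0L]
  skipped <- 0L
  if (nrow(r) == 0L) {
    data.table::setattr(empty, "ref_id", ref_id)
    data.table::setattr(empty, "skipped_reads", skipped)
    return(empty)
  }
  toks <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))
  nops <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  op <- substring(flat, nchar(flat), nchar(flat))
  len <- as.integer(substring(flat, 1L, nchar(flat) - 1L))
  rid <- rep.int(seq_len(nrow(r)), nops)
  qcons <- op %in% c("M", "I", "S", "=", "X")
  rcons <- op %in% c("M", "D", "N", "=", "X")

  qlen <- as.integer(rowsum(len * qcons, rid)[, 1L])
  rlen <- as.integer(rowsum(len * rcons, rid)[, 1L])
  ok <- qlen == nchar(r$seq) & (r$pos + rlen - 1L) <= ref_len
  skipped <- sum(!ok)
  if (skipped > 0L) {
    warning(skipped, " read(s) skipped: CIGAR/sequence length mismatch or ",
            "projection beyond reference end")
  }
  keep <- ok[rid]
  od <- data.table::data.table(rid = rid[keep], op = op[keep], len = len[keep],
                               qc = len[keep] * qcons[keep],
                               rc = len[keep] * rcons[keep])
  if (nrow(od) == 0L) {
    data.table::setattr(empty, "ref_id", ref_id)
    data.table::setattr(empty, "skipped_reads", skipped)
    return(empty)
  }
  qc <- rc <- rid2 <- NULL # data.table NSE
  od[, `:=`(qoff = cumsum(data.table::shift(qc, fill = 0L)),
            roff = cumsum(data.table::shift(rc, fill = 0L))), by = "rid"]
  m <- od[od$op %in% c("M", "=", "X")]
  if (nrow(m) == 0L) {
    data.table::setattr(empty, "ref_id", ref_id)
    data.table::setattr(empty, "skipped_reads", skipped)
    return(empty)
  }
  rowid <- rep.int(seq_len(nrow(m)), m$len)
  within <- sequence(m$len)
  posv <- r$pos[m$rid[rowid]] + m$roff[rowid] + within - 1L
  qposv <- m$qoff[rowid] + within

  seqlens <- nchar(r$seq)
  coff <- cumsum(c(0L, seqlens[-length(seqlens)]))
  allc <- unlist(strsplit(r$seq, "", fixed = TRUE), use.names = FALSE)
  basev <- allc[coff[m$rid[rowid]] + qposv]

  dt <- data.table::data.table(pos = posv, base = basev)
  dt <- dt[dt$base %chin% .BASES]
  counts <- dt[, list(N = .N), by = c("pos", "base")]
  wide <- data.table::dcast(counts, pos ~ base, value.var = "N", fill = 0L)
  for (b in .BASES) {
    if (!b %in% names(wide)) wide[, (b) := 0L]
  }
  data.table::setcolorder(wide, c("pos", .BASES))
  wide[, `:=`(rname = ref_id,
              coverage = wide$A + wide$C + wide$G + wide$T)]
  data.table::setcolorder(wide, c("rname", "pos", .BASES, "coverage"))
  data.table::setkeyv(wide, "pos")
  data.table::setattr(wide, "ref_id", ref_id)
  data.table::setattr(wide, "skipped_reads", skipped)
  wide[]
}

#' Sum pileups column-wise
#'
#' Pooling replicate samples at the pileup level: the pileup of a
#' concatenated read set equals the column-wise sum of the per-set pileups.
#'
#' @param pileups List of pileups over the same reference.
#' @return A single pileup `data.table`.
#' @export
pool_pileups <- function(pileups) {
  stopifnot(length(pileups) >= 1L)
  ids <- unique(vapply(pileups, attr, character(1L), "ref_id"))
  if (length(ids) != 1L) stop("pileups cover different references: ",
                              paste(ids, collapse = ", "))
  all <- data.table::rbindlist(pileups)
  if (nrow(all) == 0L) {
    out <- pileups[[1L]]
    return(out)
  }
  out <- all[, lapply(.SD, sum), by = c("rname", "pos"), .SDcols = .BASES]
  out[, `:=`(coverage = out$A + out$C + out$G + out$T)]
  data.table::setkeyv(out, "pos")
  data.table::setattr(out, "ref_id", ids)
  out[]
}
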