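fmt2 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 2))
fmt_p <- function(p) ifelse(is.na(p), "", gsub("E([+-])0?(\\d\\d?)$", "E\\1\\2",
                                               sprintf("%.2E", p)))

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.pooled_pileup <- function(sams, references, ref_id) {
  pileups <- lapply(sams, function(s) {
    build_pileup(parse_sam(s, references), references[ref_id])
  })
  pool_pileups(pileups)
}

#' Run the target-site branch end to end
#'
#' Builds pileups for case (resistant) and, when given, control
#' (susceptible) samples over each target-gene reference; identifies
#' differential SNPs on pooled pileups, translates them and annotates
#' against the catalog; and scans the catalog mutations directly
#' (per-replicate frequencies with their mean, or pooled, per
#' `replicates`). With no control samples only the known-mutation scan is
#' performed.
#'
#' @param case_sams Character vector of case SAM paths (replicates).
#' @param control_sams Optional character vector of control SAM paths.
#' @param ref_fasta Path to the target-gene cDNA FASTA.
#' @param catalog_tsv Path to the mutation catalog TSV (default: bundled).
#' @param min_coverage,delta_threshold SNP-calling and differential
#'   thresholds (defaults 30 and 40).
#' @param replicates `"mean"` (per-replicate scan frequencies plus their
#'   mean) or `"pool"` (scan the pooled pileup).
#' @param targets Named character vector mapping reference id to target
#'   name; default [infer_targets()] on the reference ids.
#' @param canonical_fasta Optional protein FASTA (ids = target names) used
#'   to build species-to-canonical numbering maps; when absent, references
#'   are assumed to already use canonical numbering.
#' @param out_dir Optional output directory for the TSV/JSON reports
#'   (`differential.tsv`, `incomparable.tsv`, `known_scan.tsv`,
#'   `known_scan_summary.tsv`, `snp_calls_case.tsv`,
#'   `base_frequencies.tsv`, `run_summary.json`).
#' @return List with components `differential`, `incomparable`,
#'   `snp_calls_case`, `known_scan`, `known_scan_summary`,
#'   `base_frequencies` and `summary`; invisibly when `out_dir` is given.
#' @export
run_tr <- function(case_sams, control_sams = NULL, ref_fasta,
                   catalog_tsv = fastdr_example("resistance_catalog.tsv"),
                   min_coverage = 30L, delta_threshold = 40,
                   replicates = c("mean", "pool"), targets = NULL,
                   canonical_fasta = NULL, out_dir = NULL) {
  replicates <- match.arg(replicates)
  refs <- read_fasta(ref_fasta)
  catalog <- load_catalog(catalog_tsv)
  if (is.null(targets)) targets <- infer_targets(names(refs))
  canon <- if (!is.null(canonical_fasta)) {
    x <- Biostrings::readAAStringSet(canonical_fasta)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }

  diff_all <- list()
  incomp_all <- list()
  calls_all <- list()
  scan_per <- list()
  scan_sum <- list()
  freq_all <- list()

  for (rid in names(refs)) {
    ref1 <- refs[rid]
    case_piles <- lapply(case_sams, function(s) {
      build_pileup(parse_sam(s, refs), ref1)
    })
    case_pool <- pool_pileups(case_piles)
    calls <- call_snps(case_pool, ref1, min_coverage)
    calls_all[[rid]] <- calls

    numbering <- NULL
    tgt <- targets[[rid]]
    if (!is.na(tgt) && !is.null(canon) && tgt %in% names(canon)) {
      usable <- 3L * (nchar(ref1[[1L]]) %/% 3L)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(substring(ref1[[1L]], 1L, usable)),
        if.fuzzy.codon = "X"))
      prot <- sub("\\*.*$", "", prot)
      numbering <- align_proteins(prot, canon[[tgt]], query_id = rid,
                                  canonical_id = tgt)
    }

    if (!is.null(control_sams)) {
      ctrl_pool <- pool_pileups(lapply(control_sams, function(s) {
        build_pileup(parse_sam(s, refs), ref1)
      }))
      ds <- differential_snps(case_pool, ctrl_pool, ref1, min_coverage,
                              delta_threshold)
      if (nrow(ds$differential)) {
        ann <- data.table::rbindlist(lapply(seq_len(nrow(ds$differential)),
          function(i) {
            translate_variant(ref1, ds$differential$pos[i],
                              ds$differential$variant[i])
          }))
        d <- cbind(ds$differential, ann[, c("residue", "ref_codon",
                                            "alt_codon", "ref_aa", "alt_aa",
                                            "synonymous", "label")])
        d[, `:=`(canonical_residue = if (is.null(numbering)) d$residue else
          query_to_canonical(numbering, d$residue))]
        d[, `:=`(known = vapply(seq_len(nrow(d)), function(i) {
          if (is.na(tgt) || is.na(d$canonical_residue[i]) ||
              is.na(d$label[i])) return("")
          hit <- catalog_lookup(catalog, tgt, d$canonical_residue[i],
                                d$ref_aa[i], d$alt_aa[i])
          if (is.null(hit)) "" else hit$label
        }, character(1L)))]
        diff_all[[rid]] <- d
        freq_all[[rid]] <- cbind(rname = rid,
                                 base_frequency_matrix(case_pool, d$pos))
      }
      incomp_all[[rid]] <- ds$incomparable
    }

    if (!is.na(tgt)) {
      cat_t <- catalog[catalog$target == tgt]
      if (nrow(cat_t)) {
        if (replicates == "pool") {
          sc <- scan_known(case_pool, ref1, cat_t, numbering, min_coverage)
          scan_per[[rid]] <- cbind(replicate = "pool", rname = rid, sc)
          scan_sum[[rid]] <- cbind(rname = rid,
                                   sc[, c("label", "frequency")])
        } else {
          scans <- lapply(case_piles, scan_known, reference = ref1,
                          catalog = cat_t, numbering = numbering,
                          min_coverage = min_coverage)
          agg <- aggregate_replicates(scans)
          scan_per[[rid]] <- cbind(rname = rid, agg$per_replicate)
          scan_sum[[rid]] <- cbind(rname = rid, agg$summary)
        }
      }
    }
  }

  res <- list(
    differential = data.table::rbindlist(diff_all),
    incomparable = data.table::rbindlist(incomp_all),
    snp_calls_case = data.table::rbindlist(calls_all),
    known_scan = data.table::rbindlist(scan_per),
    known_scan_summary = data.table::rbindlist(scan_sum, fill = TRUE),
    summary = list(
      n_references = length(refs),
      n_case_samples = length(case_sams),
      n_control_samples = length(control_sams),
      min_coverage = min_coverage, delta_threshold = delta_threshold,
      replicates = replicates,
      n_differential = sum(vapply(diff_all, nrow, 0L)),
      n_incomparable = sum(vapply(incomp_all, nrow, 0L))))
  res$base_frequencies <- data.table::rbindlist(freq_all)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    d <- data.table::copy(res$differential)
    if (nrow(d)) {
      d[, `:=`(case_frequency = fmt2(d$case_frequency),
               control_frequency = fmt2(d$control_frequency),
               delta = fmt2(d$delta), diff = fmt2(d$diff))]
    }
    write_tsv(d, file.path(out_dir, "differential.tsv"))
    write_tsv(res$incomparable, file.path(out_dir, "incomparable.tsv"))
    write_tsv(res$snp_calls_case, file.path(out_dir, "snp_calls_case.tsv"))
    ks <- data.table::copy(res$known_scan)
    if (nrow(ks)) ks[, `:=`(frequency = fmt2(ks$frequency))]
    write_tsv(ks, file.path(out_dir, "known_scan.tsv"))
    kss <- data.table::copy(res$known_scan_summary)
    if (nrow(kss)) {
      for (cc in intersect(c("frequency", "mean_frequency"), names(kss))) {
        kss[, (cc) := fmt2(kss[[cc]])]
      }
    }
    write_tsv(kss, file.path(out_dir, "known_scan_summary.tsv"))
    write_tsv(res$base_frequencies,
              file.path(out_dir, "base_frequencies.tsv"))
    write_json_report(res$summary, file.path(out_dir, "run_summary.json"))
    return(invisible(res))
  }
  res
}

#' Run the metabolic (overexpression) branch end to end
#'
#' Counts primary-mapped reads per detoxification gene per sample (or takes
#' a ready-made counts TSV, genes in the first column, one column per
#' sample), runs the negative-binomial Wald test (case over control) and
#' filters overexpressed genes.
#'
#' @param case_sams,control_sams SAM paths per group; ignored when
#'   `counts_tsv` is given.
#' @param ref_fasta Detoxification-gene cDNA FASTA (defines the gene set);
#'   ignored when `counts_tsv` is given.
#' @param counts_tsv Optional pre-made counts matrix TSV; requires
#'   `case_samples`/`control_samples` naming its columns.
#' @param case_samples,control_samples Column names of `counts_tsv`
#'   belonging to each group.
#' @param lfc_threshold,p_threshold Overexpression filter thresholds
#'   (defaults 1 and 0.01).
#' @param out_dir Optional output directory (`counts.tsv`, `results.tsv`,
#'   `overexpressed.tsv`, `run_summary.json`). `results.tsv` follows the
#'   standard report layout: GeneID, FC, Log2FC, SE, CI95 bounds, p value,
#'   adjusted p value.
#' @return List with `counts`, `results`, `overexpressed`, `summary`;
#'   invisibly when `out_dir` is given.
#' @export
run_mr <- function(case_sams = NULL, control_sams = NULL, ref_fasta = NULL,
                   counts_tsv = NULL, case_samples = NULL,
                   control_samples = NULL, lfc_threshold = 1,
                   p_threshold = 0.01, out_dir = NULL) {
  if (!is.null(counts_tsv)) {
    tab <- data.table::fread(counts_tsv, sep = "\t")
    genes <- as.character(tab[[1L]])
    counts <- as.matrix(tab[, -1L])
    rownames(counts) <- genes
    if (is.null(case_samples) || is.null(control_samples)) {
      stop("counts_tsv requires case_samples and control_samples")
    }
    counts <- counts[, c(case_samples, control_samples), drop = FALSE]
    groups <- rep(c("case", "control"),
                  c(length(case_samples), length(control_samples)))
  } else {
    refs <- read_fasta(ref_fasta)
    sams <- c(case_sams, control_sams)
    counts <- vapply(sams, function(s) {
      count_reads(parse_sam(s, refs), names(refs))
    }, numeric(length(refs)))
    rownames(counts) <- names(refs)
    colnames(counts) <- basename(sams)
    groups <- rep(c("case", "control"),
                  c(length(case_sams), length(control_sams)))
  }
  results <- nb_wald_test(counts, groups)
  over <- filter_overexpressed(results, lfc_threshold, p_threshold)
  res <- list(counts = counts, results = results, overexpressed = over,
              summary = list(
                n_genes = nrow(counts), n_samples = ncol(counts),
                n_tested = sum(results$tested),
                n_overexpressed = nrow(over),
                lfc_threshold = lfc_threshold, p_threshold = p_threshold))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cdt <- data.table::data.table(GeneID = rownames(counts))
    cdt <- cbind(cdt, data.table::as.data.table(counts))
    write_tsv(cdt, file.path(out_dir, "counts.tsv"))
    layout <- function(r) data.table::data.table(
      GeneID = r$gene, FC = fmt2(r$FC), Log2FC = fmt2(r$log2FC),
      SE = fmt2(r$SE),
      CI95_low = fmt2(r$CI95_low), CI95_high = fmt2(r$CI95_high),
      pValue = fmt_p(r$pvalue), pAdj = fmt_p(r$padj))
    write_tsv(layout(results), file.path(out_dir, "results.tsv"))
    write_tsv(layout(over), file.path(out_dir, "overexpressed.tsv"))
    write_json_report(res$summary, file.path(out_dir, "run_summary.json"))
    return(invisible(res))
  }
  res
}
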