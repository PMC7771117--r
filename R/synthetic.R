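.SENSE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# codon placements realizing published substitutions at their residues:
# each (residue = codon) pair is chosen so that the published ref base sits
# at the published cDNA position and a single-base change yields the
# published amino-acid substitution.
.RYR_CODONS <- c(
  "662" = "AGC", "843" = "TTC", "1843" = "CTC", "2123" = "TTT",
  "2377" = "AGA", "3103" = "TTA", "3214" = "TTC", "3511" = "AGG",
  "4170" = "GAA", "4946" = "GGA", "5164" = "GAG")
.VGSC_CODONS <- c(
  "1014" = "CTT", "1886" = "CGT", "1940" = "CGT", "2030" = "ACA",
  "2052" = "GGT")
.NACHRB1_CODONS <- c("81" = "AGA")

.make_cds <- function(n_codons, placed) {
  codons <- sample(.SENSE_CODONS, n_codons, replace = TRUE)
  codons[1L] <- "ATG"
  codons[as.integer(names(placed))] <- placed
  paste(codons, collapse = "")
}

#' Synthetic target-gene cDNA fixtures
#'
#' Deterministically generated stand-ins for the real target-gene cDNAs
#' (which live in public sequence databases): in-frame coding sequences of
#' realistic length for the ryanodine receptor (5164 codons), the
#' voltage-gated sodium channel (2100 codons, house-fly numbering) and the
#' nAChR beta1 subunit (500 codons), with the codons at published
#' resistance residues chosen so that the published nucleotide change
#' produces the published amino-acid substitution — e.g. codon 4946 of the
#' RyR sequence is `GGA`, and a `G>A` change at cDNA position 14837 (its
#' middle base) gives `GAA`, the G4946E substitution. All remaining codons
#' are random sense codons under a fixed internal seed, so the sequences
#' are reproducible and free of internal stops. The same sequences are
#' stored as `synthetic_targets.fa` under the package's `extdata`.
#'
#' @return Named character vector of three coding sequences
#'   (`RyR_synthetic`, `VGSC_synthetic`, `nAChR-beta1_synthetic`).
#' @export
synthetic_target_genes <- function() {
  withr::with_seed(20201121L, {
    c(`RyR_synthetic` = .make_cds(5164L, .RYR_CODONS),
      `VGSC_synthetic` = .make_cds(2100L, .VGSC_CODONS),
      `nAChR-beta1_synthetic` = .make_cds(500L, .NACHRB1_CODONS))
  })
}

#' Synthetic canonical proteins for residue numbering
#'
#' Translations of [synthetic_target_genes()], named by target. They stand
#' in for the canonical reference proteins that define published mutation
#' coordinates; with these fixtures the species-to-canonical numbering map
#' is the identity, and tests derive offset variants from them to exercise
#' non-trivial maps. Stored as `synthetic_canonical_proteins.fa` under
#' `extdata`.
#'
#' @return Named character vector of protein sequences (`RyR`, `VGSC`,
#'   `nAChR-beta1`).
#' @export
synthetic_canonical_proteins <- function() {
  cds <- synthetic_target_genes()
  prots <- vapply(cds, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1L))
  names(prots) <- sub("_synthetic$", "", names(cds))
  prots
}

#' Guess the catalog target for each reference id
#'
#' Matches target names (case-insensitive, punctuation-insensitive) as
#' substrings of the reference ids, longest target name first so
#' `nAChR-beta1` wins over a hypothetical bare `nAChR`.
#'
#' @param ref_ids Character vector of reference ids.
#' @return Named character vector mapping reference id to target name
#'   (`NA` when no target name matches).
#' @export
infer_targets <- function(ref_ids) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  targets <- .TARGETS[order(-nchar(.TARGETS))]
  out <- vapply(ref_ids, function(id) {
    hit <- targets[vapply(targets, function(t) {
      grepl(norm(t), norm(id), fixed = TRUE)
    }, logical(1L))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1L))
  names(out) <- ref_ids
  out
}
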