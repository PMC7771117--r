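.TARGETS <- c("AChE", "VGSC", "RyR",
              "nAChR-alpha1", "nAChR-alpha3", "nAChR-alpha6", "nAChR-beta1")

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Load a catalog of published resistance mutations
#'
#' The catalog is a tab-separated file with header columns `target`,
#' `canonical_accession`, `residue`, `ref_aa`, `alt_aa`. Residue numbers are
#' canonical coordinates: positions on the designated reference species'
#' protein for each target (e.g. the house-fly sodium channel for VGSC, so
#' the kdr substitution is L1014F regardless of the query species). Invalid
#' rows are rejected with a warning, not an error, so user-extended
#' catalogs degrade gracefully.
#'
#' @param path Path to the catalog TSV. Defaults to the bundled subset
#'   carrying the mutations used in the worked examples (G4946E on RyR,
#'   R81T on the nAChR beta1 subunit, L1014F on VGSC).
#' @return A `data.table` with the input columns plus `label`
#'   (e.g. `"L1014F"`).
#' @export
load_catalog <- function(path = fastdr_example("resistance_catalog.tsv")) {
  cat <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("target", "canonical_accession", "ref_aa", "alt_aa"),
    integer = "residue"))
  need <- c("target", "canonical_accession", "residue", "ref_aa", "alt_aa")
  if (!all(need %in% names(cat))) {
    stop("catalog is missing required column(s): ",
         paste(setdiff(need, names(cat)), collapse = ", "))
  }
  reasons <- character(nrow(cat))
  reasons[!(cat$target %chin% .TARGETS)] <- "unknown target"
  reasons[is.na(cat$residue) | cat$residue <= 0L] <- "non-positive residue"
  reasons[!(cat$ref_aa %chin% .AA) | !(cat$alt_aa %chin% .AA)] <-
    "invalid amino acid"
  reasons[cat$ref_aa == cat$alt_aa] <- "identical ref/alt amino acid"
  bad <- reasons != ""
  if (any(bad)) {
    warning(sum(bad), " catalog row(s) rejected: ",
            paste(sprintf("row %d (%s)", which(bad), reasons[bad]),
                  collapse = "; "))
    cat <- cat[!bad]
  }
  cat[, `:=`(label = paste0(cat$ref_aa, cat$residue, cat$alt_aa))]
  cat[]
}

#' Look up a mutation in the catalog
#'
#' Exact match on target, canonical residue and both amino acids. A miss
#' means the substitution is a novel candidate rather than a published
#' marker.
#'
#' @param catalog Catalog table from [load_catalog()].
#' @param target Target gene name (one of the catalog's target set).
#' @param residue Canonical residue index.
#' @param ref_aa,alt_aa Single-letter amino acids.
#' @return The matching one-row `data.table`, or `NULL` when absent.
#' @export
catalog_lookup <- function(catalog, target, residue, ref_aa, alt_aa) {
  if (!target %in% .TARGETS) stop("unknown target: ", target)
  keep <- which(catalog$target == target & catalog$residue == residue &
                  catalog$ref_aa == ref_aa & catalog$alt_aa == alt_aa)
  if (length(keep) == 0L) NULL else catalog[keep]
}

#' Map residue numbering between two proteins by global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5
#' via [Biostrings::pairwiseAlignment()]) between a query protein (the
#' species under study) and the canonical protein that defines published
#' mutation coordinates. The returned map pairs the residue indices aligned
#' without a gap on either side; it is strictly increasing on its domain by
#' construction.
#'
#' @param query,canonical Protein sequences (single strings, standard
#'   amino-acid alphabet).
#' @param query_id,canonical_id Optional identifiers stored in the map.
#' @return An object of class `numbering_map`: a list with `query_id`,
#'   `canonical_id`, `map` (a `data.table` with columns `query_pos`,
#'   `canonical_pos`) and `score`.
#' @export
align_proteins <- function(query, canonical, query_id = "query",
                           canonical_id = "canonical") {
  if (!nzchar(query) || !nzchar(canonical)) {
    stop("empty protein sequence")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(canonical),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "",
                fixed = TRUE)[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "",
                fixed = TRUE)[[1L]]
  qi <- cumsum(p != "-")
  si <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  map <- data.table::data.table(query_pos = qi[keep],
                                canonical_pos = si[keep])
  structure(list(query_id = query_id, canonical_id = canonical_id,
                 map = map, score = Biostrings::score(pa)),
            class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("numbering map %s -> %s: %d aligned residue pairs, score %.1f\n",
              x$query_id, x$canonical_id, nrow(x$map), x$score))
  invisible(x)
}

#' Translate residue indices through a numbering map
#'
#' @param map A `numbering_map` from [align_proteins()].
#' @param residue Residue indices in query coordinates
#'   (`query_to_canonical`) or canonical coordinates (`canonical_to_query`).
#' @return Integer vector of mapped indices, `NA` where the residue is
#'   unaligned.
#' @export
query_to_canonical <- function(map, residue) {
  map$map$canonical_pos[match(residue, map$map$query_pos)]
}

#' @rdname query_to_canonical
#' @export
canonical_to_query <- function(map, residue) {
  map$map$query_pos[match(residue, map$map$canonical_pos)]
}

#' Path to a bundled example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
fastdr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fastdr")))
  }
  p <- system.file("extdata", file, package = "fastdr")
  if (!nzchar(p)) stop("no bundled file named ", file)
  p
}
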