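#' @useDynLib proteocat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DECOY_PREFIX <- "DECOY_"

# Residues outside the 20-letter canonical alphabet are kept in the database
# but peptides containing them are skipped at digestion.
CANONICAL_AA <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "V", "W", "Y")

new_protein_db <- function(accession, sequence, source, origin, stage) {
  db <- data.frame(accession = as.character(accession),
                   sequence = as.character(sequence),
                   source = as.character(source),
                   origin = as.character(origin),
                   stringsAsFactors = FALSE)
  attr(db, "stage") <- stage
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Create a protein database object
#'
#' A protein database is an ordered table of records with columns
#' `accession`, `sequence`, `source` (`"target"` or `"decoy"`) and `origin`
#' (free-text provenance tag), plus a `stage` attribute describing its role
#' in the workflow (`"catalog"`, `"sample_reduced"`, `"combined_nr"` or
#' `"with_decoys"`).
#'
#' @param accession character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences (uppercase).
#' @param source `"target"` or `"decoy"`, recycled.
#' @param origin free-text database tag, recycled.
#' @param stage database stage label.
#' @return A `protein_db` data frame.
#' @export
protein_db <- function(accession, sequence, source = "target",
                       origin = "user", stage = "catalog") {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence)) {
    stop("accession and sequence must have equal length")
  }
  if (anyDuplicated(accession)) {
    dup <- accession[duplicated(accession)][1L]
    stop("duplicate accession in database: ", dup)
  }
  if (any(!nzchar(sequence))) stop("empty sequence not allowed")
  new_protein_db(accession, sequence,
                 rep_len(source, length(accession)),
                 rep_len(origin, length(accession)), stage)
}

#' Read a protein FASTA database
#'
#' The first whitespace-delimited token of each header is taken as the
#' accession. Sequences are uppercased and a terminal stop character `*` is
#' stripped. Record order is preserved.
#'
#' @param path path to an amino-acid FASTA file.
#' @param origin provenance tag stored on every record.
#' @param stage stage label for the resulting database.
#' @return A [protein_db()] object.
#' @export
read_fasta <- function(path, origin = basename(path), stage = "catalog") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  acc <- vapply(strsplit(names(aa), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    dup <- acc[duplicated(acc)][1L]
    stop("duplicate accession in FASTA: ", dup)
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ",
                               acc[!nzchar(seqs)][1L])
  src <- ifelse(startsWith(acc, DECOY_PREFIX), "decoy", "target")
  new_protein_db(acc, unname(seqs), src, origin, stage)
}

#' Write a protein database to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param db a [protein_db()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- db$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Append reversed-sequence decoys to a target database
#'
#' Each target record gains a partner whose sequence is the exact character
#' reversal of the target and whose accession carries the `DECOY_` prefix.
#'
#' @param db target-only [protein_db()].
#' @return Database with `2 * nrow(db)` records, stage `"with_decoys"`.
#' @export
add_decoys <- function(db) {
  if (any(db$source == "decoy")) stop("database already contains decoy records")
  rev_seq <- vapply(strsplit(db$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  new_protein_db(c(db$accession, paste0(DECOY_PREFIX, db$accession)),
                 c(db$sequence, rev_seq),
                 c(rep("target", nrow(db)), rep("decoy", nrow(db))),
                 c(db$origin, db$origin),
                 "with_decoys")
}

#' Extract a sample-specific reduced database
#'
#' Subsets the catalog to the accessions matched in a first-pass search,
#' preserving catalog order.
#'
#' @param catalog a [protein_db()].
#' @param matched_accessions character vector of accessions to keep.
#' @return Database with stage `"sample_reduced"`.
#' @export
build_reduced_db <- function(catalog, matched_accessions) {
  matched_accessions <- unique(as.character(matched_accessions))
  unknown <- setdiff(matched_accessions, catalog$accession)
  if (length(unknown)) {
    stop("accessions not in catalog: ", paste(unknown, collapse = ", "))
  }
  if (length(matched_accessions) == 0L) {
    warning("empty matched set: reduced database has no records")
  }
  keep <- catalog$accession %in% matched_accessions
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- "sample_reduced"
  class(out) <- c("protein_db", "data.frame")
  out
}

#' Combine per-sample protein lists into a non-redundant database
#'
#' Records are concatenated in input order and de-duplicated by exact
#' sequence identity; the first-seen accession is retained for each distinct
#' sequence.
#'
#' @param per_sample_lists list of target-only [protein_db()] objects.
#' @return Database with stage `"combined_nr"`.
#' @export
build_combined_nr <- function(per_sample_lists) {
  if (length(per_sample_lists) == 0L) {
    return(new_protein_db(character(0), character(0), character(0),
                          character(0), "combined_nr"))
  }
  acc <- unlist(lapply(per_sample_lists, `[[`, "accession"), use.names = FALSE)
  seqs <- unlist(lapply(per_sample_lists, `[[`, "sequence"), use.names = FALSE)
  org <- unlist(lapply(per_sample_lists, `[[`, "origin"), use.names = FALSE)
  keep_seq <- !duplicated(seqs)
  # same sequence may arrive under several accessions; first seen wins
  acc <- acc[keep_seq]; seqs <- seqs[keep_seq]; org <- org[keep_seq]
  keep_acc <- !duplicated(acc)
  new_protein_db(acc[keep_acc], seqs[keep_acc],
                 rep("target", sum(keep_acc)), org[keep_acc], "combined_nr")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("protein_db [%s]: %d records (%d target, %d decoy)\n",
              attr(x, "stage") %||% "?", nrow(x),
              sum(x$source == "target"), sum(x$source == "decoy")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
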