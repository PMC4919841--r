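TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' Read a taxonomy table
#'
#' Expects a TSV with columns `taxon_id`, `parent_id`, `rank`, `name`. The
#' root node is its own parent (or has an empty/NA parent). The tree must be
#' acyclic with a single root.
#'
#' @param path TSV file path.
#' @return A `taxonomy` object (validated data frame).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(taxon_id = "character",
                                         parent_id = "character"))
  taxonomy(df)
}

#' Construct and validate a taxonomy
#'
#' @param df data frame with `taxon_id`, `parent_id`, `rank`, `name`.
#' @return A `taxonomy` data frame.
#' @export
taxonomy <- function(df) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(df)))
  df$taxon_id <- as.character(df$taxon_id)
  df$parent_id <- as.character(df$parent_id)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id")
  root <- df$taxon_id[is.na(df$parent_id) | df$parent_id == "" |
                        df$parent_id == df$taxon_id]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  if (!all(df$parent_id[!df$taxon_id %in% root] %in% df$taxon_id)) {
    stop("parent_id refers to unknown taxon")
  }
  # acyclicity: walking up from every node must reach the root
  for (id in df$taxon_id) {
    seen <- character(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen) stop("cycle in taxonomy at ", cur)
      seen <- c(seen, cur)
      cur <- df$parent_id[match(cur, df$taxon_id)]
    }
  }
  attr(df, "root") <- root
  class(df) <- c("taxonomy", "data.frame")
  df
}

# Path from a node up to the root (inclusive), root last.
tax_ancestors <- function(tree, taxon_id) {
  root <- attr(tree, "root")
  path <- taxon_id
  cur <- taxon_id
  while (cur != root) {
    cur <- tree$parent_id[match(cur, tree$taxon_id)]
    path <- c(path, cur)
  }
  path
}

# I/L are indistinguishable by mass; taxonomy keys collapse both to L.
collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Build a taxon-labeled peptide index
#'
#' Digests the taxon-labeled reference proteins and maps every
#' (I/L-collapsed) tryptic peptide to the set of taxa whose proteins contain
#' it.
#'
#' @param db reference [protein_db()].
#' @param protein_taxa named character vector: accession -> taxon_id.
#' @param params a [digest_params()]; only unmodified sequences are indexed.
#' @return A `tax_peptide_index` list: `pep2taxa` (named list) and `tree`
#'   placeholder fields.
#' @export
build_tax_index <- function(db, protein_taxa, params = digest_params()) {
  if (!all(db$accession %in% names(protein_taxa))) {
    stop("every reference protein needs a taxon label")
  }
  pep2taxa <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(db))) {
    d <- digest_protein(db$sequence[i], params)
    if (!nrow(d)) next
    peps <- unique(collapse_il(d$sequence))
    tx <- protein_taxa[[db$accession[i]]]
    for (p in peps) pep2taxa[[p]] <- c(pep2taxa[[p]], tx)
  }
  lst <- as.list(pep2taxa)
  lst <- lapply(lst, unique)
  structure(list(pep2taxa = lst, params = params),
            class = "tax_peptide_index")
}

#' Lowest common ancestor of the taxa containing a peptide
#'
#' The peptide is I/L-collapsed and looked up in the index; the returned
#' node is the lowest taxon common to all source proteins, i.e. the taxon
#' the peptide is unique to. With `advanced_missed_cleavage` (default), a
#' peptide with internal cleavage sites that is absent from the index is
#' resolved by intersecting the taxon sets of its fully tryptic
#' sub-peptides.
#'
#' @param peptide peptide sequence.
#' @param index a [build_tax_index()] result.
#' @param tree a [taxonomy()].
#' @param advanced_missed_cleavage resolve missed-cleavage peptides through
#'   their tryptic parts?
#' @return The taxon_id of the LCA, or `NA_character_` if unassigned.
#' @export
lca_assign <- function(peptide, index, tree,
                       advanced_missed_cleavage = TRUE) {
  pep <- collapse_il(peptide)
  taxa <- index$pep2taxa[[pep]]
  if (is.null(taxa) && advanced_missed_cleavage) {
    res <- strsplit(pep, "", fixed = TRUE)[[1L]]
    bounds <- tryptic_boundaries(res)
    if (nrow(bounds) > 1L) {
      subs <- substring(pep, bounds[, 1L], bounds[, 2L])
      sets <- lapply(subs, function(p) index$pep2taxa[[p]])
      if (!any(vapply(sets, is.null, logical(1)))) {
        taxa <- Reduce(intersect, sets)
      }
    }
  }
  if (is.null(taxa) || !length(taxa)) return(NA_character_)
  paths <- lapply(taxa, function(t) tax_ancestors(tree, t))
  common <- Reduce(intersect, paths)
  common[1L]  # ancestors are ordered leaf-to-root; first common is lowest
}

#' Taxon-by-sample relative abundance at a rank
#'
#' A peptide counts toward a taxon at the requested rank when its LCA is
#' that taxon or one of its descendants. Intensities are summed per taxon
#' and divided by the total identified peptide intensity of each sample
#' (unassigned peptides contribute to the denominator only).
#'
#' @param feat feature table with `peptide`, `sample_id`, `intensity`.
#' @param assignments named character vector: peptide -> LCA taxon_id (NA
#'   for unassigned), as from [lca_assign()].
#' @param tree a [taxonomy()].
#' @param rank rank at which to aggregate (e.g. `"phylum"`, `"species"`).
#' @return Numeric matrix taxa x samples of relative abundances.
#' @export
taxon_abundance <- function(feat, assignments, tree, rank = "phylum") {
  nodes <- tree$taxon_id[tree$rank == rank]
  samples <- unique(feat$sample_id)
  out <- matrix(0, length(nodes), length(samples),
                dimnames = list(tree$name[match(nodes, tree$taxon_id)],
                                samples))
  totals <- tapply(feat$intensity, feat$sample_id, sum)
  lca <- assignments[feat$peptide]
  # map each LCA to its ancestor at the requested rank (if any)
  ulca <- unique(lca[!is.na(lca)])
  at_rank <- vapply(ulca, function(t) {
    anc <- tax_ancestors(tree, t)
    hit <- anc[anc %in% nodes]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  ranked <- at_rank[lca]
  ok <- !is.na(ranked)
  if (any(ok)) {
    agg <- tapply(feat$intensity[ok],
                  list(ranked[ok], feat$sample_id[ok]), sum)
    rn <- tree$name[match(rownames(agg), tree$taxon_id)]
    for (i in seq_len(nrow(agg))) {
      for (s in colnames(agg)) {
        if (!is.na(agg[i, s])) out[rn[i], s] <- agg[i, s]
      }
    }
  }
  sweep(out, 2L, as.numeric(totals[samples]), "/")
}

#' Firmicutes-to-Bacteroidetes ratio per sample
#'
#' @param phylum_matrix matrix from [taxon_abundance()] at phylum rank with
#'   rows named by phylum.
#' @return Named numeric vector of per-sample ratios; samples with zero
#'   Bacteroidetes intensity are `NA` (flagged via the `undefined`
#'   attribute), not infinite.
#' @export
fb_ratio <- function(phylum_matrix) {
  for (ph in c("Firmicutes", "Bacteroidetes")) {
    if (!ph %in% rownames(phylum_matrix)) {
      stop("phylum absent from matrix: ", ph)
    }
  }
  f <- phylum_matrix["Firmicutes", ]
  b <- phylum_matrix["Bacteroidetes", ]
  ratio <- ifelse(b > 0, f / b, NA_real_)
  attr(ratio, "undefined") <- names(ratio)[b == 0]
  ratio
}

#' Read a COG annotation table
#'
#' TSV with columns `accession`, `cog_id`, `cog_category` (one or more
#' single letters, e.g. `"EG"`).
#'
#' @param path TSV file path.
#' @return Data frame annotation.
#' @export
read_cog_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "cog_id", "cog_category") %in% names(df)))
  bad <- grepl("[^A-Z]", df$cog_category)
  if (any(bad)) stop("invalid COG category: ", df$cog_category[bad][1L])
  df
}

#' COG category abundance roll-up
#'
#' Each protein group is annotated by its leading protein; if the leading
#' protein has no COG match the remaining members are checked in rank
#' order. Unannotated groups accumulate in category `"?"`. The LFQ
#' intensities of all groups sharing a category are summed per sample.
#' Multi-letter category strings contribute, in `"primary"` mode (default),
#' only their first letter; in `"each"` mode the full group LFQ is counted
#' once per listed letter (conservation then no longer holds).
#'
#' @param groups groups from [group_proteins()]/[assign_razor()].
#' @param lfq LFQ matrix from [maxlfq()].
#' @param annotation data frame as from [read_cog_annotation()].
#' @param mode `"primary"` or `"each"`.
#' @return Numeric matrix category x sample of summed LFQ intensities.
#' @export
cog_rollup <- function(groups, lfq, annotation, mode = c("primary", "each")) {
  mode <- match.arg(mode)
  ann_cat <- stats::setNames(annotation$cog_category, annotation$accession)
  group_cat <- vapply(groups, function(g) {
    for (m in g$members) {
      cat <- unname(ann_cat[m])
      if (!is.na(cat) && nzchar(cat)) return(cat)
    }
    "?"
  }, character(1))
  cats <- if (mode == "primary") substr(group_cat, 1L, 1L) else group_cat
  letters_list <- if (mode == "primary") as.list(cats) else {
    strsplit(cats, "", fixed = TRUE)
  }
  all_letters <- sort(unique(unlist(letters_list)))
  out <- matrix(0, length(all_letters), ncol(lfq),
                dimnames = list(all_letters, colnames(lfq)))
  for (g in seq_along(groups)) {
    row <- lfq[groups[[g]]$group_id, ]
    row[is.na(row)] <- 0
    for (letter in letters_list[[g]]) {
      out[letter, ] <- out[letter, ] + row
    }
  }
  out
}
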