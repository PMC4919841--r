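#' FDR filtering parameters
#'
#' Defaults follow common practice for two-step catalog searches: PSM q-value
#' cutoff 0.01 and maximum expect value 0.05 in the identification step, and
#' a loose expect threshold of 1.0 for the recall-oriented first-step
#' database reduction.
#'
#' @param fdr_cutoff q-value cutoff for accepted PSMs (default 0.01).
#' @param max_expect maximum expect value for accepted PSMs (default 0.05).
#' @param step1_max_expect expect threshold for including a protein in the
#'   sample-specific reduced database (default 1.0).
#' @return An `fdr_params` list.
#' @export
fdr_params <- function(fdr_cutoff = 0.01, max_expect = 0.05,
                       step1_max_expect = 1.0) {
  stopifnot(fdr_cutoff > 0, fdr_cutoff < 1)
  structure(list(fdr_cutoff = fdr_cutoff, max_expect = max_expect,
                 step1_max_expect = step1_max_expect),
            class = "fdr_params")
}

#' Target-decoy q-values for a PSM table
#'
#' PSMs are sorted by descending hyperscore; the running FDR at rank i is
#' `#decoys(1..i) / max(1, #targets(1..i))` and the q-value is the minimum
#' running FDR at or below that rank (monotone non-decreasing down the
#' sorted list).
#'
#' @param psms PSM data frame from [search_run()] (one best PSM per
#'   spectrum, from a with-decoys search).
#' @return `psms` with a `q` column, sorted by descending hyperscore.
#' @export
compute_qvalues <- function(psms) {
  if (nrow(psms) == 0L) {
    psms$q <- numeric(0)
    return(psms)
  }
  ord <- order(-psms$hyperscore, psms$expect, psms$peptide)
  psms <- psms[ord, , drop = FALSE]
  n_decoy <- cumsum(psms$is_decoy)
  n_target <- cumsum(!psms$is_decoy)
  fdr <- n_decoy / pmax(1L, n_target)
  psms$q <- rev(cummin(rev(fdr)))
  rownames(psms) <- NULL
  psms
}

#' Step 1: reduce the catalog to a sample-specific database
#'
#' Searches the run against the target-only catalog and keeps every protein
#' mapped by any PSM with expect value at or below `step1_max_expect`. No
#' FDR filtering is applied at this recall-oriented step.
#'
#' @param run an [ms_run()].
#' @param catalog target-only [protein_db()].
#' @param dparams,sparams digestion and search parameters.
#' @param fparams an [fdr_params()] (supplies `step1_max_expect`).
#' @param index optional prebuilt catalog index (reused across samples).
#' @return Reduced [protein_db()] (stage `"sample_reduced"`).
#' @export
step1_reduce <- function(run, catalog, dparams = digest_params(),
                         sparams = search_params(),
                         fparams = fdr_params(), index = NULL) {
  if (any(catalog$source == "decoy")) {
    stop("step 1 expects a target-only catalog")
  }
  psms <- search_run(run, catalog, dparams, sparams, index = index)
  keep <- psms[psms$expect <= fparams$step1_max_expect, , drop = FALSE]
  accs <- unique(unlist(strsplit(keep$accessions, ";", fixed = TRUE),
                        use.names = FALSE))
  build_reduced_db(catalog, accs)
}

#' Step 2: target-decoy identification against the reduced database
#'
#' Appends reversed decoys to the reduced database, searches the run,
#' computes q-values, and keeps target PSMs with `q <= fdr_cutoff` and
#' `expect <= max_expect`.
#'
#' @param run an [ms_run()].
#' @param reduced sample-specific reduced [protein_db()] (targets only).
#' @param fparams an [fdr_params()].
#' @param dparams,sparams digestion and search parameters.
#' @return An `identified_list`: `sample_id`, `psms` (passing PSMs with q),
#'   `all_psms` (with q, unfiltered), `peptides` (best PSM per peptide
#'   sequence), `proteins` (target [protein_db()] supported by passing
#'   PSMs), `n_spectra`.
#' @export
step2_identify <- function(run, reduced, fparams = fdr_params(),
                           dparams = digest_params(),
                           sparams = search_params()) {
  if (nrow(reduced) == 0L) {
    warning("empty reduced database for sample ", run$sample_id,
            ": no identifications")
    psms0 <- empty_psm_df()
    psms0$q <- numeric(0)
    return(structure(list(sample_id = run$sample_id, psms = psms0,
                          all_psms = psms0, peptides = psms0,
                          proteins = reduced,
                          n_spectra = length(run$spectra)),
                     class = "identified_list"))
  }
  td <- add_decoys(reduced)
  psms <- compute_qvalues(search_run(run, td, dparams, sparams))
  pass <- psms[psms$q <= fparams$fdr_cutoff &
                 psms$expect <= fparams$max_expect &
                 !psms$is_decoy, , drop = FALSE]
  # best PSM per peptide sequence
  pep <- pass[order(-pass$hyperscore, pass$expect, pass$peptide), ,
              drop = FALSE]
  pep <- pep[!duplicated(pep$peptide), , drop = FALSE]
  rownames(pep) <- NULL
  accs <- as.character(unique(unlist(strsplit(pass$accessions, ";",
                                              fixed = TRUE),
                                     use.names = FALSE)))
  accs <- accs[!startsWith(accs, DECOY_PREFIX)]
  prot <- reduced[reduced$accession %in% accs, , drop = FALSE]
  rownames(prot) <- NULL
  structure(list(sample_id = run$sample_id, psms = pass, all_psms = psms,
                 peptides = pep, proteins = prot,
                 n_spectra = length(run$spectra)),
            class = "identified_list")
}

#' Run the full iterative identification and quantification workflow
#'
#' Per sample: a loose target-only search of the catalog builds a reduced
#' database (step 1), then a target-decoy search of the reduced database
#' yields FDR-controlled identifications (step 2). The per-sample protein
#' lists are combined and de-duplicated by sequence into the study's
#' non-redundant database, against which every run is searched once more for
#' quantification: features are extracted from passing PSMs, transferred
#' between runs by aligned retention time and accurate mass, proteins are
#' grouped by the subset rule with razor-peptide assignment, and MaxLFQ-style
#' protein intensities are computed.
#'
#' @param runs list of [ms_run()] objects.
#' @param catalog target-only [protein_db()].
#' @param dparams,sparams,fparams,qparams module parameter objects.
#' @return A `workflow_result` list: `reduced_dbs`, `identified`
#'   (per-sample `identified_list`s), `combined_nr`, `final_psms` (per
#'   sample, passing), `features`, `groups`, `peptide_table`,
#'   `protein_groups` (with per-sample LFQ columns), `lfq` (matrix),
#'   `id_rate` (identified MS/MS over acquired MS/MS per sample).
#' @export
run_workflow <- function(runs, catalog, dparams = digest_params(),
                         sparams = search_params(),
                         fparams = fdr_params(),
                         qparams = quant_params()) {
  if (length(runs) == 0L) stop("at least one run is required")
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids among runs")
  catalog_index <- build_peptide_index(catalog, dparams)
  reduced_dbs <- list(); identified <- list()
  for (run in runs) {
    res <- tryCatch({
      red <- step1_reduce(run, catalog, dparams, sparams, fparams,
                          index = catalog_index)
      ident <- step2_identify(run, red, fparams, dparams, sparams)
      list(red = red, ident = ident)
    }, error = function(e) {
      stop("sample ", run$sample_id, " failed: ", conditionMessage(e))
    })
    reduced_dbs[[run$sample_id]] <- res$red
    identified[[run$sample_id]] <- res$ident
  }
  combined_nr <- build_combined_nr(lapply(identified, `[[`, "proteins"))
  if (nrow(combined_nr) == 0L) {
    stop("no proteins identified in any sample; cannot quantify")
  }
  final_index <- build_peptide_index(add_decoys(combined_nr), dparams)
  final_psms <- list(); features <- list(); id_rate <- numeric(0)
  for (run in runs) {
    psms <- compute_qvalues(search_run(run, dparams = dparams,
                                       sparams = sparams,
                                       index = final_index))
    pass <- psms[psms$q <= fparams$fdr_cutoff &
                   psms$expect <= fparams$max_expect &
                   !psms$is_decoy, , drop = FALSE]
    rownames(pass) <- NULL
    final_psms[[run$sample_id]] <- pass
    features[[run$sample_id]] <- extract_features(run, pass)
    id_rate[run$sample_id] <- nrow(pass) / max(1L, length(run$spectra))
  }
  feat <- do.call(rbind, features)
  rownames(feat) <- NULL
  feat <- match_between_runs(feat, runs, final_psms, qparams)
  # peptide -> target accession map from passing final-search PSMs
  all_pass <- do.call(rbind, final_psms)
  pep2prot <- lapply(split(all_pass$accessions, all_pass$peptide),
                     function(a) {
                       u <- unique(unlist(strsplit(a, ";", fixed = TRUE)))
                       u[!startsWith(u, DECOY_PREFIX)]
                     })
  pep2prot <- pep2prot[lengths(pep2prot) > 0L]
  psm_counts <- table(all_pass$peptide)
  groups <- group_proteins(pep2prot,
                           psm_counts = stats::setNames(
                             as.integer(psm_counts), names(psm_counts)))
  groups <- assign_razor(groups)
  lfq <- maxlfq(groups, feat, qparams)
  peptide_table <- build_peptide_table(feat, sample_ids)
  protein_groups <- build_protein_group_table(groups, lfq)
  structure(list(reduced_dbs = reduced_dbs, identified = identified,
                 combined_nr = combined_nr, final_psms = final_psms,
                 features = feat, groups = groups,
                 peptide_table = peptide_table,
                 protein_groups = protein_groups, lfq = lfq,
                 id_rate = id_rate, sample_ids = sample_ids),
            class = "workflow_result")
}

# Wide peptide x sample intensity table with per-sample identification type.
build_peptide_table <- function(feat, sample_ids) {
  peps <- sort(unique(feat$peptide))
  tab <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  for (sid in sample_ids) {
    f <- feat[feat$sample_id == sid, , drop = FALSE]
    idx <- match(peps, f$peptide)
    tab[[paste0("intensity.", sid)]] <- f$intensity[idx]
    tab[[paste0("idtype.", sid)]] <- f$id_type[idx]
  }
  tab
}

build_protein_group_table <- function(groups, lfq) {
  tab <- data.frame(
    group_id = vapply(groups, `[[`, character(1), "group_id"),
    leading = vapply(groups, `[[`, character(1), "leading"),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"),
                     character(1)),
    n_peptides = vapply(groups, function(g) length(g$peptides), integer(1)),
    stringsAsFactors = FALSE)
  cbind(tab, as.data.frame(lfq[tab$group_id, , drop = FALSE]))
}

#' Per-sample identification rate of a workflow result
#' @param result a [run_workflow()] result.
#' @return Named numeric vector: identified MS/MS divided by acquired MS/MS.
#' @export
identification_rate <- function(result) result$id_rate
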