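#' Quantification parameters
#'
#' Defaults: 20 min retention-time alignment window, 5 min match window and
#' 10 ppm mass tolerance for transferring identifications between runs, and
#' a minimum ratio count of 1 for MaxLFQ pairwise ratios.
#'
#' @param rt_align_window minutes; shared identifications farther apart than
#'   this are excluded from the alignment fit.
#' @param match_window minutes; maximum distance between a candidate feature
#'   and the aligned donor retention time.
#' @param min_ratio_count minimum number of peptide pairs behind a pairwise
#'   sample ratio.
#' @param mbr_mz_tol_ppm precursor m/z tolerance for transfers (ppm).
#' @param min_shared_peptides minimum shared identifications needed to align
#'   a run pair.
#' @return A `quant_params` list.
#' @export
quant_params <- function(rt_align_window = 20, match_window = 5,
                         min_ratio_count = 1L, mbr_mz_tol_ppm = 10,
                         min_shared_peptides = 5L) {
  stopifnot(match_window <= rt_align_window)
  structure(list(rt_align_window = rt_align_window,
                 match_window = match_window,
                 min_ratio_count = as.integer(min_ratio_count),
                 mbr_mz_tol_ppm = mbr_mz_tol_ppm,
                 min_shared_peptides = as.integer(min_shared_peptides)),
            class = "quant_params")
}

#' Extract quantifiable peptide features from passing PSMs
#'
#' The feature intensity is the precursor intensity reported in the MGF
#' (second `PEPMASS` field); when absent, the summed raw fragment intensity
#' of the spectrum is used as a proxy. With `aggregate = TRUE` (default)
#' features are collapsed to one row per peptide sequence, summing
#' intensities and keeping the retention time and m/z of the most intense
#' occurrence.
#'
#' @param run an [ms_run()].
#' @param psms passing PSM rows for this run.
#' @param aggregate collapse to one feature per peptide sequence?
#' @return Data frame: `peptide`, `sample_id`, `intensity`, `rt`, `mz`,
#'   `charge`, `id_type` (`"msms"`).
#' @export
extract_features <- function(run, psms, aggregate = TRUE) {
  empty <- data.frame(peptide = character(0), sample_id = character(0),
                      intensity = numeric(0), rt = numeric(0),
                      mz = numeric(0), charge = integer(0),
                      id_type = character(0), stringsAsFactors = FALSE)
  if (nrow(psms) == 0L) return(empty)
  ids <- vapply(run$spectra, `[[`, character(1), "scan_id")
  idx <- match(psms$scan_id, ids)
  if (anyNA(idx)) stop("PSM scan_id not found in run ", run$sample_id)
  sp <- run$spectra[idx]
  inten <- vapply(sp, function(s) {
    if (is.finite(s$precursor_intensity)) s$precursor_intensity
    else sum(s$peaks[, 2L])
  }, numeric(1))
  keep <- is.finite(inten) & inten > 0
  if (!all(keep)) warning(sum(!keep), " features dropped (no intensity)")
  feat <- data.frame(peptide = psms$peptide[keep],
                     sample_id = run$sample_id,
                     intensity = inten[keep],
                     rt = vapply(sp[keep], `[[`, numeric(1), "rt"),
                     mz = vapply(sp[keep], `[[`, numeric(1), "precursor_mz"),
                     charge = psms$charge[keep],
                     id_type = "msms", stringsAsFactors = FALSE)
  if (!aggregate || nrow(feat) == 0L) return(feat)
  ord <- order(feat$peptide, -feat$intensity)
  feat <- feat[ord, , drop = FALSE]
  total <- tapply(feat$intensity, feat$peptide, sum)
  first <- feat[!duplicated(feat$peptide), , drop = FALSE]
  first$intensity <- as.numeric(total[first$peptide])
  rownames(first) <- NULL
  first
}

#' Transfer identifications between runs by aligned retention time and mass
#'
#' For every ordered pair of runs a LOWESS retention-time alignment is fit
#' on the peptides MS/MS-identified in both (within `rt_align_window`).
#' Donor peptides absent from the acceptor gain a `matched` feature when an
#' unidentified acceptor spectrum's precursor lies within `mbr_mz_tol_ppm`
#' of the donor m/z and within `match_window` minutes of the aligned
#' retention time (nearest in time wins; each acceptor spectrum is consumed
#' by at most one transfer). A peptide is never transferred into a run where
#' it was MS/MS-identified.
#'
#' @param feat feature table (rows from [extract_features()], all runs).
#' @param runs list of [ms_run()] objects.
#' @param psms_by_run named list of passing PSM tables (identifies which
#'   acceptor spectra are already explained).
#' @param params a [quant_params()].
#' @return `feat` with transferred rows appended (`id_type = "matched"`).
#' @export
match_between_runs <- function(feat, runs, psms_by_run,
                               params = quant_params()) {
  if (length(runs) < 2L) return(feat)
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  pools <- lapply(runs, function(run) {
    identified <- psms_by_run[[run$sample_id]]$scan_id
    cand <- run$spectra[!vapply(run$spectra, `[[`, character(1),
                                "scan_id") %in% identified]
    if (!length(cand)) {
      return(data.frame(mz = numeric(0), rt = numeric(0),
                        intensity = numeric(0), scan_id = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(mz = vapply(cand, `[[`, numeric(1), "precursor_mz"),
               rt = vapply(cand, `[[`, numeric(1), "rt"),
               intensity = vapply(cand, `[[`, numeric(1),
                                  "precursor_intensity"),
               scan_id = vapply(cand, `[[`, character(1), "scan_id"),
               stringsAsFactors = FALSE)
  })
  names(pools) <- sample_ids
  pools <- lapply(pools, function(p) {
    p[is.finite(p$intensity) & p$intensity > 0, , drop = FALSE]
  })
  new_rows <- list()
  msms <- feat[feat$id_type == "msms", , drop = FALSE]
  for (acceptor in sample_ids) {
    acc_pep <- feat$peptide[feat$sample_id == acceptor]
    pool <- pools[[acceptor]]
    for (donor in sample_ids) {
      if (donor == acceptor || nrow(pool) == 0L) next
      don <- msms[msms$sample_id == donor, , drop = FALSE]
      accf <- msms[msms$sample_id == acceptor, , drop = FALSE]
      shared <- intersect(don$peptide, accf$peptide)
      x <- don$rt[match(shared, don$peptide)]
      y <- accf$rt[match(shared, accf$peptide)]
      ok <- abs(x - y) <= params$rt_align_window
      x <- x[ok]; y <- y[ok]
      if (length(x) < params$min_shared_peptides) {
        warning("too few shared peptides to align ", donor, " -> ",
                acceptor, "; pair skipped")
        next
      }
      fit <- stats::lowess(x, y, f = 2 / 3)
      transfer <- don[!(don$peptide %in% acc_pep), , drop = FALSE]
      if (nrow(transfer) == 0L) next
      aligned <- stats::approx(fit$x, fit$y, xout = transfer$rt,
                               rule = 2, ties = mean)$y
      for (i in seq_len(nrow(transfer))) {
        dmz <- transfer$mz[i]
        hit <- which(abs(pool$mz - dmz) / dmz * 1e6 <= params$mbr_mz_tol_ppm &
                       abs(pool$rt - aligned[i]) <= params$match_window)
        if (!length(hit)) next
        best <- hit[which.min(abs(pool$rt[hit] - aligned[i]))]
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          peptide = transfer$peptide[i], sample_id = acceptor,
          intensity = pool$intensity[best], rt = pool$rt[best],
          mz = pool$mz[best], charge = transfer$charge[i],
          id_type = "matched", stringsAsFactors = FALSE)
        pool <- pool[-best, , drop = FALSE]
        acc_pep <- c(acc_pep, transfer$peptide[i])
      }
    }
    pools[[acceptor]] <- pool
  }
  if (length(new_rows)) feat <- rbind(feat, do.call(rbind, new_rows))
  rownames(feat) <- NULL
  feat
}

#' Group proteins by the shared/subset peptide rule
#'
#' Proteins identified by the same set or a subset of another protein's
#' peptides are merged into that protein's group. Proteins are ranked by
#' number of peptide sequences, then number of PSMs, then sequence coverage
#' (descending), with lexicographic accession as the final tie-break; the
#' top-ranked member is the leading protein and the group id.
#'
#' @param pep2prot named list: peptide sequence -> accession vector.
#' @param psm_counts optional named integer vector of PSM counts per
#'   peptide.
#' @param coverage optional named numeric vector of sequence coverage per
#'   accession.
#' @return List of `protein_group` lists: `group_id`, `members`, `leading`,
#'   `peptides`, `n_psms`.
#' @export
group_proteins <- function(pep2prot, psm_counts = NULL, coverage = NULL) {
  if (!length(pep2prot)) return(list())
  prot2pep <- list()
  for (pep in names(pep2prot)) {
    for (acc in pep2prot[[pep]]) prot2pep[[acc]] <- c(prot2pep[[acc]], pep)
  }
  prot2pep <- lapply(prot2pep, unique)
  accs <- names(prot2pep)
  npep <- lengths(prot2pep)
  npsm <- vapply(prot2pep, function(p) {
    if (is.null(psm_counts)) 0L else sum(psm_counts[p], na.rm = TRUE)
  }, numeric(1))
  cov <- if (is.null(coverage)) rep(0, length(accs)) else {
    ifelse(is.na(coverage[accs]), 0, coverage[accs])
  }
  ord <- order(-npep, -npsm, -cov, accs)
  groups <- list()
  for (i in ord) {
    peps <- prot2pep[[i]]
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(peps %in% groups[[g]]$peptides)) {
        groups[[g]]$members <- c(groups[[g]]$members, accs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- list(
        group_id = accs[i], members = accs[i], leading = accs[i],
        peptides = sort(peps), n_psms = npsm[i])
    }
  }
  lapply(groups, function(g) structure(g, class = "protein_group"))
}

#' Assign shared peptides to protein groups as razor peptides
#'
#' A peptide occurring in the peptide set of several groups is assigned, for
#' quantification only, to the group with the most peptide evidence (most
#' distinct peptides, then most PSMs, then lexicographic leading accession).
#'
#' @param groups result of [group_proteins()].
#' @return `groups` with `quant_peptides` (unique + razor) and
#'   `peptide_classes` per group, and an `assignment` attribute mapping each
#'   peptide to its quantification group and class (`unique`/`razor`).
#' @export
assign_razor <- function(groups) {
  if (!length(groups)) return(groups)
  gid <- vapply(groups, `[[`, character(1), "group_id")
  npep <- vapply(groups, function(g) length(g$peptides), integer(1))
  npsm <- vapply(groups, function(g) as.numeric(g$n_psms), numeric(1))
  pep_groups <- list()
  for (g in seq_along(groups)) {
    for (pep in groups[[g]]$peptides) {
      pep_groups[[pep]] <- c(pep_groups[[pep]], g)
    }
  }
  assignment <- data.frame(peptide = names(pep_groups),
                           group_id = NA_character_, class = NA_character_,
                           stringsAsFactors = FALSE)
  for (k in seq_along(pep_groups)) {
    gs <- pep_groups[[k]]
    if (length(gs) == 1L) {
      assignment$group_id[k] <- gid[gs]
      assignment$class[k] <- "unique"
    } else {
      ord <- order(-npep[gs], -npsm[gs], gid[gs])
      assignment$group_id[k] <- gid[gs[ord[1L]]]
      assignment$class[k] <- "razor"
    }
  }
  groups <- lapply(groups, function(g) {
    mine <- assignment$peptide[assignment$group_id == g$group_id]
    g$quant_peptides <- sort(mine)
    cls <- ifelse(g$peptides %in% mine,
                  assignment$class[match(g$peptides, assignment$peptide)],
                  "shared-out")
    g$peptide_classes <- stats::setNames(cls, g$peptides)
    g
  })
  attr(groups, "assignment") <- assignment
  groups
}

#' MaxLFQ-style protein-group intensities
#'
#' Per group, the median of log peptide-intensity ratios is computed for
#' every sample pair sharing at least `min_ratio_count` quantified peptides;
#' per connected component of the resulting ratio graph, per-sample log
#' abundances are reconstructed by least squares and rescaled so the summed
#' LFQ equals the summed raw intensity of the group's peptides in those
#' samples. Samples outside any connected component stay missing.
#'
#' @param groups razor-assigned groups from [assign_razor()].
#' @param feat feature table (after [match_between_runs()]).
#' @param params a [quant_params()].
#' @return Numeric matrix (groups x samples) of LFQ intensities with `NA`
#'   for missing values; rownames are group ids.
#' @export
maxlfq <- function(groups, feat, params = quant_params()) {
  samples <- unique(feat$sample_id)
  lfq <- matrix(NA_real_, nrow = length(groups), ncol = length(samples),
                dimnames = list(vapply(groups, `[[`, character(1),
                                       "group_id"), samples))
  if (!length(groups)) return(lfq)
  key <- paste(feat$peptide, feat$sample_id, sep = "\r")
  inten <- tapply(feat$intensity, key, sum)
  for (g in seq_along(groups)) {
    peps <- groups[[g]]$quant_peptides %||% groups[[g]]$peptides
    if (!length(peps)) next
    mat <- matrix(NA_real_, length(peps), length(samples),
                  dimnames = list(peps, samples))
    for (s in seq_along(samples)) {
      v <- inten[paste(peps, samples[s], sep = "\r")]
      mat[, s] <- as.numeric(v)
    }
    lfq[g, ] <- maxlfq_profile(mat, params$min_ratio_count)
  }
  lfq
}

# Delayed-normalization profile for one group: pairwise median log ratios,
# least squares per connected component, rescaled to the raw total.
maxlfq_profile <- function(mat, min_ratio_count = 1L) {
  ns <- ncol(mat)
  out <- rep(NA_real_, ns)
  obs <- colSums(!is.na(mat) & mat > 0) > 0
  edges <- list()
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      both <- !is.na(mat[, i]) & !is.na(mat[, j]) & mat[, i] > 0 &
        mat[, j] > 0
      if (sum(both) >= min_ratio_count) {
        r <- stats::median(log(mat[both, i] / mat[both, j]))
        edges[[length(edges) + 1L]] <- c(i, j, r)
      }
    }
  }
  adj <- lapply(seq_len(ns), function(i) integer(0))
  for (e in edges) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  comp <- rep(NA_integer_, ns)
  cid <- 0L
  for (s in which(obs)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    raw_total <- sum(mat[, members], na.rm = TRUE)
    if (length(members) == 1L) {
      out[members] <- raw_total
      next
    }
    ce <- Filter(function(e) e[1L] %in% members, edges)
    idx <- match(seq_len(ns), members)
    a_rows <- lapply(ce, function(e) {
      row <- rep(0, length(members))
      row[idx[e[1L]]] <- 1
      row[idx[e[2L]]] <- -1
      row
    })
    amat <- do.call(rbind, a_rows)
    b <- vapply(ce, `[`, numeric(1), 3L)
    # anchor the free global offset: mean log abundance = 0
    amat <- rbind(amat, rep(1, length(members)))
    b <- c(b, 0)
    x <- stats::lm.fit(amat, b)$coefficients
    prof <- exp(x)
    out[members] <- prof * raw_total / sum(prof)
  }
  out
}
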