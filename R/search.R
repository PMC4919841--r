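#' Search parameters
#'
#' Defaults: 10 ppm parent tolerance, 20 ppm fragment tolerance, charges 2+
#' and 3+ tried when the precursor charge is unknown, best hit reported.
#'
#' The expect-value estimator needs a score distribution over many scored
#' candidates; desk-scale databases rarely place enough peptide forms inside
#' a 10 ppm precursor window, so a wider background pool (`bg_window_da`,
#' deterministically thinned to at most `bg_max` forms) is scored alongside
#' the precursor-window candidates solely to fit the survival curve.
#'
#' @param parent_tol_ppm precursor mass tolerance (ppm).
#' @param frag_tol_ppm fragment m/z tolerance (ppm).
#' @param charges_tried charges assumed when the precursor charge is unknown.
#' @param max_rank number of hits reported per spectrum (only 1 supported).
#' @param bg_window_da half-width (Da) of the background mass window used for
#'   expect-value estimation.
#' @param bg_max cap on background candidates scored per spectrum/charge.
#' @param min_candidates minimum scored candidates for a survival fit;
#'   spectra below it get expect = 1 (degenerate flag).
#' @param top_n,min_mz peak-filter settings passed to
#'   [preprocess_spectrum()].
#' @return A `search_params` list.
#' @export
search_params <- function(parent_tol_ppm = 10, frag_tol_ppm = 20,
                          charges_tried = c(2L, 3L), max_rank = 1L,
                          bg_window_da = 50, bg_max = 300L,
                          min_candidates = 20L, top_n = 50L, min_mz = 150) {
  stopifnot(parent_tol_ppm > 0, frag_tol_ppm > 0, length(charges_tried) >= 1)
  structure(list(parent_tol_ppm = parent_tol_ppm,
                 frag_tol_ppm = frag_tol_ppm,
                 charges_tried = as.integer(charges_tried),
                 max_rank = as.integer(max_rank),
                 bg_window_da = bg_window_da, bg_max = as.integer(bg_max),
                 min_candidates = as.integer(min_candidates),
                 top_n = as.integer(top_n), min_mz = min_mz),
            class = "search_params")
}

#' Candidate peptide forms for a precursor
#'
#' Returns all indexed peptide forms whose neutral mass lies within
#' `parent_tol_ppm` of the neutral mass implied by the precursor m/z and
#' charge.
#'
#' @param index a [build_peptide_index()] result.
#' @param precursor_mz precursor m/z.
#' @param charge known charge state.
#' @param params a [search_params()] object.
#' @return Rows of `index$forms`.
#' @export
get_candidates <- function(index, precursor_mz, charge,
                           params = search_params()) {
  m <- neutral_mass(precursor_mz, charge)
  tol <- m * params$parent_tol_ppm * 1e-6
  query_mass_window(index, m - tol, m + tol)
}

#' Hyperscore of a peptide against a spectrum
#'
#' Singly charged b- and y-ion m/z values are computed for the modified
#' peptide; a fragment matches when a peak lies within `frag_tol_ppm`, each
#' peak pairing with at most one fragment (smallest ppm error wins). The
#' score is the sum of matched (preprocessed) peak intensities times the
#' factorials of the matched b- and y-ion counts, factorials capped at 10!.
#'
#' @param s a [spectrum()]; preprocessed automatically if not already.
#' @param sequence peptide sequence.
#' @param mod_pos semicolon-joined variable-modification positions (`""` for
#'   none).
#' @param frag_tol_ppm fragment tolerance (ppm).
#' @param params a [digest_params()] supplying the modification masses.
#' @return List with `score`, `n_b`, `n_y`, `dot` (matched intensity sum).
#' @export
hyperscore <- function(s, sequence, mod_pos = "", frag_tol_ppm = 20,
                       params = digest_params()) {
  s <- preprocess_spectrum(s)
  res <- residue_masses(sequence, mod_pos, params)
  out <- score_batch_cpp(s$peaks[, 1L], s$peaks[, 2L], list(res),
                         frag_tol_ppm, PROTON_MASS, WATER_MASS)
  list(score = out$score[1L], n_b = out$n_b[1L], n_y = out$n_y[1L],
       dot = out$dot[1L])
}

#' Expect value from the candidate score distribution
#'
#' The factorial-scaled hyperscore spans many orders of magnitude, so the
#' survival histogram is built on the log scale, `4 * log10(1 + score)`
#' (the scale on which search engines conventionally report hyperscores),
#' with unit bin width. The log10 survival counts of the contiguous
#' descending tail above the modal bin are fit by a least-squares line —
#' isolated high-score outlier bins beyond the first gap wider than 2 units
#' (the genuine hits themselves) are excluded from the fit — and the expect
#' value extrapolates that line to the best score:
#' `10^(a + b * bin(best))`, clamped to (1e-20, 1e3]. Fewer than
#' `min_candidates` scored candidates, fewer than 3 tail bins, or a
#' non-negative fitted slope yield the degenerate fallback expect = 1.
#'
#' @param best best hyperscore for the spectrum.
#' @param all_scores hyperscores of all scored candidates (background pool).
#' @param min_candidates candidate-count threshold for a fit.
#' @return List with `expect` and logical `degenerate`.
#' @export
expect_value <- function(best, all_scores, min_candidates = 20L) {
  if (length(all_scores) < min_candidates) {
    return(list(expect = 1, degenerate = TRUE))
  }
  fit <- fit_score_tail(score_bin(all_scores))
  if (!fit$ok) return(list(expect = 1, degenerate = TRUE))
  e <- 10^(fit$a + fit$b * score_bin(best))
  list(expect = min(1e3, max(1e-20, e)), degenerate = FALSE)
}

# Hyperscore histogram bin: unit bins on the conventional log scale.
score_bin <- function(score) floor(4 * log10(1 + score))

# Least-squares line through log10 survival counts of the contiguous
# descending tail above the modal bin; isolated outlier bins beyond the
# first gap wider than 2 units are the genuine hits and are excluded.
fit_score_tail <- function(bins) {
  ub <- sort(unique(bins))
  counts <- vapply(ub, function(b) sum(bins == b), numeric(1))
  mode_bin <- ub[which.max(counts)]
  tail_bins <- ub[ub > mode_bin]
  if (length(tail_bins) >= 2L) {
    gaps <- diff(tail_bins)
    cut <- which(gaps > 2L)
    if (length(cut)) tail_bins <- tail_bins[seq_len(cut[1L])]
  }
  if (length(tail_bins) < 3L) return(list(ok = FALSE))
  surv <- vapply(tail_bins, function(b) sum(bins >= b), numeric(1))
  fit <- stats::lm.fit(cbind(1, tail_bins), log10(surv))
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  if (!is.finite(b) || b >= 0) return(list(ok = FALSE))
  list(ok = TRUE, a = unname(a), b = unname(b))
}

# Pre-compute per-residue mass vectors for every indexed peptide form.
form_residue_masses <- function(index) {
  cache <- index$cache
  if (!is.null(cache) && !is.null(cache$res_masses)) return(cache$res_masses)
  forms <- index$forms
  rm_list <- lapply(seq_len(nrow(forms)), function(i) {
    residue_masses(forms$sequence[i], forms$mod_pos[i], index$params)
  })
  if (!is.null(cache)) cache$res_masses <- rm_list
  rm_list
}

empty_psm_df <- function() {
  data.frame(scan_id = character(0), peptide = character(0),
             mod_pos = character(0), charge = integer(0),
             mass = numeric(0), hyperscore = numeric(0),
             n_b = integer(0), n_y = integer(0), expect = numeric(0),
             expect_degenerate = logical(0), accessions = character(0),
             is_decoy = logical(0), stringsAsFactors = FALSE)
}

# Deterministic thinning of background rows to at most n by regular stride.
stride_subset <- function(rows, n) {
  if (length(rows) <= n) return(rows)
  rows[unique(round(seq(1L, length(rows), length.out = n)))]
}

#' Search a run against a protein database
#'
#' For each searchable spectrum the best-hyperscore candidate within the
#' precursor tolerance is reported as one PSM (ties broken by lexicographic
#' peptide sequence, then modification positions). Spectra with unknown
#' precursor charge are searched at every charge in `params$charges_tried`
#' and the global best is kept.
#'
#' @param run an [ms_run()].
#' @param db a [protein_db()]; ignored when `index` is supplied.
#' @param dparams a [digest_params()].
#' @param sparams a [search_params()].
#' @param index optional prebuilt [build_peptide_index()] of `db`.
#' @return Data frame of PSMs: `scan_id`, `peptide`, `mod_pos`, `charge`,
#'   `mass`, `hyperscore`, `n_b`, `n_y`, `expect`, `expect_degenerate`,
#'   `accessions` (semicolon-joined), `is_decoy`.
#' @export
search_run <- function(run, db = NULL, dparams = digest_params(),
                       sparams = search_params(), index = NULL) {
  if (is.null(index)) {
    if (is.null(db) || nrow(db) == 0L) stop("db (or index) required")
    index <- build_peptide_index(db, dparams)
  }
  res_masses <- form_residue_masses(index)
  forms <- index$forms
  masses <- forms$mass
  hits <- vector("list", length(run$spectra))
  for (si in seq_along(run$spectra)) {
    s <- preprocess_spectrum(run$spectra[[si]], sparams$top_n, sparams$min_mz)
    if (!isTRUE(attr(s, "searchable"))) next
    charges <- if (is.na(s$charge)) sparams$charges_tried else s$charge
    best <- NULL
    bg_scores <- numeric(0)
    bg_rows_all <- integer(0)
    for (z in charges) {
      m <- neutral_mass(s$precursor_mz, z)
      tol <- m * sparams$parent_tol_ppm * 1e-6
      lo <- findInterval(m - tol, masses, left.open = TRUE) + 1L
      hi <- findInterval(m + tol, masses)
      cand_rows <- if (hi >= lo) lo:hi else integer(0)
      blo <- findInterval(m - sparams$bg_window_da, masses,
                          left.open = TRUE) + 1L
      bhi <- findInterval(m + sparams$bg_window_da, masses)
      bg_rows <- if (bhi >= blo) stride_subset(blo:bhi, sparams$bg_max)
                 else integer(0)
      rows <- unique(c(cand_rows, bg_rows))
      if (!length(rows)) next
      sc <- score_batch_cpp(s$peaks[, 1L], s$peaks[, 2L],
                            res_masses[rows], sparams$frag_tol_ppm,
                            PROTON_MASS, WATER_MASS)
      bg_scores <- c(bg_scores, sc$score)
      bg_rows_all <- c(bg_rows_all, rows)
      if (!length(cand_rows)) next
      ci <- match(cand_rows, rows)
      ord <- order(-sc$score[ci], forms$sequence[cand_rows],
                   forms$mod_pos[cand_rows])
      top <- ci[ord[1L]]
      row <- cand_rows[ord[1L]]
      cand_best <- list(row = row, score = sc$score[top], n_b = sc$n_b[top],
                        n_y = sc$n_y[top], charge = z)
      if (is.null(best) || cand_best$score > best$score ||
          (cand_best$score == best$score &&
           forms$sequence[cand_best$row] < forms$sequence[best$row])) {
        best <- cand_best
      }
    }
    if (is.null(best) || best$score <= 0) next
    hits[[si]] <- list(scan_id = s$scan_id, best = best,
                       bg_bins = score_bin(bg_scores), bg_rows = bg_rows_all,
                       n_bg = length(bg_scores))
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty_psm_df())
  # Run-level pooled null: per-spectrum candidate pools are far too sparse
  # for a survival fit at ppm-level fragment tolerances (random candidates
  # almost always match zero fragments), so the null score distribution is
  # pooled over all spectra of the run. Every candidate form of a
  # spectrum's best-hit peptide sequence is excluded from the pool so
  # genuine matches cannot flatten the null tail.
  null_bins <- unlist(lapply(hits, function(h) {
    keep <- forms$sequence[h$bg_rows] != forms$sequence[h$best$row]
    h$bg_bins[keep]
  }), use.names = FALSE)
  pooled <- if (length(null_bins)) fit_score_tail(null_bins)
            else list(ok = FALSE)
  out <- lapply(hits, function(h) {
    if (pooled$ok && h$n_bg > 0L) {
      prob <- 10^(pooled$a + pooled$b * score_bin(h$best$score)) /
        length(null_bins)
      ev <- list(expect = min(1e3, max(1e-20, h$n_bg * prob)),
                 degenerate = FALSE)
    } else {
      ev <- expect_value_binned(score_bin(h$best$score), h$bg_bins,
                                sparams$min_candidates)
    }
    accs <- peptide_proteins(index, forms$sequence[h$best$row])
    data.frame(
      scan_id = h$scan_id, peptide = forms$sequence[h$best$row],
      mod_pos = forms$mod_pos[h$best$row], charge = h$best$charge,
      mass = forms$mass[h$best$row], hyperscore = h$best$score,
      n_b = h$best$n_b, n_y = h$best$n_y, expect = ev$expect,
      expect_degenerate = ev$degenerate,
      accessions = paste(accs, collapse = ";"),
      is_decoy = all(startsWith(accs, DECOY_PREFIX)),
      stringsAsFactors = FALSE)
  })
  psms <- do.call(rbind, out)
  rownames(psms) <- NULL
  psms
}

# expect_value on pre-binned scores (avoids re-binning in the hot loop).
expect_value_binned <- function(best_bin, bg_bins, min_candidates) {
  if (length(bg_bins) < min_candidates) {
    return(list(expect = 1, degenerate = TRUE))
  }
  fit <- fit_score_tail(bg_bins)
  if (!fit$ok) return(list(expect = 1, degenerate = TRUE))
  e <- 10^(fit$a + fit$b * best_bin)
  list(expect = min(1e3, max(1e-20, e)), degenerate = FALSE)
}
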