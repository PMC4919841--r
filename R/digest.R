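# Monoisotopic residue masses (Da, 6 decimals), proton and water constants.
AA_MONO <- c(G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
             V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
             I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
             K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
             F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Digestion parameters
#'
#' Defaults encode standard bottom-up settings: trypsin/P (cleavage
#' C-terminal to K or R with no proline exception), up to two missed
#' cleavages, fixed carbamidomethylation of cysteine (+57.021464 Da) and
#' variable oxidation of methionine (+15.994915 Da).
#'
#' @param enzyme only `"trypsin_p"` is supported.
#' @param max_missed maximum number of missed cleavage sites (default 2).
#' @param min_len,max_len peptide length bounds (defaults 7 and 45).
#' @param fixed_mods named numeric vector, residue letter to mass delta (Da),
#'   always applied.
#' @param var_mods named numeric vector of variable modifications; every
#'   combination of up to `max_var_mods` sites is enumerated.
#' @param max_var_mods cap on simultaneous variable modifications (default 3).
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = "trypsin_p", max_missed = 2L,
                          min_len = 7L, max_len = 45L,
                          fixed_mods = c(C = 57.021464),
                          var_mods = c(M = 15.994915),
                          max_var_mods = 3L) {
  enzyme <- match.arg(enzyme, "trypsin_p")
  stopifnot(max_missed >= 0L, min_len >= 1L, max_len >= min_len,
            max_var_mods >= 0L)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 fixed_mods = fixed_mods, var_mods = var_mods,
                 max_var_mods = as.integer(max_var_mods)),
            class = "digest_params")
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' deltas.
#'
#' @param sequence peptide amino-acid string (canonical residues only).
#' @param mod_deltas numeric vector of modification mass deltas (Da).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, mod_deltas = numeric(0)) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- AA_MONO[res]
  if (anyNA(m)) {
    stop("unknown residue in peptide: ", paste(res[is.na(m)], collapse = ""))
  }
  sum(m) + WATER_MASS + sum(mod_deltas)
}

#' Precursor m/z from neutral mass and charge
#'
#' @param mono_mass neutral monoisotopic mass (Da).
#' @param charge positive integer charge state.
#' @return `(mono_mass + charge * 1.007276) / charge`.
#' @export
precursor_mz <- function(mono_mass, charge) {
  if (any(charge <= 0)) stop("charge must be >= 1")
  (mono_mass + charge * PROTON_MASS) / charge
}

#' Neutral mass from precursor m/z and charge
#' @param mz precursor m/z.
#' @param charge positive integer charge state.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, charge) {
  if (any(charge <= 0)) stop("charge must be >= 1")
  mz * charge - charge * PROTON_MASS
}

# Cleave a residue vector after K/R (trypsin/P); returns 0-missed fragment
# boundaries as (start, end) pairs.
tryptic_boundaries <- function(res) {
  n <- length(res)
  cuts <- which(res == "K" | res == "R")
  cuts <- cuts[cuts < n]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  cbind(starts, ends)
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves C-terminal to K or R (no proline exception) with 0 to
#' `params$max_missed` missed cleavages, applies the length filter, skips
#' peptides containing non-canonical residues, and expands each peptide into
#' modified forms (fixed modifications always applied; variable-modification
#' site combinations enumerated up to `params$max_var_mods`).
#'
#' @param sequence protein amino-acid string.
#' @param params a [digest_params()] object.
#' @return Data frame with columns `sequence`, `missed`, `mod_pos`
#'   (semicolon-joined 1-based variable-modification positions, `""` if
#'   none), `mod_mass` (total variable delta), `mass` (neutral monoisotopic,
#'   fixed mods included).
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bounds <- tryptic_boundaries(res)
  nfrag <- nrow(bounds)
  out_seq <- character(0); out_missed <- integer(0)
  for (j in 0:params$max_missed) {
    if (j + 1L > nfrag) break
    i <- seq_len(nfrag - j)
    starts <- bounds[i, 1L]
    ends <- bounds[i + j, 2L]
    len <- ends - starts + 1L
    ok <- len >= params$min_len & len <= params$max_len
    if (!any(ok)) next
    peps <- substring(paste(res, collapse = ""), starts[ok], ends[ok])
    out_seq <- c(out_seq, peps)
    out_missed <- c(out_missed, rep(j, sum(ok)))
  }
  if (!length(out_seq)) return(empty_peptide_df())
  canon <- !grepl(paste0("[^", paste(names(AA_MONO), collapse = ""), "]"),
                  out_seq)
  out_seq <- out_seq[canon]; out_missed <- out_missed[canon]
  if (!length(out_seq)) return(empty_peptide_df())
  expand_mods(out_seq, out_missed, params)
}

empty_peptide_df <- function() {
  data.frame(sequence = character(0), missed = integer(0),
             mod_pos = character(0), mod_mass = numeric(0),
             mass = numeric(0), stringsAsFactors = FALSE)
}

# Enumerate variable-modification site combinations for each peptide and
# compute neutral masses (fixed mods folded in).
expand_mods <- function(seqs, missed, params) {
  base_mass <- vapply(strsplit(seqs, "", fixed = TRUE), function(r) {
    m <- sum(AA_MONO[r]) + WATER_MASS
    for (aa in names(params$fixed_mods)) {
      m <- m + params$fixed_mods[[aa]] * sum(r == aa)
    }
    m
  }, numeric(1))
  var_res <- names(params$var_mods)
  n <- length(seqs)
  pos_chunks <- vector("list", n)
  dm_chunks <- vector("list", n)
  for (i in seq_len(n)) {
    r <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    sites <- which(r %in% var_res)
    combos <- list(integer(0))
    if (length(sites) && params$max_var_mods > 0L) {
      kmax <- min(length(sites), params$max_var_mods)
      for (k in seq_len(kmax)) {
        picks <- utils::combn(seq_along(sites), k, simplify = FALSE)
        combos <- c(combos, lapply(picks, function(ii) sites[ii]))
      }
    }
    pos_chunks[[i]] <- vapply(combos, paste, character(1), collapse = ";")
    dm_chunks[[i]] <- vapply(combos, function(cb) {
      if (length(cb)) sum(params$var_mods[r[cb]]) else 0
    }, numeric(1))
  }
  nrep <- lengths(pos_chunks)
  idx <- rep.int(seq_len(n), nrep)
  dm <- unlist(dm_chunks, use.names = FALSE)
  data.frame(sequence = seqs[idx], missed = missed[idx],
             mod_pos = unlist(pos_chunks, use.names = FALSE),
             mod_mass = dm, mass = base_mass[idx] + dm,
             stringsAsFactors = FALSE)
}

# Per-residue mass vector for a modified peptide form (fixed mods applied to
# their residues, variable deltas added at mod_pos). Used for fragment ladders.
residue_masses <- function(sequence, mod_pos = "", params = digest_params()) {
  r <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- AA_MONO[r]
  if (anyNA(m)) stop("unknown residue in peptide: ", sequence)
  m <- unname(m)
  for (aa in names(params$fixed_mods)) {
    m[r == aa] <- m[r == aa] + params$fixed_mods[[aa]]
  }
  if (nzchar(mod_pos)) {
    pos <- as.integer(strsplit(mod_pos, ";", fixed = TRUE)[[1L]])
    m[pos] <- m[pos] + unname(params$var_mods[r[pos]])
  }
  m
}

#' Build a peptide index over a protein database
#'
#' Digests every record and builds (i) a map from peptide sequence to all
#' accessions containing it and (ii) a mass-sorted table of modified peptide
#' forms for precursor-window range queries.
#'
#' @param db a [protein_db()] object (may include decoys).
#' @param params a [digest_params()] object.
#' @return A `peptide_index` list with elements `forms` (data frame sorted by
#'   `mass`), `pep2prot` (named list, peptide sequence to accession vector),
#'   `params`, `db`.
#' @export
build_peptide_index <- function(db, params = digest_params()) {
  if (nrow(db) == 0L) stop("cannot index an empty database")
  per_prot <- lapply(seq_len(nrow(db)), function(i) {
    d <- digest_protein(db$sequence[i], params)
    if (nrow(d)) d$accession <- db$accession[i]
    d
  })
  all <- do.call(rbind, per_prot[vapply(per_prot, nrow, integer(1)) > 0L])
  if (is.null(all) || nrow(all) == 0L) {
    stop("database yields no digestible peptides")
  }
  pep2prot <- lapply(split(all$accession, all$sequence), unique)
  key <- paste(all$sequence, all$mod_pos, sep = "|")
  forms <- all[!duplicated(key),
               c("sequence", "missed", "mod_pos", "mod_mass", "mass")]
  forms <- forms[order(forms$mass), , drop = FALSE]
  rownames(forms) <- NULL
  structure(list(forms = forms, pep2prot = pep2prot, params = params,
                 db = db, cache = new.env(parent = emptyenv())),
            class = "peptide_index")
}

#' Query the index for peptide forms in a mass window
#'
#' @param index a [build_peptide_index()] result.
#' @param lo,hi neutral mass window bounds (Da).
#' @return Rows of `index$forms` with `lo <= mass <= hi`.
#' @export
query_mass_window <- function(index, lo, hi) {
  m <- index$forms$mass
  i1 <- findInterval(lo, m, left.open = TRUE) + 1L
  i2 <- findInterval(hi, m)
  if (i2 < i1) return(index$forms[0L, , drop = FALSE])
  index$forms[i1:i2, , drop = FALSE]
}

#' Accessions containing a peptide sequence
#' @param index a [build_peptide_index()] result.
#' @param sequence peptide sequence.
#' @return Character vector of accessions (empty if absent).
#' @export
peptide_proteins <- function(index, sequence) {
  index$pep2prot[[sequence]] %||% character(0)
}
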