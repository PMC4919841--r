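#' Construct a spectrum object
#'
#' @param scan_id unique scan identifier within a run.
#' @param precursor_mz precursor m/z.
#' @param charge integer charge state or `NA` if unknown.
#' @param rt retention time in minutes.
#' @param peaks two-column numeric matrix (`mz`, `intensity`), sorted by mz.
#' @param precursor_intensity precursor intensity if known (`NA` otherwise).
#' @return A `spectrum` list.
#' @export
spectrum <- function(scan_id, precursor_mz, charge = NA_integer_, rt = 0,
                     peaks = matrix(numeric(0), 0, 2),
                     precursor_intensity = NA_real_) {
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge), rt = as.numeric(rt),
                 peaks = peaks,
                 precursor_intensity = as.numeric(precursor_intensity)),
            class = "spectrum")
}

#' Construct a run (one sample's spectra)
#'
#' @param sample_id sample identifier.
#' @param spectra list of [spectrum()] objects; ordered by retention time.
#' @param source_path originating file path, if any.
#' @return An `ms_run` list.
#' @export
ms_run <- function(sample_id, spectra, source_path = NA_character_) {
  ids <- vapply(spectra, `[[`, character(1), "scan_id")
  if (anyDuplicated(ids)) {
    stop("duplicate scan_id within run: ", ids[duplicated(ids)][1L])
  }
  rt <- vapply(spectra, `[[`, numeric(1), "rt")
  structure(list(sample_id = sample_id, spectra = spectra[order(rt)],
                 source_path = source_path),
            class = "ms_run")
}

#' Read an MGF file into a run
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` is required per block
#' (blocks without it are skipped with a warning); its optional second field
#' is stored as the precursor intensity. `RTINSECONDS` is converted to
#' minutes; a missing `CHARGE` is recorded as unknown (`NA`) and expanded
#' over the configured charge list at search time.
#'
#' @param path MGF file path.
#' @param sample_id sample identifier (defaults to file name without
#'   extension).
#' @return An [ms_run()] object.
#' @export
read_mgf <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  }
  spectra <- vector("list", length(starts))
  skipped <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pm <- get("PEPMASS")
    if (is.na(pm)) {
      warning("MGF block ", b, " has no PEPMASS; skipped")
      skipped <- skipped + 1L
      next
    }
    pm_fields <- strsplit(trimws(pm), "[ \t]+")[[1L]]
    prec_mz <- as.numeric(pm_fields[1L])
    prec_int <- if (length(pm_fields) >= 2L) as.numeric(pm_fields[2L]) else NA_real_
    ch <- get("CHARGE")
    charge <- if (is.na(ch)) NA_integer_ else {
      as.integer(sub("\\+$", "", trimws(ch)))
    }
    rt_s <- get("RTINSECONDS")
    rt <- if (is.na(rt_s)) 0 else as.numeric(rt_s) / 60
    title <- get("TITLE")
    scan_id <- if (is.na(title)) paste0("scan_", b) else trimws(title)
    pk <- if (length(peak_lines)) {
      vals2 <- suppressWarnings(
        lapply(strsplit(trimws(peak_lines), "[ \t]+"), as.numeric))
      if (any(vapply(vals2, function(v) length(v) < 2L || anyNA(v[1:2]),
                     logical(1)))) {
        stop("malformed peak line near line ",
             starts[b] + which(!is_kv)[1L], " in ", path)
      }
      matrix(c(vapply(vals2, `[`, numeric(1), 1L),
               vapply(vals2, `[`, numeric(1), 2L)), ncol = 2)
    } else matrix(numeric(0), 0, 2)
    spectra[[b]] <- spectrum(scan_id, prec_mz, charge, rt, pk, prec_int)
  }
  spectra <- spectra[!vapply(spectra, is.null, logical(1))]
  run <- ms_run(sample_id, spectra, source_path = path)
  attr(run, "n_blocks") <- length(starts)
  attr(run, "n_skipped") <- skipped
  run
}

#' Write a run to MGF
#'
#' @param run an [ms_run()] object.
#' @param path output MGF path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in run$spectra) {
    pm <- if (!is.na(s$precursor_intensity)) {
      sprintf("%.6f %.6f", s$precursor_mz, s$precursor_intensity)
    } else sprintf("%.6f", s$precursor_mz)
    head <- c("BEGIN IONS",
              paste0("TITLE=", s$scan_id),
              paste0("PEPMASS=", pm),
              if (!is.na(s$charge)) paste0("CHARGE=", s$charge, "+"),
              sprintf("RTINSECONDS=%.4f", s$rt * 60))
    writeLines(head, con)
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks[, 1L], s$peaks[, 2L]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Preprocess a spectrum for scoring
#'
#' Removes peaks below `min_mz`, keeps at most `top_n` most intense peaks,
#' square-root transforms intensities and normalizes so the maximum is 1.
#' Duplicate m/z values are collapsed to their most intense peak so the peak
#' list is strictly increasing in m/z. Idempotent.
#'
#' @param s a [spectrum()].
#' @param top_n maximum number of peaks retained (default 50).
#' @param min_mz lower m/z cutoff (default 150).
#' @return The preprocessed spectrum; attribute `searchable` is `FALSE` when
#'   no peaks remain.
#' @export
preprocess_spectrum <- function(s, top_n = 50L, min_mz = 150) {
  if (isTRUE(attr(s, "preprocessed"))) return(s)
  pk <- s$peaks
  pk <- pk[pk[, 1L] >= min_mz, , drop = FALSE]
  if (nrow(pk) > top_n) {
    keep <- order(pk[, 2L], decreasing = TRUE)[seq_len(top_n)]
    pk <- pk[sort(keep), , drop = FALSE]
  }
  if (nrow(pk)) {
    # collapse duplicate m/z to the strongest peak
    if (anyDuplicated(pk[, 1L])) {
      pk <- pk[order(pk[, 1L], -pk[, 2L]), , drop = FALSE]
      pk <- pk[!duplicated(pk[, 1L]), , drop = FALSE]
    }
    pk[, 2L] <- sqrt(pk[, 2L])
    pk[, 2L] <- pk[, 2L] / max(pk[, 2L])
    pk <- pk[order(pk[, 1L]), , drop = FALSE]
  }
  s$peaks <- pk
  attr(s, "preprocessed") <- TRUE
  attr(s, "searchable") <- nrow(pk) > 0L
  s
}
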