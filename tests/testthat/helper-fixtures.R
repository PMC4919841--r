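# Shared fixtures. Heavy synthetic studies are cached so that several test
# blocks can assert different properties of the same computation without
# re-running the searches.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# Small single-sample study plus its two-step identification.
small_study <- function(seed = 11, n_catalog = 200, n_true = 25,
                        peptides_per_protein = 4, ...) {
  spec <- community_spec(seed = seed, n_catalog = n_catalog,
                         n_true = n_true,
                         peptides_per_protein = peptides_per_protein, ...)
  catalog <- make_catalog(spec)
  study <- make_study(spec, catalog)
  list(spec = spec, catalog = catalog, study = study)
}

# One calibration replicate at the reference study conditions: 1,000-protein
# catalog, 100 expressed proteins, ~800 informative plus ~400 noise spectra.
# Returns identification counts and empirical FDR for the two-step workflow
# and for a direct one-step target-decoy search of the whole catalog.
fdr_replicate <- function(seed) {
  cached(paste0("fdr_", seed), {
    spec <- community_spec(seed = seed, n_catalog = 1000, n_true = 100,
                           peptides_per_protein = 8, n_samples = 1)
    catalog <- make_catalog(spec)
    study <- make_study(spec, catalog)
    run <- study$runs[[1]]
    truth_peps <- unique(study$truth$peptides$peptide)
    red <- step1_reduce(run, catalog$db)
    ident <- step2_identify(run, red)
    two_peps <- unique(ident$peptides$peptide)
    direct_psms <- compute_qvalues(
      search_run(run, add_decoys(catalog$db)))
    fp <- fdr_params()
    dpass <- direct_psms[direct_psms$q <= fp$fdr_cutoff &
                           direct_psms$expect <= fp$max_expect &
                           !direct_psms$is_decoy, , drop = FALSE]
    direct_peps <- unique(dpass$peptide)
    list(
      n_two_step = length(two_peps),
      n_direct = length(direct_peps),
      fdr_two_step = if (length(two_peps)) {
        mean(!two_peps %in% truth_peps)
      } else 0,
      recall = mean(truth_peps %in% two_peps))
  })
}

# Noise-free 20-protein study searched once against its catalog.
clean_run_fixture <- function() {
  cached("clean_run", {
    spec <- community_spec(seed = 301, n_catalog = 150, n_true = 20,
                           peptides_per_protein = 5, noise_frac = 0)
    catalog <- make_catalog(spec)
    study <- make_study(spec, catalog)
    list(catalog = catalog, study = study,
         psms = search_run(study$runs[[1]], catalog$db))
  })
}

# Two-sample study taken through the complete workflow.
wf_small_fixture <- function() {
  cached("wf_small", {
    spec <- community_spec(seed = 302, n_catalog = 200, n_true = 30,
                           peptides_per_protein = 4, n_samples = 2)
    catalog <- make_catalog(spec)
    study <- make_study(spec, catalog)
    list(catalog = catalog, study = study,
         res = run_workflow(study$runs, catalog$db))
  })
}

# Synthetic run of pure noise spectra. Precursors are drawn from `masses`
# (e.g. the mass table of an index, so that spectra have candidates to
# score, as chimeric real noise would) or uniformly when NULL.
make_noise_run <- function(n, seed, sample_id = "noise", masses = NULL,
                           n_peaks = 40L) {
  set.seed(seed)
  spectra <- lapply(seq_len(n), function(i) {
    m <- if (is.null(masses)) runif(1, 700, 2600) else sample(masses, 1)
    spectrum(scan_id = sprintf("%s_%04d", sample_id, i),
             precursor_mz = precursor_mz(m, 2L) *
               (1 + rnorm(1, 0, 3e-6)),
             charge = 2L, rt = runif(1, 10, 230),
             peaks = cbind(runif(n_peaks, 150, 1600),
                           rlnorm(n_peaks, log(500), 1)),
             precursor_intensity = rlnorm(1, log(1e5), 1))
  })
  ms_run(sample_id, spectra)
}

# A clean b/y-ladder spectrum for a peptide (no jitter unless given).
make_ladder_spectrum <- function(peptide, charge = 2L, scan_id = "s1",
                                 rt = 60, intensity = 1e6,
                                 jitter_ppm = 0) {
  res <- proteocat:::residue_masses(peptide, "", digest_params())
  L <- length(res)
  frag <- c(PROTON + cumsum(res)[-L], PROTON + WATER + cumsum(rev(res))[-L])
  if (jitter_ppm > 0) {
    frag <- frag * (1 + rnorm(length(frag), 0, jitter_ppm * 1e-6))
  }
  mass <- sum(res) + WATER
  spectrum(scan_id = scan_id, precursor_mz = precursor_mz(mass, charge),
           charge = charge, rt = rt,
           peaks = cbind(frag, rep(1000, length(frag))),
           precursor_intensity = intensity)
}

# Random peptide sequence with tryptic ending.
random_peptide <- function(len) {
  paste(c(sample(setdiff(names(proteocat:::AA_MONO), c("K", "R")),
                 len - 1, replace = TRUE), sample(c("K", "R"), 1)),
        collapse = "")
}
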