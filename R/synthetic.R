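# Amino-acid sampling frequencies for synthetic proteins: roughly the
# composition of bacterial proteomes, with K/R at ~11 % so tryptic peptides
# average ~9 residues.
AA_FREQ <- c(A = 0.089, R = 0.055, N = 0.040, D = 0.054, C = 0.012,
             E = 0.062, Q = 0.038, G = 0.074, H = 0.021, I = 0.060,
             L = 0.099, K = 0.058, M = 0.024, F = 0.039, P = 0.044,
             S = 0.058, T = 0.054, V = 0.071, W = 0.012, Y = 0.031)

# Stable 31-bit string hash for deriving per-sample RNG streams.
stable_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Specification of a synthetic metaproteomic study
#'
#' Defines the ground-truth community and acquisition model used by
#' [make_catalog()] and [make_study()]: catalog size, expressed proteome
#' size, spectra per protein, the fraction of unexplainable noise spectra,
#' MS/MS dropout (precursor present, fragmentation uninformative), biological
#' intensity variation, and planted group effects (a Firmicutes abundance
#' shift and/or a set of differentially abundant proteins).
#'
#' @param seed mandatory RNG seed; all randomness derives from it.
#' @param n_catalog number of catalog proteins.
#' @param n_true number of truly expressed proteins per study.
#' @param peptides_per_protein observable tryptic peptides sampled per
#'   expressed protein (default 8).
#' @param n_samples number of samples (default 1).
#' @param group_labels experimental group per sample (default all `"A"`).
#' @param noise_frac fraction of acquired spectra that are shuffled-peak
#'   noise (default 1/3).
#' @param dropout_rate fraction of peptide occurrences acquired without an
#'   informative MS/MS scan (default 0); these are recoverable by
#'   match-between-runs.
#' @param intensity_cv lognormal coefficient of variation of peptide
#'   intensities across samples (default 0.10).
#' @param fb_shift fold increase of Firmicutes protein abundance in the
#'   second group (default 1 = no shift).
#' @param n_diff number of planted differential proteins (default 0).
#' @param diff_fold absolute fold change of planted differential proteins in
#'   the second group, alternating up/down (default 4).
#' @param frag_jitter_ppm,prec_jitter_ppm Gaussian m/z jitter (defaults 5
#'   and 3 ppm, inside the 20/10 ppm search tolerances).
#' @return A `community_spec` list.
#' @export
community_spec <- function(seed, n_catalog = 1000L, n_true = 100L,
                           peptides_per_protein = 8L, n_samples = 1L,
                           group_labels = rep("A", n_samples),
                           noise_frac = 1 / 3, dropout_rate = 0,
                           intensity_cv = 0.10, fb_shift = 1,
                           n_diff = 0L, diff_fold = 4,
                           frag_jitter_ppm = 5, prec_jitter_ppm = 3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_frac >= 0, noise_frac < 1, dropout_rate >= 0,
            dropout_rate <= 1, length(group_labels) == n_samples)
  structure(list(seed = as.integer(seed), n_catalog = as.integer(n_catalog),
                 n_true = as.integer(n_true),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 n_samples = as.integer(n_samples),
                 group_labels = as.character(group_labels),
                 noise_frac = noise_frac, dropout_rate = dropout_rate,
                 intensity_cv = intensity_cv, fb_shift = fb_shift,
                 n_diff = as.integer(n_diff), diff_fold = diff_fold,
                 frag_jitter_ppm = frag_jitter_ppm,
                 prec_jitter_ppm = prec_jitter_ppm),
            class = "community_spec")
}

# Fixed synthetic gut-community taxonomy: 5 phyla x 2 genera x 2 species.
synthetic_taxonomy <- function() {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Verrucomicrobia", "Actinobacteria")
  rows <- list(data.frame(taxon_id = "root", parent_id = "root",
                          rank = "root", name = "root",
                          stringsAsFactors = FALSE))
  for (pi in seq_along(phyla)) {
    pid <- paste0("p", pi)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = pid, parent_id = "root", rank = "phylum",
      name = phyla[pi], stringsAsFactors = FALSE)
    for (gi in 1:2) {
      gid <- paste0(pid, "g", gi)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = gid, parent_id = pid, rank = "genus",
        name = paste0(phyla[pi], "_genus", gi), stringsAsFactors = FALSE)
      for (si in 1:2) {
        sid <- paste0(gid, "s", si)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = sid, parent_id = gid, rank = "species",
          name = paste0(phyla[pi], "_sp", gi, si), stringsAsFactors = FALSE)
      }
    }
  }
  taxonomy(do.call(rbind, rows))
}

#' Generate a synthetic protein catalog with taxonomy and COG annotation
#'
#' Random proteins (length 100-600, bacterial-like composition) are
#' partitioned over the leaf species of a fixed five-phylum taxonomy
#' (Firmicutes and Bacteroidetes dominant) and 90 % receive a COG
#' annotation. Deterministic given the spec seed.
#'
#' @param spec a [community_spec()].
#' @return List: `db` ([protein_db()]), `tree` ([taxonomy()]), `annotation`
#'   (COG table), `protein_taxa` (accession -> species taxon_id).
#' @export
make_catalog <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_catalog
  lens <- sample(100:600, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = "")
  }, character(1))
  while (anyDuplicated(seqs)) {  # vanishing probability, but keep the invariant
    i <- which(duplicated(seqs))
    seqs[i] <- vapply(lens[i], function(L) {
      paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
            collapse = "")
    }, character(1))
  }
  acc <- sprintf("CAT_%05d", seq_len(n))
  db <- protein_db(acc, seqs, origin = "synthetic_catalog")
  tree <- synthetic_taxonomy()
  leaves <- tree$taxon_id[tree$rank == "species"]
  phylum_of_leaf <- vapply(leaves, function(l) {
    anc <- tax_ancestors(tree, l)
    tree$name[match(anc[anc %in% tree$taxon_id[tree$rank == "phylum"]],
                    tree$taxon_id)][1L]
  }, character(1))
  phylum_w <- c(Firmicutes = 0.38, Bacteroidetes = 0.32,
                Proteobacteria = 0.12, Verrucomicrobia = 0.10,
                Actinobacteria = 0.08)
  leaf_w <- phylum_w[phylum_of_leaf] / 4  # 4 leaves per phylum
  protein_taxa <- stats::setNames(
    sample(leaves, n, replace = TRUE, prob = leaf_w), acc)
  cog_letters <- strsplit("CDEFGHIJKLMNOPQRSTUVZ", "")[[1L]]
  annotated <- stats::runif(n) < 0.9
  cat1 <- sample(cog_letters, n, replace = TRUE)
  two <- stats::runif(n) < 0.1
  cat2 <- ifelse(two, paste0(cat1, sample(cog_letters, n, replace = TRUE)),
                 cat1)
  annotation <- data.frame(
    accession = acc[annotated],
    cog_id = sprintf("COG%04d", sample(1:5000, sum(annotated),
                                       replace = TRUE)),
    cog_category = cat2[annotated], stringsAsFactors = FALSE)
  list(db = db, tree = tree, annotation = annotation,
       protein_taxa = protein_taxa, spec = spec)
}

# Candidate observable tryptic peptides of one protein: fully tryptic,
# 7-30 residues, canonical only.
observable_peptides <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bounds <- tryptic_boundaries(res)
  peps <- substring(sequence, bounds[, 1L], bounds[, 2L])
  len <- nchar(peps)
  peps <- peps[len >= 7L & len <= 30L]
  peps[!grepl("[^ARNDCEQGHILKMFPSTVWY]", peps)]
}

#' Generate a synthetic study: spectra per sample plus ground truth
#'
#' Study-wide, `n_true` catalog proteins are drawn as the expressed
#' community, each with a lognormal base abundance and a fixed set of
#' observable peptides with study-wide retention times and ionization
#' efficiencies. Per sample, peptide intensities are the protein abundance
#' times the group multiplier (Firmicutes shift and/or planted differential
#' proteins) with lognormal variation `intensity_cv`; each peptide yields a
#' b/y-ladder MS/MS spectrum with Gaussian m/z jitter, partial fragment
#' coverage and the planted precursor intensity in the MGF `PEPMASS` line.
#' Dropout occurrences keep their precursor but carry shuffled fragments
#' (recoverable only by match-between-runs); additional noise spectra are
#' shuffled-peak copies of real spectra at random precursor masses.
#'
#' @param spec a [community_spec()].
#' @param catalog result of [make_catalog()].
#' @return List: `runs` (list of [ms_run()]), `truth` (tables `proteins`,
#'   `peptides`, `spectra`), `metadata` (sample_id, group).
#' @export
make_study <- function(spec, catalog) {
  set.seed(spec$seed + 1L)
  db <- catalog$db
  true_idx <- sort(sample(nrow(db), spec$n_true))
  true_acc <- db$accession[true_idx]
  base_abund <- 10^stats::rnorm(spec$n_true, mean = 7, sd = 0.5)
  names(base_abund) <- true_acc
  # planted differential proteins: first n_diff of the true set,
  # alternating direction; their fold change overrides the phylum shift
  diff_acc <- utils::head(true_acc, spec$n_diff)
  diff_dir <- rep_len(c(1, -1), length(diff_acc))
  names(diff_dir) <- diff_acc
  phylum_name <- function(accs) {
    vapply(accs, function(a) {
      anc <- tax_ancestors(catalog$tree, catalog$protein_taxa[[a]])
      ph <- anc[anc %in% catalog$tree$taxon_id[catalog$tree$rank == "phylum"]]
      catalog$tree$name[match(ph[1L], catalog$tree$taxon_id)]
    }, character(1))
  }
  true_phylum <- phylum_name(true_acc)
  # study-wide peptide selection
  pep_rows <- list()
  for (i in seq_along(true_acc)) {
    peps <- unique(observable_peptides(db$sequence[true_idx[i]]))
    if (!length(peps)) next
    k <- min(spec$peptides_per_protein, length(peps))
    sel <- sample(peps, k)
    pep_rows[[i]] <- data.frame(peptide = sel, accession = true_acc[i],
                                stringsAsFactors = FALSE)
  }
  peptides <- do.call(rbind, pep_rows)
  peptides <- peptides[!duplicated(peptides$peptide), , drop = FALSE]
  npep <- nrow(peptides)
  dparams <- digest_params()
  pep_resmass <- lapply(peptides$peptide, residue_masses, mod_pos = "",
                        params = dparams)
  peptides$mass <- vapply(pep_resmass, sum, numeric(1)) + WATER_MASS
  peptides$charge <- ifelse(peptides$mass < 2400, 2L, 3L)
  peptides$rt <- stats::runif(npep, 10, 230)
  peptides$efficiency <- 10^stats::rnorm(npep, 0, 0.3)
  groups <- spec$group_labels
  second_group <- if (length(unique(groups)) > 1L) unique(groups)[2L] else NA
  sdlog <- sqrt(log(1 + spec$intensity_cv^2))
  runs <- vector("list", spec$n_samples)
  truth_prot <- list(); truth_pep <- list(); truth_spec <- list()
  for (si in seq_len(spec$n_samples)) {
    sample_id <- sprintf("S%02d", si)
    set.seed(stable_hash(paste(spec$seed, sample_id, sep = ":")))
    in_second <- !is.na(second_group) && groups[si] == second_group
    mult <- rep(1, spec$n_true)
    names(mult) <- true_acc
    if (in_second && spec$fb_shift != 1) {
      mult[true_phylum == "Firmicutes"] <- spec$fb_shift
    }
    if (in_second && length(diff_acc)) {
      mult[diff_acc] <- ifelse(diff_dir > 0, spec$diff_fold,
                               1 / spec$diff_fold)
    }
    abund <- base_abund * mult
    pint <- abund[peptides$accession] * peptides$efficiency *
      stats::rlnorm(npep, 0, sdlog)
    rt_s <- peptides$rt * stats::runif(1, 0.97, 1.03) +
      stats::runif(1, -3, 3) + stats::rnorm(npep, 0, 0.15)
    dropout <- stats::runif(npep) < spec$dropout_rate
    spectra <- vector("list", npep)
    stypes <- character(npep)
    for (pi in seq_len(npep)) {
      rm <- pep_resmass[[pi]]
      z <- peptides$charge[pi]
      mz <- precursor_mz(peptides$mass[pi], z) *
        (1 + stats::rnorm(1, 0, spec$prec_jitter_ppm * 1e-6))
      L <- length(rm)
      bions <- PROTON_MASS + cumsum(rm)[-L]
      yions <- PROTON_MASS + WATER_MASS + cumsum(rev(rm))[-L]
      frag <- c(bions, yions)
      if (dropout[pi]) {
        nn <- 30L
        pk <- cbind(stats::runif(nn, 150, max(frag) + 50),
                    stats::rlnorm(nn, log(500), 1))
        stypes[pi] <- "dropout"
      } else {
        cover <- stats::runif(1, 0.45, 0.95)
        keep <- sort(sample(length(frag),
                            max(4L, round(cover * length(frag)))))
        fmz <- frag[keep] *
          (1 + stats::rnorm(length(keep), 0, spec$frag_jitter_ppm * 1e-6))
        fint <- stats::rlnorm(length(keep), log(1000), 0.8)
        nn <- 5L
        pk <- rbind(cbind(fmz, fint),
                    cbind(stats::runif(nn, 150, max(frag) + 50),
                          stats::rlnorm(nn, log(100), 0.5)))
        stypes[pi] <- "msms"
      }
      spectra[[pi]] <- spectrum(
        scan_id = sprintf("%s_scan%04d", sample_id, pi),
        precursor_mz = mz, charge = z, rt = rt_s[pi], peaks = pk,
        precursor_intensity = pint[pi])
    }
    # shuffled-peak noise spectra at random precursor masses
    n_noise <- round(npep * spec$noise_frac / (1 - spec$noise_frac))
    noise <- vector("list", n_noise)
    for (k in seq_len(n_noise)) {
      tmpl <- spectra[[sample(npep, 1L)]]
      ints <- sample(tmpl$peaks[, 2L])
      pk <- cbind(stats::runif(length(ints), 150, 1600), ints)
      noise[[k]] <- spectrum(
        scan_id = sprintf("%s_noise%04d", sample_id, k),
        precursor_mz = stats::runif(1, min = 350, max = 1300),
        charge = 2L, rt = stats::runif(1, 10, 230), peaks = pk,
        precursor_intensity = stats::rlnorm(1, log(1e5), 1))
    }
    runs[[si]] <- ms_run(sample_id, c(spectra, noise))
    truth_prot[[si]] <- data.frame(
      sample_id = sample_id, accession = true_acc,
      abundance = unname(abund), phylum = unname(true_phylum),
      is_diff = true_acc %in% diff_acc,
      diff_dir = unname(ifelse(true_acc %in% diff_acc,
                               diff_dir[true_acc], 0)),
      stringsAsFactors = FALSE)
    truth_pep[[si]] <- data.frame(
      sample_id = sample_id, peptide = peptides$peptide,
      accession = peptides$accession, intensity = unname(pint),
      rt = rt_s, charge = peptides$charge, mass = peptides$mass,
      dropout = dropout, stringsAsFactors = FALSE)
    truth_spec[[si]] <- data.frame(
      sample_id = sample_id,
      scan_id = c(vapply(spectra, `[[`, character(1), "scan_id"),
                  vapply(noise, `[[`, character(1), "scan_id")),
      peptide = c(peptides$peptide, rep(NA_character_, n_noise)),
      type = c(stypes, rep("noise", n_noise)), stringsAsFactors = FALSE)
  }
  list(runs = runs,
       truth = list(proteins = do.call(rbind, truth_prot),
                    peptides = do.call(rbind, truth_pep),
                    spectra = do.call(rbind, truth_spec)),
       metadata = data.frame(sample_id = sprintf("S%02d",
                                                 seq_len(spec$n_samples)),
                             group = groups, stringsAsFactors = FALSE))
}

#' Write a synthetic study to disk
#'
#' Emits the exact formats the pipeline reads: one MGF per sample, the
#' catalog FASTA, taxonomy/COG/metadata TSVs and the truth tables.
#'
#' @param study result of [make_study()].
#' @param catalog result of [make_catalog()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(catalog$db, file.path(dir, "catalog.fasta"))
  utils::write.table(as.data.frame(catalog$tree),
                     file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(catalog$annotation, file.path(dir, "cog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(accession = names(catalog$protein_taxa),
                                taxon_id = unname(catalog$protein_taxa)),
                     file.path(dir, "protein_taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (run in study$runs) {
    write_mgf(run, file.path(dir, paste0(run$sample_id, ".mgf")))
  }
  for (nm in names(study$truth)) {
    utils::write.table(study$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
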