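test_that("candidate retrieval respects the precursor tolerance", {
  db <- protein_db("p1", "MMMKELVISKDDDK")
  idx <- build_peptide_index(db, digest_params(min_len = 5))
  m <- peptide_mass("ELVISK")
  hit <- get_candidates(idx, precursor_mz(m, 2), 2L)
  expect_true("ELVISK" %in% hit$sequence)
  # a query offset by 20 ppm falls outside the 10 ppm window
  off <- get_candidates(idx, precursor_mz(m * (1 + 20e-6), 2), 2L)
  expect_false("ELVISK" %in% off$sequence)
})

test_that("candidate retrieval equals a brute-force linear scan", {
  set.seed(230)
  seqs <- vapply(rep(80, 60), function(L) {
    paste(sample(names(proteocat:::AA_MONO), L, replace = TRUE),
          collapse = "")
  }, character(1))
  idx <- build_peptide_index(protein_db(sprintf("p%02d", 1:60), seqs))
  expect_gt(nrow(idx$forms), 1000)
  sp <- search_params()
  for (q in 1:100) {
    # half the queries centered on a real peptide mass, half random
    m <- if (q %% 2 == 0) {
      idx$forms$mass[sample(nrow(idx$forms), 1)] * (1 + rnorm(1, 0, 5e-6))
    } else runif(1, 600, 4000)
    z <- sample(2:3, 1)
    mine <- get_candidates(idx, precursor_mz(m, z), z, sp)
    ref <- oracle_candidates(idx$forms, precursor_mz(m, z), z,
                             sp$parent_tol_ppm)
    expect_equal(mine$sequence, ref$sequence)
    expect_equal(mine$mod_pos, ref$mod_pos)
  }
})

test_that("hyperscore matches the hand-computed toy example", {
  # three peaks matching two b-ions and one y-ion of PEPTIDEK with
  # preprocessed intensities 1.0, 0.5, 0.25: score = 1.75 * 2! * 1! = 3.5
  res <- proteocat:::residue_masses("PEPTIDEK", "", digest_params())
  b <- PROTON + cumsum(res)[-8]
  y <- PROTON + WATER + cumsum(rev(res))[-8]
  # raw intensities chosen so sqrt-normalization yields 1.0, 0.5, 0.25
  pk <- cbind(c(b[2], b[3], y[2]), c(16, 4, 1))
  s <- spectrum("toy", precursor_mz(sum(res) + WATER, 2), 2L, 10, pk)
  out <- hyperscore(s, "PEPTIDEK")
  expect_equal(out$n_b, 2L)
  expect_equal(out$n_y, 1L)
  expect_equal(out$dot, 1.75)
  expect_equal(out$score, 3.5)
})

test_that("hyperscore is zero without matches and permutation-invariant", {
  pk <- cbind(c(200.0, 300.0, 400.0), c(5, 10, 2))
  s <- spectrum("none", 500, 2L, 10, pk)
  out <- hyperscore(s, "ELVISK")
  expect_equal(out$score, 0)
  expect_equal(out$n_b + out$n_y, 0L)
  # permuting the peak list before construction changes nothing
  s2 <- spectrum("perm", 500, 2L, 10, pk[c(3, 1, 2), ])
  expect_equal(hyperscore(s2, "ELVISK"), out)
})

test_that("adding a matched fragment peak never decreases the score", {
  set.seed(231)
  for (i in 1:20) {
    pep <- random_peptide(10)
    res <- proteocat:::residue_masses(pep, "", digest_params())
    frag <- c(PROTON + cumsum(res)[-10],
              PROTON + WATER + cumsum(rev(res))[-10])
    frag <- frag[frag >= 150]
    sel <- sample(length(frag), 4)
    pk1 <- cbind(frag[sel], rep(100, 4))
    extra <- setdiff(seq_along(frag), sel)[1]
    pk2 <- rbind(pk1, c(frag[extra], 50))
    s1 <- hyperscore(spectrum("a", 500, 2L, 1, pk1), pep)
    s2 <- hyperscore(spectrum("b", 500, 2L, 1, pk2), pep)
    expect_gte(s2$score, s1$score)
  }
})

test_that("hyperscore agrees exactly with the brute-force oracle", {
  set.seed(232)
  params <- digest_params()
  for (i in 1:100) {
    pep <- random_peptide(sample(7:20, 1))
    res <- proteocat:::residue_masses(pep, "", params)
    L <- length(res)
    frag <- c(PROTON + cumsum(res)[-L],
              PROTON + WATER + cumsum(rev(res))[-L])
    # mixture of true fragments (with jitter) and random peaks
    nf <- sample(3:min(10, length(frag)), 1)
    fmz <- sample(frag, nf) * (1 + rnorm(nf, 0, 8e-6))
    nr <- sample(3:15, 1)
    pk <- rbind(cbind(fmz, runif(nf, 10, 1000)),
                cbind(runif(nr, 150, 1700), runif(nr, 10, 1000)))
    s <- preprocess_spectrum(spectrum("o", 600, 2L, 1, pk))
    mine <- hyperscore(s, pep)
    ref <- oracle_hyperscore(s$peaks, res, 20)
    expect_equal(mine$score, ref$score, tolerance = 1e-9)
    expect_equal(mine$n_b, ref$n_b)
    expect_equal(mine$n_y, ref$n_y)
  }
})

test_that("expect values reflect the candidate score distribution", {
  set.seed(233)
  null_scores <- rlnorm(200, log(5), 1.2)
  strong <- max(null_scores) * 1e6
  ev <- expect_value(strong, c(null_scores, strong))
  expect_false(ev$degenerate)
  expect_lt(ev$expect, 0.05)
  ev_med <- expect_value(median(null_scores), null_scores)
  expect_gte(ev_med$expect, 0.5)
  # single candidate: degenerate fallback
  ev1 <- expect_value(10, 10)
  expect_true(ev1$degenerate)
  expect_equal(ev1$expect, 1)
})

test_that("a clean synthetic run is matched to its generating peptides", {
  fx <- clean_run_fixture()
  truth <- fx$study$truth$spectra
  psms <- fx$psms
  expect_gt(nrow(psms), 0.99 * nrow(truth))
  correct <- psms$peptide == truth$peptide[match(psms$scan_id,
                                                 truth$scan_id)]
  expect_gte(mean(correct), 0.99)
})

test_that("searching is deterministic and an empty run yields no PSMs", {
  fx <- clean_run_fixture()
  idx <- build_peptide_index(fx$catalog$db)
  p1 <- search_run(fx$study$runs[[1]], index = idx)
  p2 <- search_run(fx$study$runs[[1]], index = idx)
  expect_identical(p1, p2)
  empty <- search_run(ms_run("none", list()), index = idx)
  expect_equal(nrow(empty), 0L)
})

test_that("pure-noise spectra split evenly between targets and decoys", {
  fx <- clean_run_fixture()
  idx <- build_peptide_index(add_decoys(fx$catalog$db))
  run <- make_noise_run(2000, seed = 235, masses = idx$forms$mass,
                        n_peaks = 120L)
  psms <- search_run(run, index = idx)
  expect_gt(nrow(psms), 100)
  bt <- stats::binom.test(sum(psms$is_decoy), nrow(psms), p = 0.5)
  expect_gt(bt$p.value, 0.001)
})
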