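test_that("subset-rule grouping merges contained proteins", {
  # P2's peptides {a,b} are a subset of P1's {a,b,c}: one group, leading P1
  g <- group_proteins(list(a = c("P1", "P2"), b = c("P1", "P2"),
                           c = "P1"))
  expect_length(g, 1L)
  expect_equal(g[[1]]$leading, "P1")
  expect_setequal(g[[1]]$members, c("P1", "P2"))
  # incomparable peptide sets stay separate
  g2 <- group_proteins(list(a = "P1", b = c("P1", "P2"), c = "P2"))
  expect_length(g2, 2L)
})

test_that("grouping equals the brute-force subset closure", {
  set.seed(250)
  for (i in 1:100) {
    n_prot <- sample(4:12, 1)
    n_pep <- sample(6:20, 1)
    accs <- sprintf("P%02d", seq_len(n_prot))
    pep2prot <- lapply(seq_len(n_pep), function(j) {
      sample(accs, sample(1:3, 1))
    })
    names(pep2prot) <- sprintf("pep%02d", seq_len(n_pep))
    mine <- group_proteins(pep2prot)
    ref <- oracle_group_proteins(pep2prot)
    expect_setequal(vapply(mine, `[[`, character(1), "group_id"),
                    names(ref))
    for (g in mine) {
      expect_setequal(g$members, ref[[g$group_id]])
    }
  }
})

test_that("grouping is order-invariant and idempotent", {
  set.seed(251)
  pep2prot <- lapply(1:15, function(j) sample(sprintf("P%d", 1:6),
                                              sample(1:3, 1)))
  names(pep2prot) <- sprintf("pep%02d", 1:15)
  g1 <- group_proteins(pep2prot)
  g2 <- group_proteins(rev(pep2prot))
  key <- function(g) {
    lapply(g[order(vapply(g, `[[`, character(1), "group_id"))],
           function(x) list(x$group_id, sort(x$members)))
  }
  expect_equal(key(g1), key(g2))
})

test_that("razor peptides go to the group with most evidence", {
  g <- group_proteins(list(a = "G1", b = "G1", c = "G1", d = "G1",
                           e = c("G1", "G2"), f = "G2"))
  g <- assign_razor(g)
  asg <- attr(g, "assignment")
  expect_equal(asg$group_id[asg$peptide == "e"], "G1")
  expect_equal(asg$class[asg$peptide == "e"], "razor")
  # exact tie on peptides and PSMs: lexicographic leading wins
  gt <- assign_razor(group_proteins(list(a = "A", b = c("A", "B"),
                                         c = "B")))
  asgt <- attr(gt, "assignment")
  expect_equal(asgt$group_id[asgt$peptide == "b"], "A")
  # conservation: every peptide quantifies exactly one group
  set.seed(252)
  for (i in 1:20) {
    p2p <- lapply(1:12, function(j) sample(sprintf("P%d", 1:5),
                                           sample(1:3, 1)))
    names(p2p) <- sprintf("pep%02d", 1:12)
    gr <- assign_razor(group_proteins(p2p))
    quant <- unlist(lapply(gr, `[[`, "quant_peptides"))
    expect_equal(sort(quant), sort(names(p2p)))
  }
})

test_that("feature extraction recovers planted precursor intensities", {
  fx <- clean_run_fixture()
  run <- fx$study$runs[[1]]
  psms <- fx$psms
  feat <- extract_features(run, psms, aggregate = FALSE)
  truth <- fx$study$truth$peptides
  m <- match(feat$peptide, truth$peptide)
  expect_true(all(!is.na(m)))
  expect_equal(feat$intensity, truth$intensity[m], tolerance = 1e-9)
  # PEPMASS without an intensity falls back to the fragment sum
  s <- spectrum("nofb", 500.25, 2L, 12, cbind(c(200, 300), c(5, 7)))
  r <- ms_run("x", list(s))
  p1 <- psms[1, ]; p1$scan_id <- "nofb"
  f <- extract_features(r, p1)
  expect_equal(f$intensity, 12)
})

test_that("match-between-runs obeys the time and mass windows", {
  # donor peptide at RT 50; acceptor candidates at 52 (in) and 56 (out)
  qp <- quant_params()
  feat <- data.frame(
    peptide = c(sprintf("SHAREDPEP%dK", 1:6), "TRANSFERMEK"),
    sample_id = "D", intensity = 100, rt = c((1:6) * 20, 50),
    mz = c(400 + 1:6, 600.777), charge = 2L, id_type = "msms",
    stringsAsFactors = FALSE)
  featA <- data.frame(
    peptide = sprintf("SHAREDPEP%dK", 1:6), sample_id = "A",
    intensity = 90, rt = (1:6) * 20, mz = 400 + 1:6, charge = 2L,
    id_type = "msms", stringsAsFactors = FALSE)
  make_cand <- function(rt) {
    spectrum(paste0("cand", rt), 600.777, 2L, rt,
             cbind(c(200, 300), c(1, 1)), precursor_intensity = 5000)
  }
  shared_sp <- lapply(1:6, function(i) {
    spectrum(paste0("sh", i), 400 + i, 2L, i * 20,
             cbind(c(200, 300), c(1, 1)), precursor_intensity = 90)
  })
  run_d <- ms_run("D", list())
  psms_by_run <- list(
    D = data.frame(scan_id = character(0)),
    A = data.frame(scan_id = paste0("sh", 1:6)))

  run_a_in <- ms_run("A", c(shared_sp, list(make_cand(52))))
  out <- match_between_runs(rbind(feat, featA),
                            list(run_d, run_a_in), psms_by_run, qp)
  tr <- out[out$id_type == "matched", ]
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$peptide, "TRANSFERMEK")
  expect_equal(tr$sample_id, "A")
  expect_equal(tr$intensity, 5000)

  run_a_out <- ms_run("A", c(shared_sp, list(make_cand(56))))
  out2 <- match_between_runs(rbind(feat, featA),
                             list(run_d, run_a_out), psms_by_run, qp)
  expect_equal(sum(out2$id_type == "matched"), 0L)

  # never transfer a peptide already MS/MS-identified in the acceptor
  featA2 <- rbind(featA, data.frame(
    peptide = "TRANSFERMEK", sample_id = "A", intensity = 70, rt = 52,
    mz = 600.777, charge = 2L, id_type = "msms", stringsAsFactors = FALSE))
  out3 <- match_between_runs(rbind(feat, featA2),
                             list(run_d, run_a_in), psms_by_run, qp)
  expect_equal(sum(out3$id_type == "matched"), 0L)
})

test_that("dropout occurrences are recovered across runs by MBR", {
  fx <- cached("mbr_study", {
    spec <- community_spec(seed = 303, n_catalog = 150, n_true = 25,
                           peptides_per_protein = 5, n_samples = 3,
                           dropout_rate = 0.2, noise_frac = 0.1)
    catalog <- make_catalog(spec)
    study <- make_study(spec, catalog)
    list(catalog = catalog, study = study,
         res = run_workflow(study$runs, catalog$db))
  })
  truth <- fx$study$truth$peptides
  dropped <- truth[truth$dropout, ]
  matched <- fx$res$features[fx$res$features$id_type == "matched", ]
  key <- function(d) paste(d$peptide, d$sample_id)
  # recoverable dropouts: peptide identified by MS/MS in some other run
  msms_peps <- unique(fx$res$features$peptide[
    fx$res$features$id_type == "msms"])
  recoverable <- dropped[dropped$peptide %in% msms_peps, ]
  recovered <- key(recoverable) %in% key(matched)
  expect_gte(mean(recovered), 0.9)
  # transferred intensities are the planted ones
  m <- match(key(matched), key(truth))
  expect_equal(matched$intensity, truth$intensity[m], tolerance = 1e-9)
})

test_that("single-peptide LFQ reproduces intensity ratios exactly", {
  g <- assign_razor(group_proteins(list(onlypep = "P1")))
  feat <- data.frame(peptide = "onlypep", sample_id = c("a", "b", "c"),
                     intensity = c(100, 200, 400), rt = 10, mz = 500,
                     charge = 2L, id_type = "msms",
                     stringsAsFactors = FALSE)
  lfq <- maxlfq(g, feat)
  expect_equal(unname(lfq["P1", ] / lfq["P1", "a"]), c(1, 2, 4))
})

test_that("consistent two-peptide data gives the exact least-squares profile", {
  g <- assign_razor(group_proteins(list(pepa = "P1", pepb = "P1")))
  truthp <- c(a = 1, b = 3, c = 9)
  feat <- do.call(rbind, lapply(names(truthp), function(s) {
    data.frame(peptide = c("pepa", "pepb"), sample_id = s,
               intensity = c(2, 5) * truthp[[s]], rt = 10, mz = 500,
               charge = 2L, id_type = "msms", stringsAsFactors = FALSE)
  }))
  lfq <- maxlfq(g, feat)
  prof <- lfq["P1", ] / sum(lfq["P1", ])
  expect_equal(unname(prof), unname(truthp / sum(truthp) * 0 +
                                      c(7, 21, 63) / 91), tolerance = 1e-9)
})

test_that("maxlfq equals the normal-equations oracle on random instances", {
  set.seed(253)
  for (i in 1:40) {
    np <- sample(3:8, 1); ns <- sample(3:6, 1)
    truthp <- exp(rnorm(ns))
    eff <- exp(rnorm(np))
    mat <- outer(eff, truthp)
    # knock out ~30 % but keep every sample observed at least twice
    repeat {
      miss <- matrix(runif(np * ns) < 0.3, np, ns)
      if (all(crossprod(!miss) >= 1)) break  # every sample pair shares data
    }
    mat[miss] <- NA
    mine <- proteocat:::maxlfq_profile(mat, 1L)
    ref <- oracle_maxlfq_profile(mat, 1)
    expect_equal(mine, unname(ref), tolerance = 1e-9)
  }
})

test_that("noise-free connected data recovers true profiles to 1e-6", {
  set.seed(254)
  truthp <- c(4, 1, 2, 8, 0.5, 3)
  for (i in 1:10) {
    np <- 6
    eff <- exp(rnorm(np))
    mat <- outer(eff, truthp)
    repeat {
      miss <- matrix(runif(np * 6) < 0.3, np, 6)
      if (all(crossprod(!miss) >= 1) && all(rowSums(!miss) >= 2)) break
    }
    mat[miss] <- NA
    prof <- proteocat:::maxlfq_profile(mat, 1L)
    expect_equal(prof / sum(prof), truthp / sum(truthp), tolerance = 1e-6)
  }
})
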