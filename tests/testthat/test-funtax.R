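toy_tree <- function() {
  taxonomy(data.frame(
    taxon_id = c("r", "f", "b", "fg1", "fg2", "bg1",
                 "fs1", "fs2", "fs3", "bs1", "bs2"),
    parent_id = c("r", "r", "r", "f", "f", "b",
                  "fg1", "fg1", "fg2", "bg1", "bg1"),
    rank = c("root", "phylum", "phylum", "genus", "genus", "genus",
             "species", "species", "species", "species", "species"),
    name = c("root", "Firmicutes", "Bacteroidetes", "Fg1", "Fg2", "Bg1",
             "Fs1", "Fs2", "Fs3", "Bs1", "Bs2"),
    stringsAsFactors = FALSE))
}

test_that("taxonomy validation rejects broken trees", {
  expect_error(taxonomy(data.frame(
    taxon_id = c("a", "b"), parent_id = c("b", "a"),
    rank = c("root", "phylum"), name = c("a", "b"))), "root|cycle")
  tt <- toy_tree()
  expect_equal(attr(tt, "root"), "r")
})

test_that("LCA assignment resolves peptides to the deepest shared taxon", {
  tree <- toy_tree()
  index <- structure(list(pep2taxa = list(
    AAAAK = "fs1",                 # one species
    CCCCK = c("fs1", "fs2"),       # two species, one genus
    DDDDK = c("fs1", "fs3"),       # two genera, one phylum
    EEEEK = c("fs1", "bs1"))),     # across phyla: root
    class = "tax_peptide_index")
  expect_equal(lca_assign("AAAAK", index, tree), "fs1")
  expect_equal(lca_assign("CCCCK", index, tree), "fg1")
  expect_equal(lca_assign("DDDDK", index, tree), "f")
  expect_equal(lca_assign("EEEEK", index, tree), "r")
  expect_true(is.na(lca_assign("MISSINGK", index, tree)))
})

test_that("LCA matches the brute-force ancestor intersection", {
  set.seed(260)
  tree <- toy_tree()
  leaves <- tree$taxon_id[tree$rank == "species"]
  peps <- replicate(200, random_peptide(8))
  p2t <- lapply(seq_along(peps), function(i) {
    sample(leaves, sample(1:4, 1))
  })
  names(p2t) <- gsub("I", "L", peps)
  index <- structure(list(pep2taxa = p2t), class = "tax_peptide_index")
  for (i in seq_along(peps)) {
    mine <- lca_assign(peps[i], index, tree,
                       advanced_missed_cleavage = FALSE)
    ref <- oracle_lca(p2t[[gsub("I", "L", peps[i])]], tree)
    expect_equal(mine, ref)
  }
})

test_that("peptides differing only in I/L get identical assignments", {
  fx <- clean_run_fixture()
  index <- build_tax_index(
    build_reduced_db(fx$catalog$db,
                     unique(fx$study$truth$proteins$accession)),
    fx$catalog$protein_taxa)
  tree <- fx$catalog$tree
  withI <- names(index$pep2taxa)[grepl("L", names(index$pep2taxa))][1:10]
  for (p in withI) {
    swapped <- sub("L", "I", p)
    expect_equal(lca_assign(swapped, index, tree),
                 lca_assign(p, index, tree))
  }
})

test_that("missed-cleavage peptides resolve through their tryptic parts", {
  tree <- toy_tree()
  index <- structure(list(pep2taxa = list(
    AAAAAAK = c("fs1", "fs2"), CCCCCCR = c("fs2", "fs3"))),
    class = "tax_peptide_index")
  # intersection of {fs1,fs2} and {fs2,fs3} pins fs2
  expect_equal(lca_assign("AAAAAAKCCCCCCR", index, tree), "fs2")
  expect_true(is.na(lca_assign("AAAAAAKCCCCCCR", index, tree,
                               advanced_missed_cleavage = FALSE)))
})

test_that("taxon abundances are intensity sums normalized per sample", {
  tree <- toy_tree()
  feat <- data.frame(
    peptide = c("a", "b", "c", "d"),
    sample_id = c("s1", "s1", "s1", "s2"),
    intensity = c(30, 50, 20, 10), stringsAsFactors = FALSE)
  asg <- c(a = "fs1", b = "fg1", c = "bs2", d = "fs2")
  m <- taxon_abundance(feat, asg, tree, rank = "phylum")
  expect_equal(m["Firmicutes", "s1"], 0.8)
  expect_equal(m["Bacteroidetes", "s1"], 0.2)
  expect_equal(m["Firmicutes", "s2"], 1.0)
  expect_true(all(colSums(m) <= 1 + 1e-12))
  # unassigned intensity dilutes relative abundances
  asg2 <- c(asg, e = NA_character_)
  feat2 <- rbind(feat, data.frame(peptide = "e", sample_id = "s1",
                                  intensity = 100))
  m2 <- taxon_abundance(feat2, asg2, tree, rank = "phylum")
  expect_equal(m2["Firmicutes", "s1"], 0.4)
})

test_that("planted phylum mixtures are recovered from intensities", {
  tree <- toy_tree()
  set.seed(261)
  n <- 200
  phyla <- sample(c("fs1", "bs1"), n, replace = TRUE, prob = c(0.5, 0.5))
  inten <- ifelse(phyla == "fs1", 3, 1) * runif(n, 0.9, 1.1)
  feat <- data.frame(peptide = sprintf("p%03d", 1:n), sample_id = "s1",
                     intensity = inten, stringsAsFactors = FALSE)
  asg <- setNames(phyla, feat$peptide)
  m <- taxon_abundance(feat, asg, tree, rank = "phylum")
  ratio <- m["Firmicutes", 1] / m["Bacteroidetes", 1]
  planted <- sum(inten[phyla == "fs1"]) / sum(inten[phyla == "bs1"])
  expect_equal(ratio, planted, tolerance = 1e-12)
  expect_lt(abs(ratio / 3 - 1), 0.3)
})

test_that("the F/B ratio behaves under edge cases and normalization", {
  m <- matrix(c(100, 300, 100, 100, 50, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Firmicutes", "Bacteroidetes", "Other"),
                              c("s1", "s2")))
  r <- fb_ratio(m)
  expect_equal(unname(r["s1"]), 1.0)
  expect_equal(unname(r["s2"]), 3.0)
  # ratio is invariant to per-sample total normalization
  mn <- sweep(m, 2, colSums(m), "/")
  expect_equal(unname(fb_ratio(mn)), unname(r))
  # zero Bacteroidetes: undefined, not infinite
  m0 <- m; m0["Bacteroidetes", "s2"] <- 0
  r0 <- fb_ratio(m0)
  expect_true(is.na(r0["s2"]))
  expect_equal(attr(r0, "undefined"), "s2")
  expect_error(fb_ratio(m[c("Firmicutes", "Other"), ]), "Bacteroidetes")
})

test_that("COG roll-up sums group LFQ with leading-protein fallback", {
  groups <- list(
    structure(list(group_id = "G1", members = "G1", leading = "G1",
                   peptides = "a", n_psms = 1), class = "protein_group"),
    structure(list(group_id = "G2", members = c("G2", "G2b"),
                   leading = "G2", peptides = "b", n_psms = 1),
              class = "protein_group"),
    structure(list(group_id = "G3", members = "G3", leading = "G3",
                   peptides = "c", n_psms = 1), class = "protein_group"))
  lfq <- matrix(c(10, 20, 30, 40, 50, 60), nrow = 3, byrow = TRUE,
                dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
  ann <- data.frame(accession = c("G1", "G2b", "G3"),
                    cog_id = c("COG1", "COG2", "COG3"),
                    cog_category = c("G", "C", "G"),
                    stringsAsFactors = FALSE)
  m <- cog_rollup(groups, lfq, ann)
  # G1 and G3 share category G; G2 falls back to member G2b's category C
  expect_equal(m["G", "s1"], 60)
  expect_equal(m["C", "s1"], 30)
  # conservation: categories (incl. '?') sum to the total group LFQ
  ann2 <- ann[ann$accession != "G3", ]
  m2 <- cog_rollup(groups, lfq, ann2)
  expect_true("?" %in% rownames(m2))
  expect_equal(colSums(m2), colSums(lfq))
})

test_that("multi-letter categories split by mode", {
  groups <- list(structure(list(group_id = "G1", members = "G1",
                                leading = "G1", peptides = "a",
                                n_psms = 1), class = "protein_group"))
  lfq <- matrix(5, 1, 1, dimnames = list("G1", "s1"))
  ann <- data.frame(accession = "G1", cog_id = "COG9",
                    cog_category = "EG", stringsAsFactors = FALSE)
  expect_equal(rownames(cog_rollup(groups, lfq, ann, mode = "primary")),
               "E")
  m_each <- cog_rollup(groups, lfq, ann, mode = "each")
  expect_setequal(rownames(m_each), c("E", "G"))
  expect_true(all(m_each == 5))
})
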