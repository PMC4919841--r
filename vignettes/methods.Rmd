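---
title: "Iterative catalog search and label-free quantification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative catalog search and label-free quantification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`proteocat`, in the spirit of the long-form methods sections of mature
omics packages. It states no empirical result that the package's test suite
or `scripts/acceptance.R` does not itself compute.

## The problem and the workflow

A microbial gene catalog is a non-redundant collection of (translated)
genes assembled from many metagenomes; real gut catalogs hold 10^6–10^7
entries. Searching MS/MS spectra directly against such a database is both
slow and statistically punishing: with a target-decoy strategy, the decoy
space grows with the database, pushing weak but genuine matches below any
fixed FDR threshold. The iterative (two-step) strategy addresses this by
(1) a loose, target-only pass over the full catalog that retains every
protein plausibly present in the sample — a reduced, sample-specific
database — and (2) a conventional target-decoy search of the reduced
database, filtered at a PSM q-value of 0.01 and expect value of 0.05.
Identified protein lists from all samples are then combined, de-duplicated
by exact sequence, and used as a study-specific database for one final
search per run, on which all quantification is performed so intensities are
comparable across samples.

The step-1 inclusion threshold (expect ≤ 1.0) is deliberately permissive:
step 1 trades precision for recall, and all error control lives in step 2.
Protein-level FDR is not separately controlled; protein lists inherit
PSM/peptide-level control, which we note as a limitation.

## Digestion and mass arithmetic

Cleavage is C-terminal to K or R with no proline exception (trypsin/P), up
to 2 missed cleavages. Peptides of 7–45 residues are retained — the paper
trail for such bounds is thin everywhere in bottom-up proteomics, and these
are the conventional limits; both are configurable. Carbamidomethylation of
cysteine (+57.021464 Da) is fixed; oxidation of methionine (+15.994915 Da)
is variable with at most 3 simultaneous sites per peptide (a cap that
bounds the combinatorial expansion). Monoisotopic residue masses are tabled
to six decimals; water is 18.010565 Da and the proton 1.007276 Da. Peptides
containing non-canonical residues (B/J/O/U/X/Z) are skipped at digestion —
their masses would be ill-defined — while the proteins that contain them
stay in the database. Protein N-terminal methionine removal is not
modelled. Isoleucine and leucine are distinct during search and collapse
only in the taxonomy index, where mass spectrometry genuinely cannot
distinguish them.

## Spectrum preprocessing

Peaks below m/z 150 are removed and at most the 50 most intense peaks are
kept — typical practice for HCD spectra on Orbitrap-class instruments.
Intensities are square-root transformed and scaled to a maximum of 1,
which damps dominant fragment peaks and makes hyperscores reproducible
across acquisitions with different absolute intensity scales. Duplicate
m/z values collapse to their most intense peak so peak lists are strictly
increasing. Preprocessing is idempotent and never alters an m/z value.

## Scoring

For a candidate peptide with per-residue masses $r_1..r_L$ (modifications
folded in), singly charged b- and y-ion ladders are computed. A fragment
matches a peak when their relative distance is within 20 ppm; when several
fragment–peak pairs compete, the smallest ppm error wins and each peak and
each fragment is used at most once (greedy assignment on sorted errors;
ties break on fragment then peak index, which makes scores
permutation-invariant). The hyperscore is

$$H = \Big(\sum_{\text{matched}} I_p\Big)\; n_b!\; n_y!$$

with the factorials capped at $10!$ so they cannot dominate through
overflow. Only singly charged b/y ions are considered — no neutral losses,
no a/c/x/z series — keeping the score hand-checkable against the
brute-force oracle in the test suite. The inner loop is compiled (Rcpp);
the R-level oracle in `tests/testthat/helper-oracles.R` is the independent
reference.

## Expect values: the sparse-null problem

The expect value estimates how many candidates would reach the best score
by chance. The classical construction bins candidate hyperscores, fits a
least-squares line to the log10 survival counts of the descending tail
above the modal bin, and extrapolates to the best score. Two adjustments
were necessary to make that construction well-behaved, and both are
deliberate design decisions of this package:

* **Log-domain binning.** The factorial-scaled hyperscore spans many orders
  of magnitude, so "unit" bins are taken on the conventional log scale,
  $\lfloor 4\log_{10}(1+H)\rfloor$, on which search engines usually report
  hyperscores. A linear survival fit on the raw score would model a
  power-law tail with an exponential and fail.
* **A pooled run-level null.** At 10/20 ppm tolerances a random candidate
  almost always matches zero fragments, so a single spectrum's candidate
  pool (even widened to a ±50 Da background window, deterministically
  thinned to ≤300 forms) rarely contains enough non-zero scores to fit a
  tail. `search_run` therefore pools the background scores of all spectra
  in the run into one null distribution, excluding every candidate form of
  each spectrum's best-hit peptide sequence so genuine matches cannot
  flatten the tail, and computes each spectrum's expect as its own
  candidate count times the pooled tail probability at its best score.
  The per-spectrum estimator (`expect_value`) remains available and is used
  when the pooled fit is degenerate. Expect values are clamped to
  (1e-20, 1e3].

The exclusion rule matters for the two-step comparison: leaving any
residual signal in the null inflates borderline expects in the small
reduced database, which is precisely where the two-step strategy must be
*more* sensitive than a direct search, not less.

## FDR control

PSMs (one best hit per spectrum; ties break to the lexicographically
smaller peptide) are sorted by descending hyperscore; the running FDR at
rank $i$ is $\#decoys_{\le i} / \max(1, \#targets_{\le i})$ and q-values
are its running minimum from below. The simple decoys/targets estimator
(rather than $2D/(T+D)$) is the standard choice in the two-step literature,
where the reduced database is small. A peptide present in both a target and
a decoy protein counts as target — the conservative convention. Spectra
with unknown precursor charge are searched as 2+ and 3+ and the global best
is kept.

## Quantification

**Features.** The precursor intensity is read from the MGF `PEPMASS` line
(the synthetic generator plants it there); when absent, the summed raw
fragment intensity serves as a proxy. MS1 feature detection from profile
data is out of scope — a documented divergence from full MaxQuant-style
pipelines, which extract XICs from raw data. Features are aggregated to one
row per peptide sequence and sample.

**Match-between-runs.** For every ordered run pair, a LOWESS retention-time
mapping is fit on the peptides MS/MS-identified in both runs (pairs more
than 20 min apart are excluded as outliers; fewer than 5 shared peptides
skips the pair). A donor peptide absent from the acceptor is transferred
when an *unidentified* acceptor spectrum's precursor lies within 10 ppm of
the donor m/z and within 5 min of the aligned retention time; the nearest
candidate in time wins, each acceptor spectrum is consumed at most once,
and a peptide is never transferred into a run where it was identified.

**Grouping and razor peptides.** Proteins identified by the same set or a
subset of another protein's peptides merge into that protein's group.
Proteins are ranked by peptide count, then PSM count, then coverage, with
lexicographic accession as the deterministic tie-break; each protein joins
the first-ranked group whose founder covers its peptide set, so grouping is
order-invariant and idempotent. Peptides spanning several groups are
assigned once, as razor peptides, to the group with most evidence (same
tie-break cascade), so every quantified feature is used exactly once.

**MaxLFQ.** Per group and sample pair, the median of log peptide-intensity
ratios over peptides observed in both samples (at least `min_ratio_count`,
default 1) defines an edge of a ratio graph. Per connected component,
per-sample log abundances solve the least-squares system
$x_i - x_j = r_{ij}$ with a mean-zero anchor row, then the profile is
rescaled so its sum equals the component's summed raw intensity. Samples
outside any component stay missing; a singleton component receives its raw
intensity sum. On noise-free consistent data this reconstruction is exact
up to the global group scale, which the test suite asserts at 1e-6 against
an independent normal-equations solution.

## Functional and taxonomic analysis

COG annotations arrive as a precomputed table (the alignment step producing
them is off-the-shelf and out of scope). A group is annotated by its
leading protein, falling back to the next-ranked members; unannotated
groups accumulate in category `?`. In the default `primary` mode a
multi-letter category string contributes its first letter only, which keeps
the conservation identity (category sums equal total group LFQ per sample)
exact; the `each` mode credits the full group intensity to every listed
letter, for users who prefer the multi-membership view.

Taxonomy uses an index from I/L-collapsed tryptic peptides of taxon-labeled
reference proteins to taxon sets. A peptide's assignment is the lowest
common ancestor of its taxon set; a peptide with internal cleavage sites
that is absent from the index is resolved by intersecting the taxon sets of
its fully tryptic parts (mirroring the "advanced missed cleavage" handling
of unique-peptide taxonomy tools). Relative abundance at a rank divides
each taxon's summed unique-peptide intensity by the sample's total
identified peptide intensity — unassigned peptides dilute the denominator
but claim no taxon. The Firmicutes/Bacteroidetes ratio is reported per
sample and flagged undefined (not infinite) when Bacteroidetes intensity
is zero; it is invariant to the per-sample normalization by construction.
The rank at which "unique peptides" are counted is a parameter, since
different studies report phylum- or species-level bars.

## Statistics

The group comparison follows the Perseus-style pipeline: presence filter
(default fraction 29/32 ≈ 0.906 of samples with valid values), log10
transform, two-sample t-test per row with Benjamini–Hochberg correction and
significance at q < 0.05. Welch's unequal-variance test is the default —
the more defensible choice when only "two-sample t test" is specified —
with the pooled-variance variant behind `var_equal = TRUE`. Fold changes
are group1 − group2 on the log10 scale of observed values only (no
imputation feeds the tests); flags mark ≥2-fold and ≥100-fold responders.
BH is implemented explicitly (step-up $q_{(i)} = \min_{j\ge i} p_{(j)} m/j$)
and cross-checked against `p.adjust` to 1e-12 in the tests. The
Mann–Whitney test enumerates the exact permutation distribution of U for
groups of ≤8 (valid under ties, where `wilcox.test`'s exact branch is
unavailable) and otherwise uses the normal approximation with tie and
continuity corrections. Imputation for PCA and clustering only: k-nearest
rows (k = 1, the classical `knnimpute` default) on Euclidean distance over
shared columns; PCA is `prcomp` on centered sample profiles; heat-map
clustering is UPGMA (average linkage, Euclidean) via `hclust`, exported to
Newick through `ape`.

Whether repeated time points should be treated as independent samples or
per-subject averages is a genuine modelling fork; both are possible by
choosing the columns passed to `ttest_bh`, and repeated-measures modelling
is explicitly out of scope.

## The synthetic-study generator

`community_spec`/`make_catalog`/`make_study` define the study conditions
under which the package is tested. A catalog of random proteins (length
100–600, bacterial-like residue frequencies with ~11 % K/R so tryptic
peptides average ~9 residues) is partitioned over a fixed five-phylum,
20-species taxonomy with Firmicutes and Bacteroidetes dominant; 90 % of
proteins get a COG annotation. A study draws `n_true` expressed proteins
with lognormal base abundances (log10 sd 0.5), a fixed per-protein peptide
panel, study-wide retention times and ionization efficiencies, and
per-sample intensities with lognormal CV 10 %. Spectra are b/y ladders with
partial fragment coverage (uniform 45–95 %), Gaussian m/z jitter of 5 ppm
on fragments and 3 ppm on precursors (inside the 20/10 ppm tolerances), a
few random peaks, and the planted precursor intensity on the `PEPMASS`
line. Noise spectra (default one third of the acquisition) are
shuffled-peak copies of real spectra at random precursor masses, so they
are score-plausible but unexplainable. Dropout occurrences keep their
precursor (m/z, RT, intensity) but carry shuffled fragments — they fail
MS/MS identification yet are recoverable by match-between-runs, emulating
precursors that were not usefully fragmented. All randomness flows from one
mandatory seed, with per-sample streams derived by a stable string hash, so
catalogs, spectra and truth tables regenerate byte-identically.

What the generator does not emulate: chromatographic peak shapes, isotope
envelopes, co-isolation chimeras, charge-state mixtures of one peptide,
semi-tryptic products, and homology structure between catalog proteins
(random sequences share almost no peptides). Passing tests therefore
demonstrate the correctness and calibration of the algorithms under the
stated statistical model of the data, not instrument-level realism; real
spectra have richer null structure, which the pooled expect estimator and
target-decoy control absorb by construction but which these tests cannot
probe.

Reference problem sizes used by the test suite and acceptance script: the
calibration study uses a 1,000-protein catalog with 100 expressed proteins
(~800 informative + ~400 noise spectra per sample) across ten seeds; the
quantification study 6 samples at 10 % CV with 20 % dropout; the two-group
study 8 samples (4 + 4) with a planted 3:1 Firmicutes shift and 20 planted
4-fold differential proteins. These sizes were chosen so each stage is
exercised at realistic identification rates while keeping whole-suite runs
convenient on a laptop.

## Numerical details and degenerate inputs

* Tolerances are relative (ppm) everywhere; window bounds are closed.
* Deterministic tie-breaks: best PSM by score, then expect, then peptide
  string; leading proteins and razor winners by the count cascade then
  accession; MBR candidates by |ΔRT|.
* Background thinning for the expect null uses a regular index stride —
  no RNG inside the search path; given fixed inputs the entire workflow is
  byte-deterministic.
* Empty inputs: an empty matched set yields an empty reduced database with
  a warning and an empty identification list downstream; spectra without
  peaks after preprocessing are flagged unsearchable; zero-variance rows
  with equal means get p = 1.
* `expect = 1` is the honest fallback whenever no valid survival fit
  exists (too few candidates, fewer than three tail bins, or a
  non-negative slope).

## Known limitations

Protein-level FDR is inherited, not controlled. Scoring is a documented,
self-consistent hyperscore variant, not a bit-exact clone of any engine
release. Quantification starts from MGF precursor intensities rather than
raw-data XICs. The LCA implementation covers the supplied taxonomy table
only — no name resolution against live taxonomy services. Catalogs must be
amino-acid FASTA; nucleotide translation is out of scope.
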