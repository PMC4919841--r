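#' Presence filter on an abundance matrix
#'
#' Keeps rows with valid (finite, positive) values in at least
#' `ceil(min_frac * n_samples)` columns. The default fraction retains rows
#' valid in 29 of 32 samples.
#'
#' @param m numeric matrix (rows = protein groups or taxa, columns =
#'   samples), `NA` for missing.
#' @param min_frac required fraction of valid columns (default `29/32`).
#' @return The filtered matrix.
#' @export
presence_filter <- function(m, min_frac = 29 / 32) {
  need <- ceiling(min_frac * ncol(m))
  valid <- rowSums(is.finite(m) & m > 0)
  m[valid >= need, , drop = FALSE]
}

# Benjamini-Hochberg step-up q-values: q(i) = min_{j>=i} p_(j) * m / j.
bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Two-sample t-tests with Benjamini-Hochberg correction
#'
#' Per row, a Welch (default) two-sample t-test on log10-transformed values,
#' followed by Benjamini-Hochberg adjustment across the tested rows. The
#' fold change is the mean difference of log10 values, group 1 minus
#' group 2. Rows with fewer than two observed values in either group are
#' skipped (flagged `tested = FALSE`). Rows with zero variance in both
#' groups get p = 1 when the means are equal.
#'
#' @param m numeric matrix of LFQ intensities (`NA` missing); columns are
#'   samples.
#' @param groups character/factor vector of group labels per column, exactly
#'   two levels.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param q_cutoff significance threshold on the adjusted p-value.
#' @return Data frame: `row_id`, `log10_fc`, `p`, `q`, `significant`,
#'   `tested`, `fold2`, `fold100` (absolute fold change above 2x / 100x).
#' @export
ttest_bh <- function(m, groups, var_equal = FALSE, q_cutoff = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two group labels required")
  lm10 <- log10(m)
  res <- data.frame(row_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    log10_fc = NA_real_, p = NA_real_, q = NA_real_,
                    significant = FALSE, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    a <- lm10[i, groups == lv[1L]]
    b <- lm10[i, groups == lv[2L]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) next
    res$tested[i] <- TRUE
    res$log10_fc[i] <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      res$p[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 2.2e-16
    } else {
      res$p[i] <- stats::t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  tested <- which(res$tested)
  if (length(tested)) res$q[tested] <- bh_adjust(res$p[tested])
  res$significant <- res$tested & !is.na(res$q) & res$q < q_cutoff
  res$fold2 <- abs(res$log10_fc) >= log10(2)
  res$fold100 <- abs(res$log10_fc) >= 2
  res
}

#' Mann-Whitney U test
#'
#' Two-sided. For groups of at most `exact_max` observations each, the exact
#' permutation distribution of U is enumerated (valid with ties); larger
#' groups use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric vectors (each of length >= 3).
#' @param exact_max enumeration threshold per group (default 8).
#' @return List with `U` (statistic of the first group) and `p`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 3L || n2 < 3L) stop("each group needs at least 3 observations")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (all(pooled == pooled[1L])) return(list(U = U, p = 1))
  if (max(n1, n2) <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= U), mean(u_all >= U))
    return(list(U = U, p = min(1, p)))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' k-nearest-neighbour imputation of missing values
#'
#' Rows with all values missing are dropped. Each missing cell is filled
#' with the mean value of that column over the `k` nearest rows (Euclidean
#' distance over the columns observed in both rows, normalized by the
#' number of shared columns) that observe the column. Defaults to k = 1.
#'
#' @param m numeric matrix with `NA` missing values.
#' @param k number of neighbours (default 1).
#' @return The imputed matrix.
#' @export
knn_impute <- function(m, k = 1L) {
  keep <- rowSums(is.finite(m)) > 0L
  m <- m[keep, , drop = FALSE]
  if (!anyNA(m)) return(m)
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- is.finite(m[i, ]) & is.finite(m[j, ])
      if (!any(shared)) next
      d[i, j] <- d[j, i] <- sqrt(mean((m[i, shared] - m[j, shared])^2))
    }
  }
  out <- m
  for (i in seq_len(n)) {
    miss <- which(!is.finite(m[i, ]))
    if (!length(miss)) next
    ord <- order(d[i, ])
    for (cc in miss) {
      donors <- ord[is.finite(m[ord, cc]) & is.finite(d[i, ord])]
      if (!length(donors)) next
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, cc] <- mean(m[use, cc])
    }
  }
  out
}

#' kNN imputation followed by PCA over samples
#'
#' The matrix is log10-transformed, missing values are imputed with
#' [knn_impute()], and a PCA is computed on the centered sample profiles
#' (samples as observations). The first two principal-component scores are
#' the usual score-plot coordinates.
#'
#' @param m LFQ matrix (rows = proteins, columns = samples).
#' @param k neighbours for imputation.
#' @param log_transform log10-transform first? (default TRUE)
#' @return List with `scores` (samples x 2), `loadings`, `sdev` and the
#'   imputed matrix.
#' @export
knn_impute_pca <- function(m, k = 1L, log_transform = TRUE) {
  x <- if (log_transform) log10(m) else m
  x[!is.finite(x)] <- NA
  x <- knn_impute(x, k)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  list(scores = pc$x[, 1:2, drop = FALSE],
       loadings = pc$rotation, sdev = pc$sdev, imputed = x)
}

#' Average-linkage hierarchical clustering of rows and columns
#'
#' UPGMA (average linkage) on Euclidean distances, as used for expression
#' heat maps.
#'
#' @param m numeric matrix without missing values.
#' @return List with `rows` and `cols` (`hclust` objects).
#' @export
hcluster_matrix <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least 2 rows and columns")
  if (anyNA(m)) stop("missing values present; impute first")
  list(rows = stats::hclust(stats::dist(m), method = "average"),
       cols = stats::hclust(stats::dist(t(m)), method = "average"))
}

#' Newick string for a dendrogram
#'
#' @param hc an `hclust` object.
#' @return Newick string (with branch lengths).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
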