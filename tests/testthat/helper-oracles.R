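# Independent brute-force reference implementations used to cross-check the
# package's optimized code paths. Deliberately naive and self-contained.

PROTON <- 1.007276
WATER <- 18.010565

# Hyperscore by direct enumeration: all b/y singly charged ions, all
# fragment-peak pairs within tolerance, greedy assignment by |ppm error|.
oracle_hyperscore <- function(peaks, res, tol_ppm) {
  L <- length(res)
  if (L < 2 || nrow(peaks) == 0) return(list(score = 0, n_b = 0, n_y = 0))
  bions <- PROTON + cumsum(res)[-L]
  yions <- PROTON + WATER + cumsum(rev(res))[-L]
  frag <- c(bions, yions)
  pairs <- NULL
  for (f in seq_along(frag)) {
    for (p in seq_len(nrow(peaks))) {
      err <- abs(peaks[p, 1] - frag[f]) / frag[f] * 1e6
      if (err <= tol_ppm) pairs <- rbind(pairs, c(err, f, p))
    }
  }
  if (is.null(pairs)) return(list(score = 0, n_b = 0, n_y = 0))
  pairs <- pairs[order(pairs[, 1], pairs[, 2], pairs[, 3]), , drop = FALSE]
  used_f <- used_p <- integer(0)
  dot <- 0; n_b <- 0; n_y <- 0
  for (k in seq_len(nrow(pairs))) {
    f <- pairs[k, 2]; p <- pairs[k, 3]
    if (f %in% used_f || p %in% used_p) next
    used_f <- c(used_f, f); used_p <- c(used_p, p)
    dot <- dot + unname(peaks[p, 2])
    if (f <= L - 1) n_b <- n_b + 1 else n_y <- n_y + 1
  }
  cap_fact <- function(n) factorial(min(n, 10))
  list(score = dot * cap_fact(n_b) * cap_fact(n_y), n_b = n_b, n_y = n_y)
}

# Candidate retrieval by linear scan.
oracle_candidates <- function(forms, precursor_mz, charge, tol_ppm) {
  m <- precursor_mz * charge - charge * PROTON
  forms[abs(forms$mass - m) <= m * tol_ppm * 1e-6, , drop = FALSE]
}

# Subset-rule protein grouping: rank proteins, then greedily attach each
# protein to the first already-formed group whose founder covers it.
oracle_group_proteins <- function(pep2prot) {
  prot2pep <- list()
  for (pep in names(pep2prot)) {
    for (acc in pep2prot[[pep]]) {
      prot2pep[[acc]] <- union(prot2pep[[acc]], pep)
    }
  }
  accs <- names(prot2pep)
  ord <- accs[order(-lengths(prot2pep), accs)]
  founders <- character(0)
  membership <- list()
  for (acc in ord) {
    assigned <- FALSE
    for (f in founders) {
      if (all(prot2pep[[acc]] %in% prot2pep[[f]])) {
        membership[[f]] <- c(membership[[f]], acc)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      founders <- c(founders, acc)
      membership[[acc]] <- acc
    }
  }
  membership
}

# Naive UPGMA on a distance matrix; returns the cophenetic matrix.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n)
  dist_cl <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  while (sum(active) > 1) {
    ids <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in ids) for (j in ids) {
      if (i >= j) next
      dd <- dist_cl(i, j)
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- bestd
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- bestd
    clusters[[length(clusters) + 1]] <- c(clusters[[best[1]]],
                                          clusters[[best[2]]])
    active[best] <- FALSE
    active <- c(active, TRUE)
  }
  coph
}

# Ancestor-set intersection LCA.
oracle_lca <- function(taxa, tree) {
  root <- attr(tree, "root")
  anc_set <- function(t) {
    out <- t
    while (t != root) {
      t <- tree$parent_id[match(t, tree$taxon_id)]
      out <- c(out, t)
    }
    out
  }
  common <- Reduce(intersect, lapply(taxa, anc_set))
  depth <- vapply(common, function(t) length(anc_set(t)), numeric(1))
  common[which.max(depth)]
}

# Welch t-test p-value from first principles.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# MaxLFQ profile by explicit normal equations over all sample pairs
# (assumes the ratio graph is connected over the observed samples).
oracle_maxlfq_profile <- function(mat, min_count = 1) {
  ns <- ncol(mat)
  A <- NULL; b <- NULL
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      both <- which(!is.na(mat[, i]) & !is.na(mat[, j]) &
                      mat[, i] > 0 & mat[, j] > 0)
      if (length(both) < min_count) next
      row <- rep(0, ns); row[i] <- 1; row[j] <- -1
      A <- rbind(A, row)
      b <- c(b, median(log(mat[both, i] / mat[both, j])))
    }
  }
  A <- rbind(A, rep(1, ns)); b <- c(b, 0)
  x <- solve(t(A) %*% A, t(A) %*% b)[, 1]
  prof <- exp(x)
  prof * sum(mat, na.rm = TRUE) / sum(prof)
}
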