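# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and the stats:: shortcuts) the package uses:
# everything is explicit loops over the definitions.

# average ranks by explicit pairwise comparison
rank_oracle <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      if (x[j] < x[i]) r[i] <- r[i] + 1
      else if (x[j] == x[i]) r[i] <- r[i] + 0.5
    }
  }
  r
}

# Spearman rho: Pearson product-moment formula on oracle ranks, via sums
spearman_oracle <- function(x, y) {
  rx <- rank_oracle(x); ry <- rank_oracle(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (rx[i] - mx) * (ry[i] - my)
    sxx <- sxx + (rx[i] - mx)^2
    syy <- syy + (ry[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Kendall tau-b by O(n^2) concordance counting with tie correction
kendall_oracle <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  (nc - nd) / sqrt((nc + nd + tx) * (nc + nd + ty))
}

# median-of-ratios size factors by explicit per-sample loops
size_factor_oracle <- function(counts) {
  ref <- which(apply(counts, 1, function(g) all(g > 0)))
  geo <- numeric(length(ref))
  for (k in seq_along(ref)) geo[k] <- exp(mean(log(counts[ref[k], ])))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- numeric(length(ref))
    for (k in seq_along(ref)) ratios[k] <- counts[ref[k], j] / geo[k]
    sf[j] <- median(ratios)
  }
  setNames(sf, colnames(counts))
}

# quantile normalization with the mean-of-spanned-quantiles tie rule
quantile_oracle <- function(X) {
  n <- nrow(X)
  sorted <- apply(X, 2, sort)
  ref <- rowMeans(sorted)
  out <- X
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    vals <- X[o, j]
    i <- 1
    while (i <= n) {
      k <- i
      while (k < n && vals[k + 1] == vals[i]) k <- k + 1
      out[o[i:k], j] <- mean(ref[i:k])
      i <- k + 1
    }
  }
  out
}

# expression filter: the stated rule as explicit loops
filter_oracle <- function(counts, group, min_count = 10, min_total = 15) {
  lib <- colSums(counts)
  cutoff <- min_count / median(lib) * 1e6
  n_min <- min(table(group))
  keep <- character()
  for (g in rownames(counts)) {
    n_ok <- 0
    for (j in seq_len(ncol(counts)))
      if (counts[g, j] / lib[j] * 1e6 >= cutoff) n_ok <- n_ok + 1
    if (n_ok >= n_min && sum(counts[g, ]) >= min_total)
      keep <- c(keep, g)
  }
  keep
}

# small labelled count matrix helper
rand_counts <- function(ng, n, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rnbinom(ng * n, mu = lambda, size = 5), ng, n,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%03d", seq_len(n))))
  expression_matrix(m, "raw_counts")
}

# Jaccard index between two gene sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# best Jaccard of a target set over the reported clusters of a cluster set
best_jaccard <- function(cluster_set, target) {
  if (!length(cluster_set$clusters)) return(0)
  max(vapply(cluster_set$clusters, jaccard, numeric(1), b = target))
}

# a small catalog used across io/normalization tests
demo_catalog <- function() {
  matrisome_catalog(
    c("COL1", "COL2", "PRG1", "GLY1", "GLY2", "REG1", "REG2", "AFF1",
      "SEC1", "SEC2"),
    category = c("collagens", "collagens", "proteoglycans",
                 "ECM_glycoproteins", "ECM_glycoproteins", "ECM_regulators",
                 "ECM_regulators", "ECM_affiliated", "secreted_factors",
                 "secreted_factors"))
}
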