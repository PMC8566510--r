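# shared fixture: two correlated blocks plus noise genes, n samples
make_block_data <- function(n = 100, k = 15, noise_genes = 30, sd_noise = 0.6,
                            anti = FALSE, seed = 50) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  blockA <- t(sapply(seq_len(k), function(i) f1 + rnorm(n, 0, sd_noise)))
  blockB <- if (anti)
    t(sapply(seq_len(k), function(i) -f1 + rnorm(n, 0, sd_noise)))
  else t(sapply(seq_len(k), function(i) f2 + rnorm(n, 0, sd_noise)))
  X <- rbind(blockA, blockB)
  if (noise_genes > 0) X <- rbind(X, matrix(rnorm(noise_genes * n), noise_genes))
  rownames(X) <- c(sprintf("A%02d", seq_len(k)), sprintf("B%02d", seq_len(k)),
                   if (noise_genes > 0) sprintf("N%02d", seq_len(noise_genes)))
  colnames(X) <- sprintf("s%03d", seq_len(n))
  expression_matrix(X + 10, "vst")
}

test_that("the high-variance filter applies both thresholds strictly", {
  m <- rbind(const = rep(6, 20),
             lowmean = rnorm(20, 2, 2),
             lowvar = rnorm(20, 8, 0.1),
             good = rnorm(20, 8, 3))
  colnames(m) <- paste0("s", 1:20)
  em <- expression_matrix(m - min(m) + 0.1, "vst")
  # recompute thresholds relative to the shifted matrix
  v <- em_values(em)
  kept <- high_variance_filter(em, mean_min = 5, var_min = 1.5)
  manual <- rownames(v)[apply(v, 1, mean) > 5 &
                          apply(v, 1, var) > 1.5]
  expect_identical(sort(kept), sort(manual))
  expect_false("const" %in% kept)
  expect_error(high_variance_filter(em, mean_min = 1e6), "no gene passes")
})

test_that("tau-critical matches the closed form and its permutation oracle", {
  # n = 10, one gene pair: z_{0.975} * sqrt(50 / 810)
  expect_equal(tau_critical(10, 2, 0.05),
               qnorm(0.975) * sqrt(2 * 25 / (9 * 10 * 9)), tolerance = 1e-12)
  expect_equal(tau_critical(10, 2, 0.05), 0.487, tolerance = 1e-3)
  # strictly decreasing in n_samples at fixed pair count
  tc <- sapply(5:40, tau_critical, n_genes = 2, alpha = 0.05)
  expect_true(all(diff(tc) < 0))
  # Bonferroni: more genes -> larger threshold
  expect_gt(tau_critical(20, 50), tau_critical(20, 2))
  expect_error(tau_critical(3, 10), "n_samples")
  expect_error(tau_critical(10, 1), "n_genes")

  # permutation oracle at n = 12: null tau quantile within 0.03 of formula
  set.seed(51)
  x <- rnorm(12)
  taus <- replicate(20000, cor(x, sample(x), method = "kendall"))
  emp <- quantile(taus, 0.975, names = FALSE)
  expect_lt(abs(emp - tau_critical(12, 2, 0.05)), 0.03)
})

test_that("planted blocks are recovered and reported clusters honor the
           tau bound", {
  em <- make_block_data()
  cs <- cut_clusters(em)
  expect_gte(best_jaccard(cs, sprintf("A%02d", 1:15)), 0.9)
  expect_gte(best_jaccard(cs, sprintf("B%02d", 1:15)), 0.9)
  for (genes in cs$clusters) {
    sub <- cs$tau[genes, genes]
    expect_gte(mean(sub[upper.tri(sub)]), cs$tau_critical)
    expect_gte(length(genes), 2)
  }
  # clusters are disjoint
  expect_equal(anyDuplicated(unlist(cs$clusters)), 0)
})

test_that("anti-correlated programs come back as paired sub-clusters", {
  em <- make_block_data(anti = TRUE, noise_genes = 0, sd_noise = 0.4,
                        seed = 52)
  cs <- cut_clusters(em)
  expect_equal(length(cs$clusters), 2)
  expect_true(all(grepl("\\.", names(cs$clusters))))  # c1.1 / c1.2 labels
  expect_equal(cs$parent, c(1L, 1L))                  # one parent cluster
  expect_gte(best_jaccard(cs, sprintf("A%02d", 1:15)), 0.9)
  expect_gte(best_jaccard(cs, sprintf("B%02d", 1:15)), 0.9)
})

test_that("i.i.d. noise genes produce no clusters", {
  set.seed(53)
  X <- matrix(rnorm(40 * 80), 40, 80,
              dimnames = list(sprintf("N%02d", 1:40), sprintf("s%03d", 1:80)))
  expect_warning(cs <- cut_clusters(expression_matrix(X + 10, "vst")),
                 "no partition")
  expect_length(cs$clusters, 0)
})

test_that("cluster membership is invariant to gene input order", {
  em <- make_block_data(n = 60, k = 8, noise_genes = 10, seed = 54)
  cs1 <- cut_clusters(em)
  set.seed(55)
  perm <- sample(nrow(em$values))
  em2 <- expression_matrix(em_values(em)[perm, , drop = FALSE], "vst")
  cs2 <- cut_clusters(em2)
  expect_equal(unname(lapply(cs1$clusters, sort)),
               unname(lapply(cs2$clusters, sort)))
})

test_that("cluster scores reproduce the hand example and its invariants", {
  em <- expression_matrix(
    matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("g1", paste0("s", 1:4))),
    "vst")
  st <- data.frame(sample_id = paste0("s", 1:4), tissue = "T1")
  sc <- cluster_score(em, st, "g1")
  # centers 2.5, MAD 1.0, contributions (-1.5, -0.5, 0.5, 1.5)
  expect_equal(sc$score, c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(unname(attr(sc, "centers")[1, 1]), 2.5)
  expect_equal(unname(attr(sc, "mads")[1, 1]), 1)
  # two identical genes: J = 2, same score vector
  em2 <- expression_matrix(rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4)) |>
                             `colnames<-`(paste0("s", 1:4)), "vst")
  sc2 <- cluster_score(em2, st, c("g1", "g2"))
  expect_equal(sc2$score, sc$score)
  expect_equal(unname(attr(sc2, "J")["T1"]), 2L)
})

test_that("cluster scores are tissue-centered and affine-invariant", {
  set.seed(56)
  genes <- sprintf("g%02d", 1:6)
  m <- matrix(rnorm(6 * 30, 8, 2), 6, 30,
              dimnames = list(genes, sprintf("s%02d", 1:30)))
  st <- data.frame(sample_id = colnames(m),
                   tissue = rep(c("T1", "T2"), 15))
  sc <- cluster_score(expression_matrix(m, "vst"), st, genes)
  for (tt in c("T1", "T2"))
    expect_equal(mean(sc$score[sc$tissue == tt]), 0, tolerance = 1e-13)
  # a sample sitting exactly at the gene means scores zero
  vals <- rbind(g1 = c(5, 5, 1, 9), g2 = c(3, 3, 1, 5))
  colnames(vals) <- paste0("s", 1:4)
  stc <- data.frame(sample_id = paste0("s", 1:4), tissue = "T1")
  scc <- cluster_score(expression_matrix(vals, "vst"), stc, c("g1", "g2"))
  expect_equal(scc$score[1], 0)   # s1 equals both gene means (5 and 3)
  # per-gene positive scaling and constant shifts leave scores unchanged
  m3 <- m * matrix(rep(c(2, 0.5, 3, 1, 7, 10), 30), 6, 30) +
    matrix(rep(c(-3, 0, 5, 1, 2, -8), 30), 6, 30)
  dimnames(m3) <- dimnames(m)
  sc3 <- cluster_score(expression_matrix(m3, "vst"), st, genes)
  expect_equal(sc3$score, sc$score, tolerance = 1e-12)
})

test_that("zero-MAD genes are excluded per tissue with J adjusted", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4))
  colnames(vals) <- paste0("s", 1:4)
  st <- data.frame(sample_id = paste0("s", 1:4), tissue = "T1")
  expect_warning(sc <- cluster_score(expression_matrix(vals, "vst"), st,
                                     c("g1", "g2")),
                 "zero-MAD")
  expect_equal(unname(attr(sc, "J")["T1"]), 1L)
  expect_equal(sc$score, c(-1.5, -0.5, 0.5, 1.5))
  expect_error(suppressWarnings(cluster_score(
    expression_matrix(vals[2, , drop = FALSE], "vst"), st, "g2")),
    "zero MAD")
})

test_that("association models recover fixed effects and reject singular
           designs", {
  d <- data.frame(y = 1 + 2 * (1:12) + 3 * rep(0:1, 6), x = 1:12,
                  z = rep(0:1, 6))
  fit <- suppressWarnings(association_models(d, "y", c("x", "z")))
  expect_equal(fit$coefficients$estimate, c(1, 2, 3), tolerance = 1e-10)
  d$w <- d$x * 2
  expect_error(association_models(d, "y", c("x", "w")), "singular|aliased")
})

test_that("the random-intercept model recovers a small slope across
           replicates", {
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    set.seed(600 + r)
    n_subj <- 14; n_meas <- 4
    subj <- rep(sprintf("P%02d", 1:n_subj), each = n_meas)
    u <- rnorm(n_subj, 0, 1)[rep(1:n_subj, each = n_meas)]
    score <- rnorm(n_subj * n_meas, 0, 10)
    y <- 2 + 0.03 * score + u + rnorm(n_subj * n_meas, 0, 0.5)
    d <- data.frame(y = y, score = score, subject = subj)
    fit <- association_models(d, "y", "score", random_intercept = "subject")
    est <- fit$coefficients[fit$coefficients$term == "score", ]
    if (abs(est$estimate - 0.03) <= 3 * est$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("sex has calibrated p-values under a permuted null", {
  set.seed(57)
  pvals <- replicate(150, {
    d <- data.frame(y = rnorm(40), sex = sample(rep(c("M", "F"), 20)))
    fit <- association_models(d, "y", "sex")
    fit$coefficients$p[2]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("multi-tissue gene scores average across required tissues", {
  v <- matrix(5, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  v["g1", ] <- c(1, 2, 3, 4, 5, 6, 7, 8)
  st <- data.frame(sample_id = paste0("s", 1:8),
                   subject_id = rep(c("A", "B"), 4),
                   tissue = rep(c("T1", "T2", "T3", "T4"), each = 2))
  sc <- multi_tissue_gene_score(expression_matrix(v, "vst"), st, "g1",
                                c("T1", "T2", "T3", "T4"))
  expect_equal(sc[["A"]], mean(c(1, 3, 5, 7)))
  expect_equal(sc[["B"]], mean(c(2, 4, 6, 8)))
  # identical values in all tissues give the value itself
  sc3 <- multi_tissue_gene_score(expression_matrix(v, "vst"), st, "g3",
                                 c("T1", "T2", "T3", "T4"))
  expect_true(all(sc3 == 5))
  # subject missing a tissue is excluded and logged
  st2 <- st[-1, ]
  sc2 <- multi_tissue_gene_score(expression_matrix(v[, -1], "vst"), st2,
                                 "g1", c("T1", "T2", "T3", "T4"))
  expect_identical(attr(sc2, "excluded"), "A")
  expect_identical(names(sc2), "B")
})

test_that("extreme-subject selection is seeded, masked, and bounded", {
  scores <- setNames(c(10, 8, 6, 4, 2, 1), paste0("P", 1:6))
  sel <- select_extremes(scores, top = 2, bottom = 2, seed = 3)
  expect_setequal(sel$subject_id[sel$group == "high"], c("P1", "P2"))
  expect_setequal(sel$subject_id[sel$group == "low"], c("P5", "P6"))
  expect_identical(sel$masked_id, sprintf("S%02d", 1:4))
  sel2 <- select_extremes(scores, top = 2, bottom = 2, seed = 3)
  expect_identical(sel, sel2)
  expect_error(select_extremes(scores, top = 4, bottom = 4), "exceeds")
  sex <- setNames(rep(c("M", "F"), 3), paste0("P", 1:6))
  sel3 <- select_extremes(scores, top = 1, bottom = 1, by_sex = sex, seed = 4)
  expect_equal(nrow(sel3), 4)
})

test_that("sample clustering centers genes and separates planted groups", {
  set.seed(58)
  n1 <- 20; n2 <- 20
  m <- cbind(matrix(rnorm(10 * n1, 0), 10),
             matrix(rnorm(10 * n2, 4), 10))
  dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:(n1 + n2)))
  st <- data.frame(sample_id = colnames(m),
                   disease = rep(c("normal", "IPF"), c(n1, n2)))
  out <- sample_cluster(expression_matrix(m + 10, "vst"), k = 2, samples = st)
  expect_equal(unname(rowMeans(out$centered)), rep(0, 10), tolerance = 1e-12)
  ct <- out$crosstab
  agreement <- max(ct[1, 1] + ct[2, 2], ct[1, 2] + ct[2, 1]) / sum(ct)
  expect_gte(agreement, 0.95)
  # duplicate samples land together
  dup <- expression_matrix(cbind(m + 10, s99 = m[, 1] + 10), "vst")
  outd <- sample_cluster(dup, k = 2)
  expect_equal(unname(outd$groups["s99"]), unname(outd$groups["s01"]))
  expect_error(sample_cluster(expression_matrix(m + 10, "vst"), k = 100),
               "exceeds")
})
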