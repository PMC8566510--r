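test_that("median-ratio size factors match hand computation and symmetry", {
  m <- matrix(c(2, 8, 4, 16), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- median_ratio_size_factors(expression_matrix(m, "raw_counts"))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- matrix(7, 5, 3, dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  sf2 <- median_ratio_size_factors(expression_matrix(same, "raw_counts"))
  expect_equal(unname(sf2), rep(1, 3))
})

test_that("scaling one sample's counts follows the exact median-ratio
           transformation law", {
  # scaling column 3 by c multiplies every geometric mean by c^(1/n), so
  # factor 3 scales by c^(1 - 1/n), the others by c^(-1/n); relative depth
  # (ratios of factors) scales by exactly c
  em <- rand_counts(40, 6, seed = 1)
  sf <- median_ratio_size_factors(em)
  v <- em_values(em)
  cc <- 4
  v[, 3] <- v[, 3] * cc
  sf2 <- median_ratio_size_factors(expression_matrix(v, "raw_counts"))
  n <- ncol(v)
  expect_equal(sf2[3], sf[3] * cc^(1 - 1 / n), tolerance = 1e-12)
  expect_equal(sf2[-3], sf[-3] * cc^(-1 / n), tolerance = 1e-12)
  expect_equal(unname(sf2[3] / sf2[1]), unname(cc * sf[3] / sf[1]),
               tolerance = 1e-12)
})

test_that("size factors agree with the reference implementation", {
  # the reference takes the median of log ratios; with an odd reference-gene
  # count the two medians coincide exactly
  set.seed(2)
  m <- matrix(rnbinom(31 * 8, mu = 60, size = 5) + 1, 31, 8,
              dimnames = list(sprintf("g%02d", 1:31), sprintf("s%02d", 1:8)))
  ours <- median_ratio_size_factors(expression_matrix(m, "raw_counts"))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("size factors error when no gene is positive everywhere", {
  m <- matrix(c(0, 5, 5, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(median_ratio_size_factors(expression_matrix(m, "raw_counts")),
               "no gene has positive counts")
})

test_that("VST is monotone per gene, constant on constant genes, and
           order-invariant", {
  em <- rand_counts(60, 8, seed = 2, lambda = 200)
  v <- em_values(em)
  v["g001", ] <- 55   # constant gene
  em <- expression_matrix(v, "raw_counts")
  out <- suppressWarnings(vst_transform(em))
  tv <- em_values(out)
  expect_equal(em_units(out), "vst")
  # strictly increasing in normalized counts within each gene
  sf <- attr(out, "size_factors")
  nx <- sweep(v, 2, sf, "/")
  for (g in c("g005", "g020")) {
    o <- order(nx[g, ])
    expect_true(all(diff(tv[g, o]) >= 0))
  }
  # with identical samples (unit size factors) a constant gene maps to a
  # constant transformed value
  dup <- em_values(rand_counts(30, 1, seed = 11, lambda = 300))[, 1]
  same <- matrix(dup, 30, 5, dimnames = list(names(dup), paste0("s", 1:5)))
  outc <- suppressWarnings(vst_transform(expression_matrix(same, "raw_counts")))
  expect_equal(apply(em_values(outc), 1, var), setNames(rep(0, 30), names(dup)))
  # gene-order invariance
  set.seed(12)
  perm <- sample(nrow(v))
  out2 <- suppressWarnings(vst_transform(
    expression_matrix(v[perm, , drop = FALSE], "raw_counts")))
  expect_equal(em_values(out2)[rownames(v), ], tv, tolerance = 1e-12)
})

test_that("VST approaches 2*sqrt shape on Poisson-like counts", {
  set.seed(3)
  lam <- exp(runif(400, 2, 6))
  m <- matrix(rpois(400 * 40, rep(lam, 40)), 400,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:40)))
  em <- expression_matrix(m, "raw_counts")
  out <- suppressWarnings(vst_transform(em))
  sf <- attr(out, "size_factors")
  nx <- sweep(m, 2, sf, "/")
  expect_gt(cor(as.vector(em_values(out)), sqrt(as.vector(nx))), 0.999)
})

test_that("VST recovers a planted dispersion trend within 20%", {
  set.seed(4)
  ng <- 2000; n <- 100
  a_true <- 3; b_true <- 0.05
  mu <- exp(rnorm(ng, 5, 1.5))
  phi <- a_true / mu + b_true
  m <- matrix(rnbinom(ng * n, mu = mu, size = rep(1 / phi, n)), ng,
              dimnames = list(sprintf("g%04d", 1:ng), sprintf("s%03d", 1:n)))
  out <- vst_transform(expression_matrix(m, "raw_counts"))
  trend <- attr(out, "trend")
  expect_lt(abs(trend["a"] - a_true) / a_true, 0.2)
  expect_lt(abs(trend["b"] - b_true) / b_true, 0.2)
  # log2-like at large counts
  a <- trend["a"]; b <- trend["b"]
  f <- function(x) log2((1 + a + 2 * b * x +
                           2 * sqrt(b * x * (1 + a + b * x))) / (4 * b))
  expect_equal(unname(f(2e6) - f(1e6)), 1, tolerance = 1e-3)
})

test_that("quantile normalization matches hand examples and the tie rule", {
  a <- expression_matrix(matrix(c(1, 2, 3), 3, 1,
                                dimnames = list(paste0("g", 1:3), "a")), "vst")
  b <- expression_matrix(matrix(c(4, 5, 6), 3, 1,
                                dimnames = list(paste0("g", 1:3), "b")), "vst")
  qn <- quantile_normalize(a, b)
  expect_equal(unname(em_values(qn[[1]])[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(em_values(qn[[2]])[, 1]), c(2.5, 3.5, 4.5))

  t1 <- expression_matrix(matrix(c(1, 1, 3), 3, 1,
                                 dimnames = list(paste0("g", 1:3), "a")), "vst")
  t2 <- expression_matrix(matrix(c(2, 4, 6), 3, 1,
                                 dimnames = list(paste0("g", 1:3), "b")), "vst")
  qn2 <- quantile_normalize(t1, t2)
  expect_equal(unname(em_values(qn2[[1]])[, 1]), c(2, 2, 4.5))
  expect_equal(unname(em_values(qn2[[2]])[, 1]), c(1.5, 2.5, 4.5))
})

test_that("quantile normalization: identical columns are a fixed point and
           outputs share one multiset", {
  em <- rand_counts(50, 1, seed = 5)
  two <- expression_matrix(cbind(s1 = em_values(em)[, 1],
                                 s2 = em_values(em)[, 1]), "vst")
  out <- quantile_normalize(two)
  expect_equal(em_values(out), em_values(two))

  # tie-free columns share one multiset exactly (ties instead receive
  # spanned-quantile means, which perturbs the shared distribution)
  set.seed(6)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%03d", 1:50), sprintf("s%d", 1:6)))
  out2 <- quantile_normalize(expression_matrix(m, "vst"))
  v <- em_values(out2)
  for (j in 2:ncol(v))
    expect_identical(unname(sort(v[, j])), unname(sort(v[, 1])))
})

test_that("quantile normalization rejects mismatched gene sets", {
  a <- rand_counts(10, 2, seed = 7)
  bv <- em_values(rand_counts(10, 2, seed = 8))
  rownames(bv)[1] <- "other"
  b <- expression_matrix(bv, "raw_counts")
  expect_error(quantile_normalize(a, b), "symmetric difference.*other|other")
})

test_that("category fractions match the brute-force group sums", {
  cat10 <- demo_catalog()
  genes <- c(cat10$gene_id, "BG1", "BG2")
  set.seed(9)
  m <- matrix(rexp(length(genes) * 3, 1 / 100), length(genes), 3,
              dimnames = list(genes, c("T1", "T2", "T3")))
  tpm <- expression_matrix(m, "tpm")
  cf <- category_fraction(tpm, cat10)
  expect_true(all(cf$percent >= 0 & cf$percent <= 100))
  for (i in seq_len(nrow(cf))) {
    genes_ct <- cat10$gene_id[cat10$category == cf$category[i]]
    expect_equal(cf$percent[i],
                 100 * sum(m[genes_ct, cf$tissue[i]]) / sum(m[, cf$tissue[i]]),
                 tolerance = 1e-12)
  }
  # four analyzed categories sum to <= 100
  per_tissue <- tapply(cf$percent, cf$tissue, sum)
  expect_true(all(per_tissue <= 100 + 1e-9))
  # rescaling a tissue column leaves its percentages unchanged
  m2 <- m; m2[, "T2"] <- m2[, "T2"] * 37
  cf2 <- category_fraction(expression_matrix(m2, "tpm"), cat10)
  expect_equal(cf2$percent, cf$percent, tolerance = 1e-12)
})

test_that("degenerate category fractions behave", {
  cat10 <- demo_catalog()
  m <- matrix(0, 3, 1, dimnames = list(c("COL1", "COL2", "BG"), "T1"))
  m[c("COL1", "COL2"), 1] <- c(30, 70)
  cf <- category_fraction(expression_matrix(m, "tpm"), cat10)
  expect_equal(cf$percent[cf$category == "collagens"], 100)
  expect_equal(sum(cf$percent[cf$category != "collagens"]), 0)
  m0 <- matrix(0, 2, 1, dimnames = list(c("COL1", "BG"), "T1"))
  expect_error(category_fraction(expression_matrix(m0, "tpm"), cat10),
               "zero total")
})

test_that("median tissue profiles collapse brain and match two-stage medians", {
  genes <- paste0("g", 1:4)
  tissues <- c("LUNG", "BRNCTX", "BRNCBL", "BRNAMY")
  set.seed(10)
  samples <- do.call(rbind, lapply(tissues, function(tt)
    data.frame(sample_id = paste0(tt, "_", 1:3), tissue = tt,
               stringsAsFactors = FALSE)))
  m <- matrix(rnorm(4 * 12, 10), 4, 12,
              dimnames = list(genes, samples$sample_id))
  em <- expression_matrix(m, "vst")
  prof <- median_tissue_profile(em, samples)
  pv <- em_values(prof)
  expect_true("BRAIN" %in% colnames(pv))
  for (tt in tissues)
    expect_equal(pv[, tt], apply(m[, samples$tissue == tt], 1, median))
  sub_medians <- sapply(c("BRNCTX", "BRNCBL", "BRNAMY"),
                        function(tt) pv[, tt])
  expect_equal(pv[, "BRAIN"], apply(sub_medians, 1, median))
  # single sample per tissue: profile equals the sample
  one <- expression_matrix(m[, c(1, 4), drop = FALSE], "vst")
  prof1 <- median_tissue_profile(one, samples, collapse_brain = FALSE)
  expect_equal(unname(em_values(prof1)[, "LUNG"]), unname(m[, 1]))
})
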