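#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors estimated by the median-ratio method:
#' the reference level of gene g is its geometric mean across samples, and the
#' size factor of sample j is the median over reference genes of
#' `counts[g, j] / geomean[g]`. Only genes with strictly positive counts in
#' every sample enter the reference set. Factors are returned unscaled (no
#' renormalization to unit geometric mean).
#'
#' @param counts an [expression_matrix()] with units `raw_counts` and >= 2
#'   samples.
#' @return named numeric vector of positive factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts) {
  assert_units(counts, "raw_counts")
  x <- em_values(counts)
  if (ncol(x) < 2L) stop("need >= 2 samples to estimate size factors")
  ref <- rowSums(x > 0) == ncol(x)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "median-ratio size factors are undefined ",
         "(no pseudo-reference fallback is applied)")
  geo <- exp(rowMeans(log(x[ref, , drop = FALSE])))
  sf <- apply(x[ref, , drop = FALSE], 2,
              function(col) stats::median(col / geo))
  stats::setNames(sf, colnames(x))
}

# internal: per-gene sample variance of a matrix (n-1 denominator)
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

# internal: fit the parametric dispersion trend phi(mu) = a/mu + b by
# iterated gamma GLM over gene-wise method-of-moments dispersions,
# excluding gross outliers by the ratio to the current fit.
fit_dispersion_trend <- function(mu, disp) {
  keep <- is.finite(disp) & disp > 1e-8 & mu > 0
  if (sum(keep) < 10) {
    warning("too few genes with usable dispersion estimates; ",
            "falling back to constant (b-only) dispersion trend")
    b <- if (any(keep)) stats::median(disp[keep]) else 1e-8
    return(c(a = 0, b = max(b, 1e-8)))
  }
  m <- mu[keep]; d <- disp[keep]
  coefs <- c(b = 0.1, a = 1)
  use <- rep(TRUE, length(d))
  for (iter in 1:10) {
    fit <- try(suppressWarnings(
      stats::glm(d[use] ~ I(1 / m[use]), family = stats::Gamma(link = "identity"),
                 start = unname(coefs))), silent = TRUE)
    if (inherits(fit, "try-error") || !all(is.finite(stats::coef(fit)))) break
    old <- coefs
    coefs <- c(b = unname(stats::coef(fit)[1]), a = unname(stats::coef(fit)[2]))
    pred <- coefs["a"] / m + coefs["b"]
    use <- d / pred > 1e-4 & d / pred < 15
    if (sum(abs(coefs - old) / abs(old + 1e-12)) < 1e-6) break
  }
  a <- unname(coefs["a"]); b <- unname(coefs["b"])
  if (!is.finite(a) || a <= 0) {
    warning("dispersion trend fit failed (a <= 0); ",
            "falling back to constant (b-only) dispersion")
    a <- 0
    b <- stats::median(d)
  }
  if (!is.finite(b) || b <= 0) b <- 1e-8  # Poisson-like data
  c(a = a, b = b)
}

#' Variance-stabilizing transform of raw counts
#'
#' A self-contained variance-stabilizing transform for negative-binomial
#' counts. Counts are divided by median-of-ratios size factors; gene-wise
#' dispersions are estimated by the method of moments on the normalized
#' counts (`(var - xim * mu) / mu^2`, `xim` the mean reciprocal size factor);
#' a parametric mean-dispersion trend `phi(mu) = a / mu + b` is fitted by an
#' iterated gamma GLM robust to ratio outliers; and the closed-form VST of
#' the fitted family is applied to the normalized counts:
#'
#' `vst(x) = log2( (1 + a + 2 b x + 2 sqrt(b x (1 + a + b x))) / (4 b) )`
#'
#' The transform is strictly increasing per gene, approximately `2 sqrt(x)`
#' shaped for Poisson-like data, and log2-like at large counts
#' (`vst(2x) - vst(x) -> 1`). If the trend fit yields `a <= 0` the transform
#' falls back to constant dispersion (b-only) with a warning.
#'
#' @param counts an [expression_matrix()] of raw counts with >= 10 genes and
#'   >= 4 samples.
#' @return an [expression_matrix()] with units `vst`; attributes
#'   `size_factors` and `trend` (fitted `a`, `b`) record the fit.
#' @export
vst_transform <- function(counts) {
  assert_units(counts, "raw_counts")
  x <- em_values(counts)
  if (nrow(x) < 10L) stop("need >= 10 genes to fit the dispersion trend")
  if (ncol(x) < 4L) stop("need >= 4 samples to fit the dispersion trend")
  sf <- median_ratio_size_factors(counts)
  nx <- sweep(x, 2, sf, "/")
  mu <- rowMeans(nx)
  v <- row_vars(nx)
  xim <- mean(1 / sf)
  disp <- (v - xim * mu) / mu^2
  trend <- fit_dispersion_trend(mu, disp)
  a <- trend["a"]; b <- trend["b"]
  tx <- log2((1 + a + 2 * b * nx + 2 * sqrt(b * nx * (1 + a + b * nx))) / (4 * b))
  out <- expression_matrix(tx, units = "vst", description = counts$description)
  attr(out, "size_factors") <- sf
  attr(out, "trend") <- c(a = unname(a), b = unname(b))
  out
}

#' Quantile normalization across one or more matrices
#'
#' Forces every sample column onto the common reference distribution: the
#' per-rank mean of the sorted input columns. Tied values within a column
#' receive the mean of the reference quantiles they span. When several
#' matrices are supplied (e.g. the normal/normal/cancer dataset trio) they
#' are combined, normalized together, and re-separated, so every column of
#' every output matrix carries the identical multiset of values.
#'
#' @param ... one or more [expression_matrix()] objects over an identical
#'   gene set and ordering, or a single list of them.
#' @return a single `expression_matrix` (units `quantile`) if one input was
#'   given, else a list of them parallel to the inputs.
#' @export
quantile_normalize <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) &&
      !inherits(mats[[1]], "expression_matrix"))
    mats <- mats[[1]]
  stopifnot(length(mats) >= 1L)
  for (m in mats) assert_units(m, c("raw_counts", "vst", "log_cpm", "tpm",
                                    "quantile"), "input")
  genes <- gene_ids(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(gene_ids(m), genes)) {
      d <- union(setdiff(gene_ids(m), genes), setdiff(genes, gene_ids(m)))
      stop("gene sets differ across inputs",
           if (length(d)) paste0("; symmetric difference: ",
                                 paste(utils::head(d, 20), collapse = ", "))
           else " (same set, different order)")
    }
  }
  big <- do.call(cbind, lapply(mats, em_values))
  if (anyDuplicated(colnames(big)))
    stop("sample ids must be unique across inputs")
  ref <- rowMeans(apply(big, 2, sort))
  qn <- apply(big, 2, function(col) {
    o <- order(col)
    out <- numeric(length(col))
    grp <- cumsum(c(1, diff(col[o]) != 0))
    out[o] <- stats::ave(ref, grp)
    out
  })
  rownames(qn) <- genes
  split_at <- cumsum(vapply(mats, ncol, 0L))
  start <- c(1L, utils::head(split_at, -1) + 1L)
  res <- lapply(seq_along(mats), function(i)
    expression_matrix(qn[, start[i]:split_at[i], drop = FALSE],
                      units = "quantile"))
  if (length(res) == 1L) res[[1]] else res
}

#' Matrisome category share of the transcriptome
#'
#' For each tissue column of a TPM profile, sums the TPM of the genes in each
#' analyzed matrisome category (collagens, proteoglycans, ECM glycoproteins,
#' ECM regulators) and divides by the tissue's total TPM, giving the percent
#' of the transcriptome attributable to each category.
#'
#' @param tpm an [expression_matrix()] with units `tpm`; columns are tissues
#'   (typically a per-tissue median profile).
#' @param catalog a `matrisome_catalog`.
#' @return data.frame with columns `tissue`, `category`, `percent`.
#' @export
category_fraction <- function(tpm, catalog) {
  assert_units(tpm, "tpm")
  stopifnot(inherits(catalog, "matrisome_catalog"))
  x <- em_values(tpm)
  totals <- colSums(x)
  if (any(totals == 0))
    stop("tissue(s) with zero total TPM: ",
         paste(colnames(x)[totals == 0], collapse = ", "))
  cats <- c(CORE_CATEGORIES, "ECM_regulators")
  out <- do.call(rbind, lapply(cats, function(ct) {
    genes <- intersect(catalog$gene_id[catalog$category == ct], rownames(x))
    num <- if (length(genes)) colSums(x[genes, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(x)), colnames(x))
    data.frame(tissue = colnames(x), category = ct,
               percent = 100 * num / totals, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Median expression profile per tissue
#'
#' Per-tissue, per-gene median of normalized expression, optionally
#' collapsing all brain sub-tissues into one `BRAIN` super-tissue whose value
#' is the per-gene median of the sub-tissue medians.
#'
#' @param expr an [expression_matrix()] (any normalized units; typically
#'   `vst`).
#' @param samples sample table with `sample_id` and `tissue`; every column of
#'   `expr` must resolve to a tissue.
#' @param collapse_brain add the `BRAIN` super-tissue when any tissue matches
#'   `brain_pattern`.
#' @param brain_pattern regular expression identifying brain sub-tissues
#'   (GTEx brain codes start with `BRN`).
#' @return an `expression_matrix` in the input units, genes x tissues, with a
#'   `provenance` attribute listing the samples behind each tissue column.
#' @export
median_tissue_profile <- function(expr, samples, collapse_brain = TRUE,
                                  brain_pattern = "^BRN") {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- em_values(expr)
  tis <- samples$tissue[match(colnames(x), samples$sample_id)]
  if (anyNA(tis))
    stop("samples without tissue assignment: ",
         paste(colnames(x)[is.na(tis)], collapse = ", "))
  tissues <- unique(tis)
  prof <- vapply(tissues, function(tt)
    apply(x[, tis == tt, drop = FALSE], 1, stats::median),
    numeric(nrow(x)))
  if (!is.matrix(prof)) prof <- matrix(prof, nrow = nrow(x),
                                       dimnames = list(rownames(x), tissues))
  colnames(prof) <- tissues
  provenance <- split(colnames(x), tis)[tissues]
  if (collapse_brain && any(grepl(brain_pattern, tissues))) {
    sub <- grepl(brain_pattern, colnames(prof))
    brain <- apply(prof[, sub, drop = FALSE], 1, stats::median)
    prof <- cbind(prof, BRAIN = brain)
    provenance$BRAIN <- unlist(provenance[grepl(brain_pattern, names(provenance))],
                               use.names = FALSE)
  }
  out <- expression_matrix(prof, units = em_units(expr))
  attr(out, "provenance") <- provenance
  out
}
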