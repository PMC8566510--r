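#' High-variance gene filter
#'
#' Selects genes for co-expression clustering: mean normalized expression
#' above `mean_min` and across-sample variance (n-1 denominator) above
#' `var_min`. The adipose analysis uses (5, 1.5); the lung fibrosis analysis
#' raises the variance floor to 2.
#'
#' @param expr an [expression_matrix()] with units `vst`.
#' @param mean_min mean threshold (strict `>`).
#' @param var_min variance threshold (strict `>`).
#' @return character vector of retained gene ids.
#' @export
high_variance_filter <- function(expr, mean_min = 5, var_min = 1.5) {
  assert_units(expr, "vst")
  x <- em_values(expr)
  keep <- rowMeans(x) > mean_min & row_vars(x) > var_min
  if (!any(keep))
    stop("no gene passes the high-variance filter; ",
         "consider lowering mean_min/var_min")
  rownames(x)[keep]
}

#' Critical Kendall tau for declaring co-expression
#'
#' The significance threshold used to cut the co-expression dendrogram: the
#' normal-approximation critical value of Kendall's tau at `n_samples`
#' observations,
#' `tau_crit = z * sqrt(2 (2n + 5) / (9 n (n - 1)))`,
#' with `z` the two-sided normal quantile at a Bonferroni-corrected level
#' `alpha / choose(n_genes, 2)` so the bound holds family-wise over all gene
#' pairs under consideration.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_genes number of genes entering the clustering (>= 2).
#' @param alpha family-wise level before correction (default 0.05).
#' @return the critical tau.
#' @export
tau_critical <- function(n_samples, n_genes, alpha = 0.05) {
  if (n_samples < 4L) stop("need n_samples >= 4")
  if (n_genes < 2L) stop("need n_genes >= 2")
  alpha_pair <- alpha / choose(n_genes, 2)
  z <- stats::qnorm(1 - alpha_pair / 2)
  n <- n_samples
  z * sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
}

# internal: mean of the off-diagonal entries of a square matrix
mean_offdiag <- function(m) {
  if (nrow(m) < 2L) return(NA_real_)
  mean(m[upper.tri(m)])
}

# internal: recursively split a gene set along its (average-linkage,
# 1 - tau) dendrogram while it contains negatively correlated gene pairs.
# Returns a list of gene-id vectors (possibly singletons).
split_negative <- function(genes, tau) {
  if (length(genes) < 2L) return(list(genes))
  sub <- tau[genes, genes, drop = FALSE]
  if (min(sub[upper.tri(sub)]) >= 0) return(list(genes))
  hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
  parts <- stats::cutree(hc, k = 2)
  c(split_negative(genes[parts == 1], tau),
    split_negative(genes[parts == 2], tau))
}

# internal: does a cluster pass the tau bound after anti-correlation
# refinement? Returns NULL on failure, else the list of size>=2 sub-clusters.
refine_cluster <- function(genes, tau, tau_crit) {
  pieces <- split_negative(genes, tau)
  pieces <- pieces[lengths(pieces) >= 2L]
  if (!length(pieces)) return(NULL)
  ok <- vapply(pieces, function(g)
    mean_offdiag(tau[g, g, drop = FALSE]) >= tau_crit, logical(1))
  if (all(ok)) pieces else NULL
}

#' Cut a co-expression dendrogram at the tau-critical bound
#'
#' Genes are clustered by average linkage on `1 - tau` distances (Kendall's
#' tau-b across samples). Partitions are scanned from coarsest (one cluster)
#' to finest; the first partition in which every cluster of size >= 2 passes
#' the bound is accepted, i.e. the largest cut height whose clusters all have
#' mean pairwise tau at or above `tau_crit`. A candidate cluster containing
#' negatively correlated gene pairs is first re-cut into maximal sub-clusters
#' of non-negative internal correlation and the bound is applied to each
#' sub-cluster; such clusters are reported as paired anti-correlated
#' sub-clusters (labels `c1.1`, `c1.2`, ...), the pattern fibrosis programs
#' show. Singletons are never reported. If no partition passes, an empty
#' cluster set is returned with a warning.
#'
#' @param expr an [expression_matrix()] (units `vst`) already restricted to
#'   the filtered high-variance genes; >= 3 genes.
#' @param alpha family-wise level fed to [tau_critical()] (default 0.05).
#' @param tau_crit override the computed critical tau (optional).
#' @param label_prefix prefix for cluster labels (default `"c"`).
#' @return a `gene_cluster_set`: list with `clusters` (named list of gene-id
#'   vectors, ordered by decreasing size), `parent` (integer id of the
#'   pre-split cluster each entry came from), `tau_critical`, `tau` (the
#'   correlation matrix), `hclust`, and `params`.
#' @export
cut_clusters <- function(expr, alpha = 0.05, tau_crit = NULL,
                         label_prefix = "c") {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- em_values(expr)
  g <- nrow(x)
  if (g < 3L) stop("need >= 3 genes")
  x <- x[order(rownames(x)), , drop = FALSE]   # input-order invariance
  tau <- stats::cor(t(x), method = "kendall")
  if (is.null(tau_crit)) tau_crit <- tau_critical(ncol(x), g, alpha)
  hc <- stats::hclust(stats::as.dist(1 - tau), method = "average")
  chosen <- NULL
  for (k in seq_len(g - 1L)) {
    parts <- stats::cutree(hc, k = k)
    ids <- split(names(parts), parts)
    big <- ids[lengths(ids) >= 2L]
    if (!length(big)) next
    refined <- lapply(big, refine_cluster, tau = tau, tau_crit = tau_crit)
    if (!any(vapply(refined, is.null, logical(1)))) {
      chosen <- refined
      break
    }
  }
  clusters <- list()
  parent <- integer()
  if (is.null(chosen)) {
    warning("no partition satisfies the tau-critical bound; ",
            "returning an empty cluster set")
  } else {
    ord <- order(-vapply(chosen, function(p) sum(lengths(p)), 0))
    for (i in seq_along(ord)) {
      pieces <- chosen[[ord[i]]]
      pieces <- pieces[order(-lengths(pieces))]
      lab <- if (length(pieces) == 1L) paste0(label_prefix, i)
      else paste0(label_prefix, i, ".", seq_along(pieces))
      for (j in seq_along(pieces)) {
        clusters[[lab[j]]] <- sort(pieces[[j]])
        parent <- c(parent, i)
      }
    }
  }
  structure(list(clusters = clusters, parent = parent,
                 tau_critical = tau_crit, tau = tau, hclust = hc,
                 params = list(alpha = alpha, n_samples = ncol(x),
                               n_genes = g)),
            class = "gene_cluster_set")
}

#' @exportS3Method base::print
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("gene_cluster_set: %d cluster(s), tau_critical = %.3f\n",
              length(x$clusters), x$tau_critical))
  for (nm in names(x$clusters))
    cat(sprintf("  %s: n = %d\n", nm, length(x$clusters[[nm]])))
  invisible(x)
}

#' MAD-normalized cluster score
#'
#' The per-sample summary of a gene cluster's expression:
#' `S_i = (1/J) * sum_j (x_ij - xbar_j) / median_{m: t(m) = t(i)} |x_mj - xmed_j|`
#' where `x` is VST-normalized expression, `xbar_j` and `xmed_j` are the mean
#' and median of gene `j` over the samples of sample i's tissue, and the
#' denominator is the raw median absolute deviation about the median (no
#' consistency constant). Genes whose MAD is zero within a tissue are
#' excluded there with a warning and `J` decremented accordingly. Within each
#' tissue the scores average to zero by construction.
#'
#' @param expr an [expression_matrix()] with units `vst`.
#' @param samples sample table with `sample_id` and `tissue` covering the
#'   columns of `expr`.
#' @param genes gene ids of the cluster.
#' @param label cluster label carried along (optional).
#' @return a `cluster_score` data.frame with columns `sample_id`, `tissue`,
#'   `score`; attributes `J` (genes used per tissue), `centers` and `mads`
#'   (per tissue x gene), `label`.
#' @export
cluster_score <- function(expr, samples, genes, label = NULL) {
  assert_units(expr, "vst")
  x <- em_values(expr)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes))
    stop("cluster genes absent from expression: ",
         paste(missing_genes, collapse = ", "))
  x <- x[genes, , drop = FALSE]
  tis <- samples$tissue[match(colnames(x), samples$sample_id)]
  if (anyNA(tis)) stop("every sample must resolve to a tissue")
  score <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  tissues <- unique(tis)
  J <- stats::setNames(integer(length(tissues)), tissues)
  centers <- mads <- matrix(NA_real_, length(tissues), length(genes),
                            dimnames = list(tissues, genes))
  for (tt in tissues) {
    cols <- tis == tt
    xt <- x[, cols, drop = FALSE]
    xbar <- rowMeans(xt)
    xmed <- apply(xt, 1, stats::median)
    mad_raw <- apply(abs(xt - xmed), 1, stats::median)
    usable <- mad_raw > 0
    if (!any(usable))
      stop("all cluster genes have zero MAD in tissue ", tt)
    if (any(!usable))
      warning("tissue ", tt, ": zero-MAD gene(s) excluded from the score: ",
              paste(genes[!usable], collapse = ", "))
    contrib <- (xt[usable, , drop = FALSE] - xbar[usable]) / mad_raw[usable]
    score[cols] <- colMeans(contrib)
    J[tt] <- sum(usable)
    centers[tt, ] <- xbar
    mads[tt, ] <- mad_raw
  }
  out <- data.frame(sample_id = colnames(x), tissue = tis, score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "J") <- J
  attr(out, "centers") <- centers
  attr(out, "mads") <- mads
  attr(out, "label") <- label
  class(out) <- c("cluster_score", "data.frame")
  out
}

#' Association models for cluster scores and histology readouts
#'
#' Fits either a fixed-effects linear model or a random-intercept
#' (per-subject) mixed model of a response on the given covariates. Repeated
#' measurements can be averaged per subject before a fixed-effects fit (the
#' design used when relating a score to per-sample percent-area measurements
#' without a random effect). Mixed models are fitted by REML via lme4;
#' p-values for fixed effects are Wald normal approximations.
#'
#' @param data data.frame holding response and covariates (one row per
#'   measurement).
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @param random_intercept optional grouping column name (e.g. subject id)
#'   for a random intercept; `NULL` fits ordinary least squares.
#' @param average_by optional column name: average the response (and numeric
#'   covariates) within levels of this column before a fixed-effects fit.
#' @return an `association_fit` list: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `p`), `varcomp` (random-intercept and residual
#'   variance for mixed fits), `model` (the underlying fit), `n`.
#' @export
association_models <- function(data, response, covariates,
                               random_intercept = NULL, average_by = NULL) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  if (!is.null(average_by) && !is.null(random_intercept))
    stop("choose either averaging or a random intercept, not both")
  df <- data
  if (!is.null(average_by)) {
    stopifnot(average_by %in% names(df))
    agg <- lapply(split(df, df[[average_by]]), function(d) {
      row <- d[1, , drop = FALSE]
      for (nm in c(response, covariates))
        if (is.numeric(d[[nm]])) row[[nm]] <- mean(d[[nm]])
      row
    })
    df <- do.call(rbind, agg)
  }
  keep <- stats::complete.cases(df[, c(response, covariates,
                                       random_intercept), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  rhs <- paste(covariates, collapse = " + ")
  if (is.null(random_intercept)) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(fml, data = df)
    if (any(is.na(stats::coef(fit))))
      stop("singular fit; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    cs <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                        p = cs[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
    varcomp <- c(residual = summary(fit)$sigma^2)
  } else {
    stopifnot(random_intercept %in% names(data))
    fml <- stats::as.formula(paste(response, "~", rhs,
                                   "+ (1 |", random_intercept, ")"))
    fit <- lme4::lmer(fml, data = df)
    cs <- as.data.frame(summary(fit)$coefficients)
    z <- cs[, "t value"]
    coefs <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                        se = cs[, "Std. Error"],
                        p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                        row.names = NULL, stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, ifelse(is.na(vc$grp) |
                                                 vc$grp == "Residual",
                                               "residual", vc$grp))
  }
  structure(list(coefficients = coefs, varcomp = varcomp, model = fit,
                 n = nrow(df)),
            class = "association_fit")
}

#' Multi-tissue single-gene score and extreme-subject selection
#'
#' Averages one gene's normalized expression over a required set of tissues
#' per subject (subjects missing any required tissue are excluded and
#' recorded). [select_extremes()] then picks the top/bottom subjects —
#' overall or per sex — de-identified and presented in a seeded random order
#' so downstream manual scoring is blinded.
#'
#' @param expr an [expression_matrix()] with units `vst`.
#' @param samples sample table with `sample_id`, `subject_id`, `tissue` and
#'   (for per-sex selection) `sex`.
#' @param gene_id the gene to score.
#' @param tissues tissues that must all be present for a subject.
#' @return named numeric vector of scores (names are subject ids), with the
#'   excluded subjects in the `excluded` attribute.
#' @export
multi_tissue_gene_score <- function(expr, samples, gene_id, tissues) {
  assert_units(expr, "vst")
  x <- em_values(expr)
  if (!gene_id %in% rownames(x)) stop("gene not in expression: ", gene_id)
  st <- samples[match(colnames(x), samples$sample_id), , drop = FALSE]
  st$value <- x[gene_id, ]
  st <- st[st$tissue %in% tissues, , drop = FALSE]
  per_subj <- split(st, st$subject_id)
  have_all <- vapply(per_subj, function(d)
    all(tissues %in% d$tissue), logical(1))
  excluded <- names(per_subj)[!have_all]
  scores <- vapply(per_subj[have_all], function(d) {
    per_tissue <- vapply(split(d$value, d$tissue)[tissues], mean, numeric(1))
    mean(per_tissue)
  }, numeric(1))
  attr(scores, "excluded") <- excluded
  scores
}

#' @rdname multi_tissue_gene_score
#' @param scores named score vector from [multi_tissue_gene_score()].
#' @param top,bottom how many subjects to take from each extreme.
#' @param by_sex optional named vector mapping subject id to sex; when given,
#'   `top`/`bottom` are taken within each sex.
#' @param seed seed for the blinding shuffle.
#' @return data.frame with `masked_id`, `group` (`high`/`low`), `score`,
#'   `subject_id`; rows in seeded random order.
#' @export
select_extremes <- function(scores, top, bottom, by_sex = NULL, seed = 1L) {
  pick <- function(s, n_top, n_bot) {
    if (n_top + n_bot > length(s))
      stop("top + bottom exceeds the available cohort (", length(s), ")")
    s <- sort(s, decreasing = TRUE)
    rbind(data.frame(subject_id = names(utils::head(s, n_top)),
                     score = unname(utils::head(s, n_top)), group = "high",
                     stringsAsFactors = FALSE),
          data.frame(subject_id = names(utils::tail(s, n_bot)),
                     score = unname(utils::tail(s, n_bot)), group = "low",
                     stringsAsFactors = FALSE))
  }
  sel <- if (is.null(by_sex)) pick(scores, top, bottom)
  else do.call(rbind, lapply(split(names(scores), by_sex[names(scores)]),
                             function(ids) pick(scores[ids], top, bottom)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sel <- sel[sample.int(nrow(sel)), , drop = FALSE]
  sel$masked_id <- sprintf("S%02d", seq_len(nrow(sel)))
  rownames(sel) <- NULL
  sel[, c("masked_id", "group", "score", "subject_id")]
}

#' Cluster samples on a gene cluster's expression
#'
#' Centers each gene on its across-sample mean, clusters the samples by
#' complete linkage on Euclidean distances, cuts the tree into `k` groups,
#' and cross-tabulates groups against disease labels (the disease-vs-cluster
#' table of the lung fibrosis analysis).
#'
#' @param expr an [expression_matrix()] restricted to the cluster genes.
#' @param k number of sample groups.
#' @param samples optional sample table with `sample_id` and `disease` for
#'   the cross-tabulation.
#' @param linkage linkage method (default `complete`).
#' @return list with `groups` (named integer vector), `hclust`, `centered`
#'   (the centered matrix), and `crosstab` (group x disease, or `NULL`).
#' @export
sample_cluster <- function(expr, k, samples = NULL, linkage = "complete") {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- em_values(expr)
  if (k > ncol(x)) stop("k exceeds the number of samples")
  centered <- x - rowMeans(x)
  hc <- stats::hclust(stats::dist(t(centered)), method = linkage)
  groups <- stats::cutree(hc, k = k)
  crosstab <- NULL
  if (!is.null(samples)) {
    dis <- samples$disease[match(names(groups), samples$sample_id)]
    crosstab <- table(cluster = groups, disease = dis)
  }
  list(groups = groups, hclust = hc, centered = centered, crosstab = crosstab)
}
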