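#' Dataset trio for normal-vs-cancer comparison
#'
#' Bundles, for one tissue, the normal reference expression (a GTEx-style
#' cohort), an optional matched normal from the cancer study, and the cancer
#' samples, all as raw-count matrices over a shared gene universe.
#'
#' @param tissue tissue label.
#' @param gtex_normal,tcga_cancer [expression_matrix()] raw counts.
#' @param tcga_normal optional [expression_matrix()] raw counts; `NULL` is
#'   legal (some tissues have no study-matched normals).
#' @return a `dataset_trio` list.
#' @export
dataset_trio <- function(tissue, gtex_normal, tcga_cancer, tcga_normal = NULL) {
  assert_units(gtex_normal, "raw_counts")
  assert_units(tcga_cancer, "raw_counts")
  if (!is.null(tcga_normal)) assert_units(tcga_normal, "raw_counts")
  shared <- intersect(gene_ids(gtex_normal), gene_ids(tcga_cancer))
  if (!is.null(tcga_normal)) shared <- intersect(shared, gene_ids(tcga_normal))
  if (length(shared) < 2L)
    stop("gene universes of the trio datasets barely intersect")
  structure(list(tissue = tissue, gtex_normal = gtex_normal,
                 tcga_normal = tcga_normal, tcga_cancer = tcga_cancer),
            class = "dataset_trio")
}

# internal: datasets present in a trio, in canonical order
trio_datasets <- function(trio) {
  ds <- list(gtex_normal = trio$gtex_normal, tcga_normal = trio$tcga_normal,
             tcga_cancer = trio$tcga_cancer)
  ds[!vapply(ds, is.null, logical(1))]
}

#' Two-stage expression whitelist for a dataset trio
#'
#' Stage 1, per dataset: keep genes with an across-sample raw-count sum
#' strictly greater than `raw_sum_min`, then variance-stabilize the dataset.
#' Stage 2: a gene enters the whitelist if its mean normalized value exceeds
#' `norm_mean_min` in at least one dataset of the trio — which deliberately
#' admits genes silent in normal tissue but expressed in cancer. Optionally
#' the whitelist is intersected with the matrisome analysis gene set.
#'
#' @param trio a [dataset_trio()].
#' @param catalog optional `matrisome_catalog`; when given the whitelist is
#'   restricted to [core_plus_regulators()].
#' @param raw_sum_min stage-1 threshold (default 5, strict `>`).
#' @param norm_mean_min stage-2 threshold on mean normalized counts (default
#'   5, strict `>`).
#' @return character vector of whitelisted gene ids (shared-universe order).
#' @export
build_whitelist <- function(trio, catalog = NULL, raw_sum_min = 5,
                            norm_mean_min = 5) {
  stopifnot(inherits(trio, "dataset_trio"))
  ds <- trio_datasets(trio)
  shared <- Reduce(intersect, lapply(ds, gene_ids))
  passed <- character()
  for (d in ds) {
    x <- d[shared, ]
    stage1 <- gene_ids(x)[rowSums(em_values(x)) > raw_sum_min]
    if (length(stage1) < 10L) next
    v <- vst_transform(x[stage1, ])
    mu <- rowMeans(em_values(v))
    passed <- union(passed, stage1[mu > norm_mean_min])
  }
  wl <- shared[shared %in% passed]
  if (!is.null(catalog)) wl <- intersect(wl, core_plus_regulators(catalog))
  if (!length(wl)) stop("empty whitelist")
  wl
}

#' Quantile-normalized mean profiles, ranks, and the joined normal
#'
#' Variance-stabilizes each dataset of the trio over the whitelist, quantile
#' normalizes all datasets together (so a shared reference distribution
#' absorbs per-dataset batch scale), re-separates them, and computes each
#' dataset's per-gene mean. The joined normal (`joined_n`) is the unweighted
#' mean of the GTEx-normal and study-normal means — or the GTEx-normal mean
#' alone when no study normal exists. Ranks are ascending in expression
#' (rank 1 = lowest), average ranks on ties.
#'
#' @param trio a [dataset_trio()].
#' @param whitelist gene ids from [build_whitelist()].
#' @return list with `means` (gene x dataset matrix incl. `joined_n`) and
#'   `ranks` (same shape).
#' @export
mean_rank_profiles <- function(trio, whitelist) {
  stopifnot(inherits(trio, "dataset_trio"))
  ds <- trio_datasets(trio)
  vsts <- lapply(ds, function(d) vst_transform(d[whitelist, ]))
  qn <- quantile_normalize(vsts)
  if (inherits(qn, "expression_matrix")) qn <- list(qn)
  means <- vapply(qn, function(m) rowMeans(em_values(m)),
                  numeric(length(whitelist)))
  colnames(means) <- names(ds)
  joined <- if ("tcga_normal" %in% colnames(means))
    (means[, "gtex_normal"] + means[, "tcga_normal"]) / 2
  else means[, "gtex_normal"]
  means <- cbind(means, joined_n = joined)
  ranks <- apply(means, 2, rank)          # ties.method = "average"
  rownames(means) <- rownames(ranks) <- whitelist
  list(means = means, ranks = ranks)
}

# internal: equal-count decile bins on values, ties at bin boundaries broken
# by lexicographic gene id; bin sizes differ by at most one.
decile_bins <- function(values, gene_id, n_bins = 10L) {
  ord <- order(values, gene_id)
  n <- length(values)
  bins <- integer(n)
  bins[ord] <- ceiling(seq_len(n) * n_bins / n)
  bins
}

#' Normal-to-cancer rank changes across tissues
#'
#' For each tissue trio: builds the whitelist, computes quantile-normalized
#' mean ranks, and takes `delta = rank(cancer) - rank(joined normal)` per
#' gene, so a positive delta means relatively higher expression in cancer.
#' Deltas are summed per gene across the tissues where the gene is
#' whitelisted; both the per-tissue deltas and the summed values are
#' segmented into equal-count deciles (decile 10 = largest increase). The top
#' and bottom `n_top` genes by summed delta are reported together with a
#' per-tissue decile membership matrix (`NA` where a gene is not whitelisted)
#' and consistency counts of how many of those extreme genes sit in the
#' extreme decile per tissue.
#'
#' @param trios list of [dataset_trio()] objects (>= 1).
#' @param catalog optional `matrisome_catalog` restriction, passed to
#'   [build_whitelist()].
#' @param n_deciles number of rank-change bins (default 10).
#' @param n_top size of the extreme gene lists (default 10).
#' @return a `rank_change_result` list: `per_tissue` (data.frame with
#'   `tissue`, `gene_id`, `rank_normal`, `rank_cancer`, `delta`, `decile`),
#'   `summed` (data.frame `gene_id`, `summed_delta`, `n_tissues`, `decile`),
#'   `top`, `bottom` (gene ids), `decile_matrix` (gene x tissue, `NA` =
#'   not whitelisted), `consistency` (counts of extreme-decile membership).
#' @export
rank_change_summary <- function(trios, catalog = NULL, n_deciles = 10L,
                                n_top = 10L) {
  if (inherits(trios, "dataset_trio")) trios <- list(trios)
  stopifnot(length(trios) >= 1L)
  per_tissue <- list()
  for (trio in trios) {
    wl <- build_whitelist(trio, catalog = catalog)
    mr <- mean_rank_profiles(trio, wl)
    delta <- mr$ranks[, "tcga_cancer"] - mr$ranks[, "joined_n"]
    per_tissue[[trio$tissue]] <- data.frame(
      tissue = trio$tissue, gene_id = wl,
      rank_normal = mr$ranks[, "joined_n"],
      rank_cancer = mr$ranks[, "tcga_cancer"],
      delta = delta,
      decile = decile_bins(delta, wl, n_deciles),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  pt <- do.call(rbind, per_tissue)
  rownames(pt) <- NULL
  summed_delta <- tapply(pt$delta, pt$gene_id, sum)
  n_tis <- tapply(pt$delta, pt$gene_id, length)
  genes <- names(summed_delta)
  summed <- data.frame(gene_id = genes,
                       summed_delta = as.numeric(summed_delta),
                       n_tissues = as.integer(n_tis),
                       decile = decile_bins(as.numeric(summed_delta), genes,
                                            n_deciles),
                       row.names = NULL, stringsAsFactors = FALSE)
  summed <- summed[order(-summed$summed_delta, summed$gene_id), ]
  rownames(summed) <- NULL
  top <- utils::head(summed$gene_id, n_top)
  bottom <- rev(utils::tail(summed$gene_id, n_top))
  tissues <- vapply(trios, `[[`, "", "tissue")
  dm <- matrix(NA_integer_, length(genes), length(tissues),
               dimnames = list(sort(genes), tissues))
  for (tt in tissues) {
    d <- per_tissue[[tt]]
    dm[d$gene_id, tt] <- d$decile
  }
  consistency <- c(
    top_in_top_decile = sum(dm[top, , drop = FALSE] == n_deciles,
                            na.rm = TRUE),
    bottom_in_bottom_decile = sum(dm[bottom, , drop = FALSE] == 1L,
                                  na.rm = TRUE),
    cells_top = sum(!is.na(dm[top, , drop = FALSE])),
    cells_bottom = sum(!is.na(dm[bottom, , drop = FALSE])))
  structure(list(per_tissue = pt, summed = summed, top = top,
                 bottom = bottom, decile_matrix = dm,
                 consistency = consistency),
            class = "rank_change_result")
}

#' Two-group Wilcoxon rank-sum tests across genes
#'
#' Compares each gene's values between two groups with a two-sided Wilcoxon
#' rank-sum test — exact when both groups are small and tie-free, normal
#' approximation with tie correction otherwise — and applies Holm correction
#' across the supplied gene list. Direction is the sign of the
#' second-minus-first group median difference.
#'
#' @param expr an [expression_matrix()] of normalized values, or a plain
#'   genes x samples matrix.
#' @param groups two-level factor over the samples.
#' @param genes genes to test (default: all rows).
#' @return data.frame with `gene_id`, `p`, `p_holm`, `direction` (sign of
#'   median(level 2) - median(level 1)).
#' @export
group_wilcoxon <- function(expr, groups, genes = NULL) {
  x <- if (inherits(expr, "expression_matrix")) em_values(expr)
  else as.matrix(expr)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(x)) stop("'groups' must match the samples")
  if (any(table(groups) < 3L)) stop("both groups need >= 3 observations")
  if (is.null(genes)) genes <- rownames(x)
  g1 <- groups == levels(groups)[1]
  res <- t(vapply(genes, function(g) {
    a <- x[g, g1]; b <- x[g, !g1]
    exact <- length(a) + length(b) <= 20 &&
      !anyDuplicated(c(a, b))
    p <- stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value
    c(p = p, direction = sign(stats::median(b) - stats::median(a)))
  }, c(p = 0, direction = 0)))
  out <- data.frame(gene_id = genes, p = res[, "p"],
                    p_holm = stats::p.adjust(res[, "p"], method = "holm"),
                    direction = res[, "direction"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
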