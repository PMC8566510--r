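#' Join protein and transcript abundance tables
#'
#' Inner-joins matched protein and transcript abundance tables on
#' (tissue, gene), drops pairs with a zero or missing value in either column
#' (only pairs detected at both levels are comparable), and annotates each
#' pair with its matrisome category; genes absent from the catalog are
#' labeled `non_matrisome`.
#'
#' @param protein data.frame with columns `tissue`, `gene_id`, `value`
#'   (protein abundance, e.g. iBAQ).
#' @param transcript data.frame with columns `tissue`, `gene_id`, `value`
#'   (transcript abundance, e.g. FPKM/TPM).
#' @param catalog a `matrisome_catalog`.
#' @return a `paired_abundance` data.frame with columns `tissue`, `gene_id`,
#'   `protein`, `transcript`, `category`; one row per (tissue, gene), both
#'   abundances strictly positive.
#' @export
build_pair_table <- function(protein, transcript, catalog) {
  for (nm in c("tissue", "gene_id", "value")) {
    if (!nm %in% names(protein)) stop("protein table lacks column ", nm)
    if (!nm %in% names(transcript)) stop("transcript table lacks column ", nm)
  }
  if (!length(intersect(protein$gene_id, transcript$gene_id)))
    stop("no overlapping genes between protein and transcript tables")
  joined <- merge(
    data.frame(tissue = protein$tissue, gene_id = protein$gene_id,
               protein = protein$value, stringsAsFactors = FALSE),
    data.frame(tissue = transcript$tissue, gene_id = transcript$gene_id,
               transcript = transcript$value, stringsAsFactors = FALSE),
    by = c("tissue", "gene_id"))
  keep <- !is.na(joined$protein) & !is.na(joined$transcript) &
    joined$protein > 0 & joined$transcript > 0
  joined <- joined[keep, , drop = FALSE]
  if (anyDuplicated(joined[, c("tissue", "gene_id")]))
    stop("more than one row per (tissue, gene) after the join")
  joined$category <- catalog_category(catalog, joined$gene_id)
  rownames(joined) <- NULL
  class(joined) <- c("paired_abundance", "data.frame")
  joined
}

#' Rank correlation (Spearman's rho / Kendall's tau-b)
#'
#' Spearman via Pearson correlation of average ranks; Kendall as tau-b
#' (tie-corrected). A constant input vector makes the coefficient undefined:
#' `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"kendall"`.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need length >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  if (method == "spearman")
    stats::cor(rank(x), rank(y))
  else
    stats::cor(x, y, method = "kendall")
}

# internal: deterministic substream seed from a base seed and strings,
# keeping the result inside the 32-bit integer range set.seed accepts
substream_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (str in as.character(c(...)))
    for (code in utf8ToInt(str))
      s <- (s * 31 + code) %% 2147483647
  as.integer(s)
}

#' Classify a category's protein-transcript correlation against a
#' permutation null
#'
#' Computes the observed Spearman correlation between protein and transcript
#' abundance over a (tissue, category)'s pairs, then builds a null
#' distribution by drawing `n_perm` random subsets (without replacement,
#' independent across draws) of equal size N from the tissue's non-matrisome
#' pairs and correlating each. The verdict is `superior` if the observed rho
#' exceeds the upper `1 - alpha/2` empirical quantile of the null, `inferior`
#' below the `alpha/2` quantile, else `equivalent`.
#'
#' The random stream is derived deterministically from `seed` and the
#' (tissue, category) labels, so per-category calls are reproducible and
#' independent of the order they are made in.
#'
#' @param pairs a `paired_abundance` table from [build_pair_table()].
#' @param tissue tissue to analyze.
#' @param category matrisome category to test (needs >= 3 pairs).
#' @param n_perm number of null draws (the study design uses 10,000).
#' @param alpha two-sided level for the verdict (default 0.05).
#' @param seed integer seed.
#' @return a `permutation_verdict` list: `tissue`, `category`, `n_pairs`,
#'   `observed_rho`, `null_rhos` (length `n_perm`), `percentile`, `verdict`.
#' @export
permutation_classify <- function(pairs, tissue, category, n_perm = 10000,
                                 alpha = 0.05, seed = 1L) {
  stopifnot(inherits(pairs, "paired_abundance"))
  sub <- pairs[pairs$tissue == tissue, , drop = FALSE]
  cat_rows <- sub[sub$category == category, , drop = FALSE]
  bg <- sub[sub$category == "non_matrisome", , drop = FALSE]
  n <- nrow(cat_rows)
  if (n < 3L) stop("category '", category, "' has fewer than 3 pairs in ", tissue)
  if (nrow(bg) < n)
    stop("fewer non-matrisome pairs (", nrow(bg), ") than category pairs (",
         n, ") in ", tissue)
  observed <- rank_correlation(cat_rows$protein, cat_rows$transcript,
                               "spearman")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, tissue, category))
  null_rhos <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(bg), n)
    stats::cor(rank(bg$protein[idx]), rank(bg$transcript[idx]))
  }, numeric(1))
  lo <- stats::quantile(null_rhos, alpha / 2, names = FALSE)
  hi <- stats::quantile(null_rhos, 1 - alpha / 2, names = FALSE)
  verdict <- if (observed > hi) "superior" else if (observed < lo) "inferior"
  else "equivalent"
  structure(list(tissue = tissue, category = category, n_pairs = n,
                 observed_rho = observed, null_rhos = null_rhos,
                 percentile = mean(null_rhos <= observed), alpha = alpha,
                 verdict = verdict),
            class = "permutation_verdict")
}

#' Rank-correlation matrix with dendrogram ordering
#'
#' Pairwise rank correlations between entities (columns), e.g. tissue median
#' profiles. Entities with a constant profile are excluded with a warning.
#' Entities are then clustered hierarchically on the Euclidean distances
#' between the rows of the `1 - correlation` matrix and the leaf order is
#' returned, reproducing the usual correlation-heatmap layout.
#'
#' @param profiles numeric matrix (features x entities) or an
#'   [expression_matrix()] whose columns are the entities.
#' @param method `"kendall"` (default, tau-b) or `"spearman"`.
#' @param linkage linkage for the display clustering (default `complete`).
#' @return list with `cor` (symmetric, unit-diagonal matrix), `hclust`, and
#'   `order` (leaf order labels).
#' @export
correlation_matrix <- function(profiles, method = c("kendall", "spearman"),
                               linkage = "complete") {
  method <- match.arg(method)
  x <- if (inherits(profiles, "expression_matrix")) em_values(profiles)
  else as.matrix(profiles)
  if (ncol(x) < 2L) stop("need >= 2 entities")
  keep <- apply(x, 2, function(col) stats::var(col) > 0)
  if (any(!keep)) {
    warning("excluding constant profile(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 non-constant entities remain")
  }
  cm <- if (method == "kendall") stats::cor(x, method = "kendall")
  else stats::cor(apply(x, 2, rank))
  diag(cm) <- 1
  hc <- stats::hclust(stats::dist(1 - cm), method = linkage)
  list(cor = cm, hclust = hc, order = colnames(cm)[hc$order])
}

#' Compare category correlations against the background
#'
#' For each matrisome category with enough observations, compares its
#' per-pair correlations against all other pairs with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test, then adjusts the p-values across
#' categories with Benjamini-Hochberg.
#'
#' @param correlations data.frame with columns `pair_id`, `correlation`,
#'   `category`.
#' @param min_n minimum group size per side (default 3); smaller categories
#'   are skipped with a warning.
#' @return data.frame with columns `category`, `n`, `statistic` (Mann-Whitney
#'   U for the category side), `p`, `fdr_p`, `direction` (sign of the
#'   category-minus-background median difference).
#' @export
category_background_test <- function(correlations, min_n = 3L) {
  stopifnot(all(c("pair_id", "correlation", "category") %in%
                  names(correlations)))
  cats <- setdiff(unique(correlations$category), "non_matrisome")
  rows <- list()
  for (ct in cats) {
    incat <- correlations$correlation[correlations$category == ct]
    rest <- correlations$correlation[correlations$category != ct]
    if (length(incat) < min_n || length(rest) < min_n) {
      warning("skipping category '", ct, "': fewer than ", min_n,
              " observations on one side")
      next
    }
    wt <- stats::wilcox.test(incat, rest, alternative = "two.sided",
                             exact = length(incat) + length(rest) <= 50)
    rows[[ct]] <- data.frame(
      category = ct, n = length(incat), statistic = unname(wt$statistic),
      p = wt$p.value,
      direction = sign(stats::median(incat) - stats::median(rest)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no category had enough observations to test")
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("category", "n", "statistic", "p", "fdr_p", "direction")]
}
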