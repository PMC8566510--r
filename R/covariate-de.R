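#' Expression filter for model fitting
#'
#' Keeps genes that are expressed at a usable level given the design: a gene
#' is retained when its counts-per-million reach the CPM equivalent of 10
#' counts at the median library size in at least `n_min` samples, where
#' `n_min` is the smallest group size, and its total count across samples is
#' at least 15.
#'
#' @param counts an [expression_matrix()] of raw counts.
#' @param group factor of group membership (e.g. sex) defining the smallest
#'   group size.
#' @param min_count count level that must be reachable (default 10).
#' @param min_total minimum total count (default 15).
#' @return character vector of retained gene ids.
#' @export
filter_by_expression <- function(counts, group, min_count = 10,
                                 min_total = 15) {
  assert_units(counts, "raw_counts")
  x <- em_values(counts)
  group <- droplevels(as.factor(group))
  if (length(group) != ncol(x))
    stop("'group' must have one entry per sample")
  lib <- colSums(x)
  cpm_cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- sweep(x, 2, lib, "/") * 1e6
  n_min <- min(table(group))
  keep <- rowSums(cpm >= cpm_cutoff) >= n_min & rowSums(x) >= min_total
  if (!any(keep)) stop("all genes removed by the expression filter")
  rownames(x)[keep]
}

# internal: voom-style log2-CPM with a 0.5-count offset
log_cpm <- function(x, lib = colSums(x)) {
  t(log2(t(x + 0.5) / (lib + 1) * 1e6))
}

# internal: mean-variance trend precision weights. Fits every gene
# unweighted, smooths sqrt(residual sd) against average log2 count with
# lowess, and returns per-observation weights 1 / predicted_sd^4 from each
# observation's fitted log2 count.
meanvar_weights <- function(y, X, lib) {
  n <- ncol(y); p <- ncol(X)
  qrX <- qr(X)
  beta <- qr.coef(qrX, t(y))
  res <- t(y) - X %*% beta
  sigma <- sqrt(colSums(res^2) / (n - p))
  amean <- rowMeans(y)
  sx <- amean + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy) & sy > 0
  lo <- stats::lowess(sx[ok], sy[ok], f = 0.5)
  lofun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_y <- t(X %*% beta)                       # genes x samples, log2-CPM
  fitted_logcount <- sweep(fitted_y, 2, log2(lib + 1) - log2(1e6), "+")
  w <- 1 / pmax(lofun(fitted_logcount), 1e-4)^4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  w
}

# internal: build the per-tissue design matrix; returns list(X, dropped)
build_design <- function(st, scale_age) {
  age <- st$age
  scaled_age <- if (scale_age) as.numeric(scale(age)) else age
  df <- data.frame(scaled_age = scaled_age, sex = st$sex)
  if (!is.null(st$ischemic_time)) df$ischemic_time <- st$ischemic_time
  if (!is.null(st$hardy_scale)) df$hardy_scale <- droplevels(st$hardy_scale)
  if (!is.null(st$batch)) df$batch <- droplevels(st$batch)
  dropped <- character()
  for (nm in names(df)) {
    v <- df[[nm]]
    n_lev <- if (is.factor(v)) nlevels(v) else length(unique(v))
    if (n_lev < 2L) {
      dropped <- c(dropped, nm)
      df[[nm]] <- NULL
    }
  }
  X <- stats::model.matrix(~., data = df)
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    aliased <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, dropped = dropped)
}

#' Per-tissue linear models of expression on scaled age and sex
#'
#' For each tissue with enough samples, models voom-style log2-CPM (0.5-count
#' offset) of each gene as a linear function of scaled age (standardized to
#' mean 0, sd 1 within tissue by default) and sex, corrected for ischemic
#' time (numeric), Hardy scale (unordered categorical, missing as its own
#' level) and experimental batch (categorical), whichever of those covariates
#' the sample table carries. With `weights = "meanvar_trend"`, per-observation
#' precision weights are derived from a lowess-smoothed mean-variance trend
#' and the fits are weighted least squares; no empirical-Bayes moderation of
#' the standard errors is applied.
#'
#' @param counts an [expression_matrix()] of raw counts.
#' @param samples sample table with at least `sample_id`, `tissue`, `age`,
#'   `sex`; optional `ischemic_time`, `hardy_scale`, `batch`.
#' @param genes optional gene-id restriction applied after expression
#'   filtering (e.g. [core_plus_regulators()] output).
#' @param weights `"meanvar_trend"` (default) or `"none"`.
#' @param filter apply [filter_by_expression()] per tissue with sex as the
#'   group factor (default TRUE).
#' @param scale_age standardize age within tissue (default TRUE); set FALSE
#'   to pass a pre-scaled or global covariate through unchanged.
#' @param min_samples minimum samples per tissue after missing-covariate
#'   exclusion (default 10); smaller tissues are skipped with a warning.
#' @return a `de_result` data.frame with one row per (tissue, gene,
#'   covariate in {age, sex}): `beta` (log2 change per 1 sd of age, or F-vs-M
#'   contrast), `se`, `p` (two-sided t), `fdr_p` (`NA` until
#'   [collate_multitissue_fdr()]), `direction`.
#' @export
fit_covariate_models <- function(counts, samples, genes = NULL,
                                 weights = c("meanvar_trend", "none"),
                                 filter = TRUE, scale_age = TRUE,
                                 min_samples = 10L) {
  assert_units(counts, "raw_counts")
  weights <- match.arg(weights)
  stopifnot(all(c("sample_id", "tissue", "age", "sex") %in% names(samples)))
  res <- list()
  for (tt in unique(samples$tissue)) {
    st <- samples[samples$tissue == tt & samples$sample_id %in%
                    sample_ids(counts), , drop = FALSE]
    complete <- !is.na(st$age) & !is.na(st$sex)
    if (!is.null(st$ischemic_time)) complete <- complete & !is.na(st$ischemic_time)
    st <- st[complete, , drop = FALSE]
    if (nrow(st) < min_samples) {
      warning("skipping tissue ", tt, ": fewer than ", min_samples,
              " samples with complete covariates")
      next
    }
    em_t <- counts[, st$sample_id]
    keep <- if (filter) filter_by_expression(em_t, st$sex) else gene_ids(em_t)
    if (!is.null(genes)) keep <- intersect(keep, genes)
    if (!length(keep)) next
    x <- em_values(em_t)[keep, , drop = FALSE]
    lib <- colSums(em_values(em_t))
    y <- log_cpm(x, lib)
    des <- build_design(st, scale_age)
    if (length(des$dropped))
      warning("tissue ", tt, ": constant covariate(s) dropped: ",
              paste(des$dropped, collapse = ", "))
    X <- des$X
    n <- nrow(X); p <- ncol(X)
    if (n <= p) {
      warning("skipping tissue ", tt, ": design has no residual df")
      next
    }
    W <- if (weights == "meanvar_trend") meanvar_weights(y, X, lib) else NULL
    want <- c(age = "scaled_age", sex = "sexF")
    want <- want[want %in% colnames(X)]
    if (!length(want)) next
    rdf <- n - p
    G <- nrow(y)
    beta_m <- se_m <- matrix(NA_real_, G, length(want),
                             dimnames = list(rownames(y), names(want)))
    for (g in seq_len(G)) {
      yg <- y[g, ]
      fit <- if (is.null(W)) stats::lm.fit(X, yg)
      else stats::lm.wfit(X, yg, W[g, ])
      rss <- if (is.null(W)) sum(fit$residuals^2)
      else sum(W[g, ] * fit$residuals^2)
      dinv <- diag(chol2inv(qr.R(fit$qr)))[order(fit$qr$pivot)]
      se_all <- sqrt(pmax(dinv, 0) * rss / rdf)
      names(se_all) <- colnames(X)
      beta_m[g, ] <- fit$coefficients[want]
      se_m[g, ] <- se_all[want]
    }
    p_m <- 2 * stats::pt(abs(beta_m / se_m), rdf, lower.tail = FALSE)
    res[[length(res) + 1L]] <- data.frame(
      tissue = tt,
      gene_id = rep(rownames(y), times = length(want)),
      covariate = rep(names(want), each = G),
      beta = as.vector(beta_m), se = as.vector(se_m), p = as.vector(p_m),
      fdr_p = NA_real_, direction = sign(as.vector(beta_m)),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no tissue could be modeled")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Pool per-tissue results and apply FDR control
#'
#' Collates model results across all tissues and applies Benjamini-Hochberg
#' correction over the pooled (tissue, gene) rows, one family per covariate.
#' A `summary` attribute tallies significant rows, unique significant genes,
#' and direction counts per covariate at the given threshold.
#'
#' @param results a `de_result` from [fit_covariate_models()].
#' @param fdr significance threshold used for the summary tallies (default
#'   0.05).
#' @param per_tissue adjust within each tissue separately instead of pooling
#'   (off by default; the pooled family is the primary analysis).
#' @return the `de_result` with `fdr_p` filled in.
#' @export
collate_multitissue_fdr <- function(results, fdr = 0.05, per_tissue = FALSE) {
  stopifnot(inherits(results, "de_result") || is.data.frame(results))
  out <- results
  fam <- if (per_tissue) interaction(out$covariate, out$tissue, drop = TRUE)
  else factor(out$covariate)
  for (f in levels(fam)) {
    idx <- fam == f
    out$fdr_p[idx] <- stats::p.adjust(out$p[idx], method = "BH")
  }
  summ <- lapply(split(out, out$covariate), function(d) {
    sig <- d[!is.na(d$fdr_p) & d$fdr_p < fdr, , drop = FALSE]
    list(n_significant = nrow(sig),
         n_unique_genes = length(unique(sig$gene_id)),
         n_up = sum(sig$direction > 0), n_down = sum(sig$direction < 0))
  })
  attr(out, "summary") <- summ
  class(out) <- c("de_result", "data.frame")
  out
}

#' Reporting filter: most varied transcripts
#'
#' For each tissue, selects the gene with the smallest adjusted p-value per
#' covariate, plus every other significant instance of those genes with
#' `|beta|` at or above `beta_min` — the selection rule behind the "most
#' varied transcripts" displays.
#'
#' @param results a `de_result` with `fdr_p` filled.
#' @param covariate `"age"` or `"sex"`.
#' @param fdr significance threshold (default 0.05).
#' @param beta_min effect-size floor for the secondary instances (default
#'   0.15).
#' @return subset of `results`.
#' @export
top_de_genes <- function(results, covariate = c("age", "sex"), fdr = 0.05,
                         beta_min = 0.15) {
  covariate <- match.arg(covariate)
  d <- results[results$covariate == covariate & !is.na(results$fdr_p) &
                 results$fdr_p < fdr, , drop = FALSE]
  if (!nrow(d)) return(d)
  top_per_tissue <- do.call(rbind, lapply(split(d, d$tissue), function(x)
    x[which.min(x$fdr_p), , drop = FALSE]))
  genes <- unique(top_per_tissue$gene_id)
  extra <- d[d$gene_id %in% genes & abs(d$beta) >= beta_min, , drop = FALSE]
  out <- unique(rbind(top_per_tissue, extra))
  out[order(out$tissue, out$fdr_p), , drop = FALSE]
}
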