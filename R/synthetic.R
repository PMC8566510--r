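#' Cohort simulation specification
#'
#' Describes a synthetic multi-tissue bulk RNA-seq cohort with the
#' statistical structure the downstream analyses assume: negative-binomial
#' counts (`Var = mu + phi mu^2`, per-gene dispersions gamma-distributed),
#' lognormal library sizes, tissue / batch offsets, planted age and sex
#' effects on the log2 scale, and correlated gene blocks induced through a
#' Gaussian copula on the latent log-means. Defaults mirror the GTEx cohort
#' shape at desk scale: a roughly 2:1 male:female cohort with ages centered
#' near 53 (sd ~13), 3 experimental batches, and <= a few hundred samples.
#'
#' @param n_tissues number of tissues.
#' @param samples_per_tissue subjects (one sample per subject per tissue).
#' @param n_genes total genes.
#' @param fraction_matrisome fraction of genes assigned to matrisome
#'   categories in the generated catalog.
#' @param nb_dispersion list `(shape, rate)` of the gamma prior on per-gene
#'   dispersion phi (default mean 0.1).
#' @param library_size list `(meanlog, sdlog)` of lognormal library-size
#'   factors.
#' @param age_range truncation range of the age distribution (years).
#' @param age_mean,age_sd normal age parameters before truncation.
#' @param male_fraction probability a subject is male.
#' @param n_batches number of experimental batches.
#' @param base_logmean_mean,base_logmean_sd natural-log baseline expression.
#' @param tissue_sd,batch_sd sd of per-gene tissue and batch offsets (natural
#'   log).
#' @param planted_age_effects,planted_sex_effects named numeric vectors
#'   (gene id -> log2 effect per sd of age, resp. F-vs-M contrast).
#' @param correlated_blocks list of blocks, each a list with `size`,
#'   `tau` (within-block Kendall target, |tau| <= 0.95), and optional `sign`
#'   (+1/-1 per gene, recycled) and `logmean` (baseline for block genes,
#'   default 7 so the latent structure dominates the counting noise).
#' @param block_dispersion dispersion of block genes (small, so the copula
#'   correlation survives counting noise).
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_tissues = 3, samples_per_tissue = 60, n_genes = 600,
                        fraction_matrisome = 0.3,
                        nb_dispersion = list(shape = 2, rate = 20),
                        library_size = list(meanlog = log(5e5), sdlog = 0.2),
                        age_range = c(20, 70), age_mean = 52.76, age_sd = 12.91,
                        male_fraction = 653 / 980, n_batches = 3,
                        base_logmean_mean = 4, base_logmean_sd = 1.2,
                        tissue_sd = 0.4, batch_sd = 0.15,
                        planted_age_effects = NULL, planted_sex_effects = NULL,
                        correlated_blocks = list(),
                        block_dispersion = 0.02, seed = 1L) {
  if (!all(vapply(correlated_blocks, function(blk)
    is.list(blk) && !is.null(blk$size) && !is.null(blk$tau) &&
      abs(blk$tau) <= 0.95, logical(1))))
    stop("each correlated block needs 'size' and 'tau' with |tau| <= 0.95 ",
         "(larger targets are infeasible through the copula)")
  structure(as.list(environment()), class = "cohort_spec")
}

# internal: restore the caller's RNG stream on exit
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# internal: truncated normal by rejection (ranges used are wide, so cheap)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' Generate a synthetic multi-tissue cohort
#'
#' Draws counts `NB(mean = s_i * exp(b_g + tissue_{g,t(i)} + ln2 * (
#' beta_age_g * age_i^scaled + beta_sex_g * [sex_i = F]) + batch_{g,b(i)} +
#' block term), dispersion phi_g)`. Correlated blocks share a per-sample
#' latent factor: gene g in a block with target Kendall tau gets
#' `sign_g * (sqrt(rho) f_i + sqrt(1 - rho) e_ig)` added to its log-mean,
#' with `rho = sin(pi * tau / 2)` (the Gaussian-copula inversion of
#' Kendall's tau), scaled so the block structure dominates counting noise.
#'
#' @param spec a [cohort_spec()].
#' @return list with `counts` ([expression_matrix()] raw counts), `samples`
#'   (sample table), `catalog` (`matrisome_catalog`), and `truth` (planted
#'   effect and block assignments).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_sub <- spec$samples_per_tissue
    tissues <- sprintf("TIS%02d", seq_len(spec$n_tissues))
    subjects <- sprintf("SUBJ%03d", seq_len(n_sub))
    age <- rtruncnorm(n_sub, spec$age_mean, spec$age_sd,
                      spec$age_range[1], spec$age_range[2])
    sex <- factor(ifelse(stats::runif(n_sub) < spec$male_fraction, "M", "F"),
                  levels = c("M", "F"))
    bmi <- stats::rnorm(n_sub, 27, 4)
    samples <- do.call(rbind, lapply(tissues, function(tt) data.frame(
      sample_id = paste0(subjects, "-", tt), subject_id = subjects,
      tissue = tt, age = age, sex = sex,
      ischemic_time = stats::rlnorm(n_sub, log(300), 0.5),
      hardy_scale = factor(sample(as.character(0:4), n_sub, replace = TRUE),
                           levels = c(as.character(0:4), "(missing)")),
      batch = factor(sample(sprintf("B%02d", seq_len(spec$n_batches)), n_sub,
                            replace = TRUE)),
      bmi = bmi, disease = "none", stringsAsFactors = FALSE)))
    rownames(samples) <- NULL
    n <- nrow(samples)
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    b_g <- stats::rnorm(spec$n_genes, spec$base_logmean_mean,
                        spec$base_logmean_sd)
    phi <- stats::rgamma(spec$n_genes, shape = spec$nb_dispersion$shape,
                         rate = spec$nb_dispersion$rate)
    names(b_g) <- names(phi) <- genes
    tissue_eff <- matrix(stats::rnorm(spec$n_genes * spec$n_tissues, 0,
                                      spec$tissue_sd),
                         spec$n_genes, spec$n_tissues,
                         dimnames = list(genes, tissues))
    batches <- levels(samples$batch)
    batch_eff <- matrix(stats::rnorm(spec$n_genes * length(batches), 0,
                                     spec$batch_sd),
                        spec$n_genes, length(batches),
                        dimnames = list(genes, batches))
    scaled_age <- as.numeric(scale(samples$age))
    eta <- matrix(b_g, spec$n_genes, n, dimnames = list(genes,
                                                        samples$sample_id))
    eta <- eta + tissue_eff[, samples$tissue] + batch_eff[, as.character(samples$batch)]
    ln2 <- log(2)
    beta_age <- stats::setNames(rep(0, spec$n_genes), genes)
    if (!is.null(spec$planted_age_effects))
      beta_age[names(spec$planted_age_effects)] <- spec$planted_age_effects
    beta_sex <- stats::setNames(rep(0, spec$n_genes), genes)
    if (!is.null(spec$planted_sex_effects))
      beta_sex[names(spec$planted_sex_effects)] <- spec$planted_sex_effects
    eta <- eta + ln2 * outer(beta_age, scaled_age) +
      ln2 * outer(beta_sex, as.numeric(samples$sex == "F"))
    block_genes <- list()
    gi <- 0L
    for (bi in seq_along(spec$correlated_blocks)) {
      blk <- spec$correlated_blocks[[bi]]
      ids <- genes[gi + seq_len(blk$size)]
      gi <- gi + blk$size
      sgn <- rep(if (is.null(blk$sign)) 1 else blk$sign, length.out = blk$size)
      rho <- sin(pi * blk$tau / 2)
      f <- stats::rnorm(n)
      e <- matrix(stats::rnorm(blk$size * n), blk$size, n)
      z <- sqrt(rho) * f2mat(f, blk$size) + sqrt(1 - rho) * e
      lm0 <- if (is.null(blk$logmean)) 7 else blk$logmean
      eta[ids, ] <- lm0 + tissue_eff[ids, samples$tissue] + sgn * z
      phi[ids] <- spec$block_dispersion
      block_genes[[bi]] <- ids
    }
    lib <- stats::rlnorm(n, spec$library_size$meanlog, spec$library_size$sdlog)
    s_i <- lib / mean(lib)
    mu <- sweep(exp(eta), 2, s_i, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = rep(1 / phi, n)),
                     nrow = spec$n_genes, dimnames = dimnames(mu))
    n_mat <- round(spec$fraction_matrisome * spec$n_genes)
    mat_genes <- genes[seq_len(n_mat)]
    cats <- rep(MATRISOME_CATEGORIES, length.out = n_mat)
    catalog <- matrisome_catalog(mat_genes, category = cats)
    list(counts = expression_matrix(counts, "raw_counts"),
         samples = samples, catalog = catalog,
         truth = list(beta_age = beta_age, beta_sex = beta_sex,
                      blocks = block_genes, phi = phi, mu = mu,
                      scaled_age = scaled_age))
  })
}

# internal: replicate a sample-length vector across block genes
f2mat <- function(f, k) matrix(rep(f, each = k), k, length(f))

#' Generate a paired protein/transcript abundance table
#'
#' Transcript abundance is a lognormal latent; protein abundance shares a
#' bivariate-normal latent with Pearson correlation `r = 2 sin(pi rho / 6)`
#' so the realized Spearman correlation approximates each category's target.
#' A `non_matrisome` entry in `rho_by_category` supplies the background
#' pairs the permutation machinery samples from.
#'
#' @param n_pairs named integer vector: pairs per category (must include
#'   `non_matrisome`).
#' @param rho_by_category named numeric vector of target Spearman rho in
#'   (-1, 1), same names as `n_pairs`.
#' @param tissue tissue label stamped on the rows (default `"TIS01"`).
#' @param seed integer seed.
#' @return a `paired_abundance` data.frame (see [build_pair_table()]).
#' @export
generate_paired_proteome <- function(n_pairs, rho_by_category,
                                     tissue = "TIS01", seed = 1L) {
  stopifnot(identical(sort(names(n_pairs)), sort(names(rho_by_category))),
            "non_matrisome" %in% names(n_pairs))
  if (any(abs(rho_by_category) >= 1))
    stop("target rank correlations must lie in (-1, 1)")
  with_seed(seed, {
    rows <- list()
    gi <- 0L
    for (ct in names(n_pairs)) {
      n <- n_pairs[[ct]]
      if (n < 10 && abs(rho_by_category[[ct]]) > 0)
        warning("category '", ct, "': target correlation is unreliable at n = ",
                n)
      r <- 2 * sin(pi * rho_by_category[[ct]] / 6)
      z1 <- stats::rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
      rows[[ct]] <- data.frame(
        tissue = tissue, gene_id = sprintf("P%05d", gi + seq_len(n)),
        protein = exp(2 + z2), transcript = exp(3 + z1),
        category = ct, stringsAsFactors = FALSE)
      gi <- gi + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("paired_abundance", "data.frame")
    out
  })
}

#' Cancer trio simulation specification
#'
#' @param n_tissues number of tissues (default 5, the primary analysis
#'   scale).
#' @param n_genes shared gene universe size (default 400, the matrisome
#'   whitelist scale).
#' @param n_up,n_down planted up-/down-shifted gene counts (disjoint sets).
#' @param shift_log2 cancer shift size in log2 units (default 2).
#' @param n_gtex,n_tcga_n,n_tcga_c samples per dataset.
#' @param with_tcga_normal logical, recycled over tissues; `FALSE` drops the
#'   study normal for that tissue.
#' @param base_logmean_mean,base_logmean_sd natural-log baseline expression.
#' @param batch_scale_sd,batch_shift_sd per-dataset monotone distortion in
#'   log space: `eta' = a * eta + b`, `a ~ lognormal(0, batch_scale_sd)`,
#'   `b ~ normal(0, batch_shift_sd)`.
#' @param dispersion NB dispersion of all genes.
#' @param seed integer seed.
#' @return a `cancer_trio_spec` list.
#' @export
cancer_trio_spec <- function(n_tissues = 5, n_genes = 400, n_up = 20,
                             n_down = 20, shift_log2 = 2, n_gtex = 40,
                             n_tcga_n = 30, n_tcga_c = 40,
                             with_tcga_normal = TRUE,
                             base_logmean_mean = 5, base_logmean_sd = 1.2,
                             batch_scale_sd = 0.15, batch_shift_sd = 0.5,
                             dispersion = 0.05, seed = 1L) {
  stopifnot(n_up + n_down <= n_genes)
  structure(as.list(environment()), class = "cancer_trio_spec")
}

#' Generate normal/normal/cancer dataset trios
#'
#' Per tissue: a shared baseline log-mean per gene; the cancer dataset shifts
#' the planted up/down genes by `+/- shift_log2 * ln 2`; each dataset's
#' log-means then pass through an independent monotone batch distortion
#' (`a * eta + b`, `a > 0`) before negative-binomial sampling — emulating the
#' cross-dataset batch effects the rank-change statistic is designed to
#' survive.
#'
#' @param spec a [cancer_trio_spec()].
#' @return list with `trios` (list of [dataset_trio()]), `planted_up`,
#'   `planted_down` (gene ids).
#' @export
generate_cancer_trio <- function(spec) {
  stopifnot(inherits(spec, "cancer_trio_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    planted_up <- genes[seq_len(spec$n_up)]
    planted_down <- genes[spec$n_up + seq_len(spec$n_down)]
    shift <- stats::setNames(rep(0, spec$n_genes), genes)
    shift[planted_up] <- spec$shift_log2 * log(2)
    shift[planted_down] <- -spec$shift_log2 * log(2)
    with_n <- rep(spec$with_tcga_normal, length.out = spec$n_tissues)
    trios <- lapply(seq_len(spec$n_tissues), function(ti) {
      base <- stats::rnorm(spec$n_genes, spec$base_logmean_mean,
                           spec$base_logmean_sd)
      sample_ds <- function(eta, n_samp, prefix) {
        a <- stats::rlnorm(1, 0, spec$batch_scale_sd)
        b <- stats::rnorm(1, 0, spec$batch_shift_sd)
        mu <- exp(a * eta + b)
        cnt <- matrix(stats::rnbinom(spec$n_genes * n_samp,
                                     mu = mu, size = 1 / spec$dispersion),
                      spec$n_genes, n_samp,
                      dimnames = list(genes, sprintf("%s_T%02d_%03d", prefix,
                                                     ti, seq_len(n_samp))))
        expression_matrix(cnt, "raw_counts")
      }
      gtex <- sample_ds(base, spec$n_gtex, "GTEXN")
      tcga_n <- if (with_n[ti]) sample_ds(base, spec$n_tcga_n, "TCGAN")
      tcga_c <- sample_ds(base + shift, spec$n_tcga_c, "TCGAC")
      dataset_trio(sprintf("T%02d", ti), gtex, tcga_c, tcga_n)
    })
    list(trios = trios, planted_up = planted_up, planted_down = planted_down)
  })
}

#' Generate a synthetic lung fibrosis cohort
#'
#' Emulates the integration of a lung fibrosis study with normal reference
#' samples: a latent severity score per sample (near zero in normal and
#' ventilator-injury lung, intermediate in acute lung injury, high in
#' fibrosis, following the observed effect ordering) drives an
#' anti-correlated pair of gene programs — program 1 up, program 2 down —
#' on top of negative-binomial counts with per-source batch offsets
#' (reference cohort vs. two study batches).
#'
#' @param n_normal,n_vent,n_ali,n_ipf study sample counts (defaults 26, 10,
#'   8, 46, the integrated-study shape; `n_vent` and `n_ref_normal` samples
#'   come from the reference source).
#' @param n_ref_normal normal samples from the reference cohort (default 10).
#' @param program_sizes integer vector (program 1, program 2) (default
#'   `c(15, 10)`).
#' @param severity_means named means of the latent severity per disease
#'   (defaults `c(normal = 0, ventilator_injury = 0.15, ALI = 0.47,
#'   IPF = 1.63)`).
#' @param severity_sd within-group sd of the latent severity.
#' @param loading log-scale effect of severity on program genes.
#' @param gene_noise_sd per-gene, per-sample latent noise (keeps program
#'   correlations below 1).
#' @param n_filler matrisome background genes of low variance.
#' @param batch_sd sd of per-gene batch offsets.
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @return list with `counts` ([expression_matrix()]), `samples` (sample
#'   table with `disease` and `batch`), `program1`, `program2` (gene ids).
#' @export
generate_lung_cohort <- function(n_normal = 26, n_vent = 10, n_ali = 8,
                                 n_ipf = 46, n_ref_normal = 10,
                                 program_sizes = c(15, 10),
                                 severity_means = c(normal = 0,
                                                    ventilator_injury = 0.15,
                                                    ALI = 0.47, IPF = 1.63),
                                 severity_sd = 0.3, loading = 1.4,
                                 gene_noise_sd = 0.45, n_filler = 300,
                                 batch_sd = 0.25, dispersion = 0.05,
                                 seed = 1L) {
  with_seed(seed, {
    disease <- c(rep("normal", n_normal), rep("ALI", n_ali),
                 rep("IPF", n_ipf), rep("ventilator_injury", n_vent),
                 rep("normal", n_ref_normal))
    batch <- c(sample(c("STUDY-1", "STUDY-2"), n_normal + n_ali + n_ipf,
                      replace = TRUE),
               rep("REF", n_vent + n_ref_normal))
    n <- length(disease)
    sample_id <- sprintf("LNG%03d", seq_len(n))
    samples <- data.frame(
      sample_id = sample_id, subject_id = sample_id, tissue = "LUNG",
      age = round(rtruncnorm(n, 60, 10, 30, 85)),
      sex = factor(sample(c("M", "F"), n, replace = TRUE),
                   levels = c("M", "F")),
      batch = factor(batch), disease = factor(disease,
        levels = c("normal", "ventilator_injury", "ALI", "IPF")),
      stringsAsFactors = FALSE)
    severity <- stats::rnorm(n, severity_means[as.character(disease)],
                             severity_sd)
    p1 <- sprintf("PRG1_%03d", seq_len(program_sizes[1]))
    p2 <- sprintf("PRG2_%03d", seq_len(program_sizes[2]))
    filler <- sprintf("FIL_%04d", seq_len(n_filler))
    genes <- c(p1, p2, filler)
    base <- c(stats::rnorm(length(p1), 6, 0.3),
              stats::rnorm(length(p2), 6, 0.3),
              stats::rnorm(n_filler, 4.5, 1))
    names(base) <- genes
    load_vec <- stats::setNames(rep(0, length(genes)), genes)
    load_vec[p1] <- loading
    load_vec[p2] <- -loading
    eta <- outer(base, rep(1, n)) + outer(load_vec, severity)
    eta[c(p1, p2), ] <- eta[c(p1, p2), ] +
      matrix(stats::rnorm(length(c(p1, p2)) * n, 0, gene_noise_sd),
             length(c(p1, p2)), n)
    batches <- levels(samples$batch)
    batch_eff <- matrix(stats::rnorm(length(genes) * length(batches), 0,
                                     batch_sd),
                        length(genes), length(batches),
                        dimnames = list(genes, batches))
    eta <- eta + batch_eff[, as.character(samples$batch)]
    colnames(eta) <- sample_id
    counts <- matrix(stats::rnbinom(length(eta), mu = exp(eta),
                                    size = 1 / dispersion),
                     nrow = length(genes), dimnames = dimnames(eta))
    list(counts = expression_matrix(counts, "raw_counts"), samples = samples,
         program1 = p1, program2 = p2, severity = severity)
  })
}
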