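---
title: "Matrisome transcriptomics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrisome transcriptomics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrisomics)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely open.

## The analysis gene set

The matrisome catalog divides ECM genes into a core division (collagens,
proteoglycans, ECM glycoproteins — the structural scaffold) and an
associated division (ECM regulators, ECM-affiliated proteins, secreted
factors). All analyses here run on the core matrisome plus the ECM
regulators (`core_plus_regulators()`); affiliated proteins and secreted
factors are excluded because they are not integral structural elements.
The catalog must be keyed on the same identifier space as the expression
input — the package strips Ensembl version suffixes at read time and treats
collisions as errors rather than merging, so joins stay deterministic.

## Normalization

**Size factors.** Sequencing depth is removed with median-of-ratios
factors: gene references are geometric means across samples, and a sample's
factor is the median of its count-to-reference ratios over genes positive in
every sample. The median is taken on the ratio scale, exactly as defined.
One consequence worth knowing: scaling a single sample's counts by $c$
rescales every geometric mean by $c^{1/n}$, so the scaled sample's factor
moves by $c^{1-1/n}$ and the others by $c^{-1/n}$ — relative depth (factor
ratios) scales by exactly $c$. There is no pseudo-reference fallback: if no
gene is positive everywhere the function stops and says so.

**Variance-stabilizing transform.** The VST assumes counts are negative
binomial with $\mathrm{Var} = \mu + \phi\mu^2$ and a parametric dispersion
trend $\phi(\mu) = a/\mu + b$. Per-gene dispersions are method-of-moments
estimates on size-factor-normalized counts; the trend is fitted by an
iterated gamma GLM that drops gross ratio outliers (outside
$[10^{-4}, 15]$ of the fit), and the closed-form VST of the fitted family is
applied. The transform is strictly increasing, behaves like $2\sqrt{x}$ for
Poisson-like data, and gains exactly one unit per doubling at large counts.
Two fallbacks: a fitted $a \le 0$ drops the $1/\mu$ term (constant
dispersion, with a warning); a fitted $b \le 0$ (Poisson-like data) clamps
$b$ at $10^{-8}$, which preserves monotonicity and the square-root shape.
This is deliberately a self-contained approximation without gene-wise
dispersion shrinkage: every downstream stage that crosses datasets is
rank-based, and ranks are invariant to any per-sample monotone transform, so
approximation error does not propagate into rank-change results. The
planted-trend recovery test holds the fit to within 20% of the generating
$(a, b)$ at 2000 genes.

**Quantile normalization.** All columns are forced onto the per-rank mean
of the sorted columns. Ties receive the mean of the reference quantiles they
span — the de-facto standard rule. Note this makes the "all columns share
one multiset" property exact only for tie-free columns: tied entries
collapse to averaged values by construction.

## Protein–transcript concordance

For a tissue and category with $N$ paired, strictly positive protein and
transcript abundances, the observed Spearman correlation is compared to
`n_perm` correlations of random size-$N$ subsets (without replacement,
independent across draws) of the tissue's non-matrisome pairs. The verdict
uses two-sided empirical quantiles at $\alpha = 0.05$ by default — the only
reading under which "equivalent" is the bulk outcome, as observed in
practice. The paper-scale run uses 10,000 permutations; the calibration
suite uses 400, which is enough for 2.5% tails.

Two design notes. First, seeding: each (tissue, category) derives its own
stream from the global seed by string hashing, so results are reproducible
and independent of call order. Second, the calibration suite draws 30
category pairs against a 2000-pair background. The large background mirrors
the real geometry (genome-wide non-matrisome pools of thousands of pairs
against tens of category pairs); with a small pool the permutation null is
conditionally narrow — subsets of one small sample share too much — and the
nominal 5% extreme rate inflates to roughly 7%.

## Age and sex models

Per tissue, each gene's response is $\log_2$ counts-per-million with a
0.5-count offset. Age is standardized to mean 0, sd 1 *within tissue* (the
scaling is applied where the model is fitted; a flag passes a pre-scaled
covariate through). Sex, Hardy scale (unordered categorical — the 0–4 codes
are not linear in severity — with missing as its own level), and batch enter
as indicator contrasts; ischemic time is numeric. With
`weights = "meanvar_trend"`, a lowess of $\sqrt{\text{residual sd}}$ against
average log-count supplies per-observation precision weights, and fits are
weighted least squares. There is no empirical-Bayes moderation of standard
errors: the package validates this machinery by recovery properties
(sensitivity $\ge 0.9$ and empirical FDR $\le 0.075$ at planted
$|\beta| = 0.5$, $n = 200$, 5000 genes, averaged over 20 seeds) rather than
coefficient-level equality with a moderated fit, since shrinkage affects
standard errors, not identifiability.

FDR control pools all (tissue, gene) rows into one Benjamini–Hochberg family
per covariate; per-tissue families exist behind a flag but are off by
default, because the screen is reported body-wide. One subtlety the null
tests respect: within a single permutation of age, all genes share the
library-size component of log-CPM, so per-shuffle beta signs are correlated
across genes; sign balance is therefore assessed pooled over several
shuffles.

The reporting filter (`top_de_genes`) mirrors the usual display: the
smallest-FDR gene per tissue, plus that gene's other significant instances
with $|\beta| \ge 0.15$; both thresholds are arguments.

## Co-expression programs

Genes pass a high-variance filter (mean VST expression $> 5$ and variance
$> 1.5$ for adipose-style analyses; variance $> 2$ for the lung analysis —
the stricter floor suits a cohort with disease-driven variance). Clustering
is average linkage on $1 - \tau$ (Kendall tau-b); average linkage respects
correlation structure better than complete linkage, which is reserved for
sample/tissue display clustering.

**The cut.** The critical value uses the normal approximation of the null
tau at $n$ samples, Bonferroni-corrected over all $\binom{g}{2}$ gene pairs.
Both $\alpha$ and the correction are configurable, since "based on the
number of samples and genes" admits several readings; Bonferroni-over-pairs
is the conservative one and calibrates the i.i.d.-noise null to produce no
clusters. Partitions are scanned from coarsest to finest and the first
partition whose every size-$\ge 2$ cluster passes is accepted — i.e. the
*largest* valid cut height. Scanning from the finest end instead would
always accept the all-singleton partition vacuously and return nothing, so
coarsest-first is the only self-consistent direction; at equal heights the
finer partition (as `cutree` orders merges) wins.

**Anti-correlated programs.** A candidate cluster containing negatively
correlated gene pairs is recursively re-cut along its own subtree until
every piece has non-negative internal correlation; the tau bound then
applies to each piece, and pieces are reported as paired sub-clusters
(`c1.1`, `c1.2`) of one parent. The check runs *before* the bound: a parent
made of two anti-correlated halves has mean pairwise tau near zero and could
never be accepted otherwise, yet it is exactly the structure fibrosis
programs show. The same rule serves both the adipose and lung analyses.

**The score.** The cluster score is
$S_i = \frac{1}{J}\sum_j (x_{ij} - \bar{x}_j)/\mathrm{MAD}_j$ with tissue-wise
means in the numerator and the *raw* median absolute deviation about the
tissue median in the denominator — no 1.4826 consistency constant, matching
the mixed mean/median definition exactly. Zero-MAD genes are excluded per
tissue with a warning and $J$ decremented. Consequences asserted in the
tests: tissue-wise score means are zero to machine precision, and the score
is invariant under per-gene positive affine maps.

**Association models.** Fixed-effects fits average repeated measurements per
subject first when requested; the random-intercept variant
($y = X\beta + u_{subject} + \varepsilon$) is fitted by REML via lme4, and
fixed-effect p-values are Wald normal approximations — adequate at the
cohort sizes involved and free of extra dependencies; exact small-sample
df corrections are out of scope.

## Normal-vs-cancer rank changes

The whitelist is two-stage per dataset: total raw count $> 5$ (strict),
then mean VST $> 5$; a gene enters the final list if it passes in *any*
dataset of the trio, which deliberately admits genes silent in normal tissue
but active in cancer. The trio is quantile-normalized together over the
whitelist, re-separated, and each gene ranked (ascending, average ranks on
ties) by its per-dataset mean. The joined normal is the unweighted mean of
the reference-normal and study-normal means regardless of their sample
sizes; tissues without a study normal use the reference mean alone.

$\Delta = \mathrm{rank}(cancer) - \mathrm{rank}(joined)$, so positive means
relatively up in cancer. Batch robustness is structural: only within-dataset
orderings of means enter, so any strictly monotone per-dataset distortion
leaves deltas bit-identical — the tests verify this with random monotone
maps applied to the mean profiles. Deltas are summed across the tissues
where the gene is whitelisted; per-tissue and summed deltas are segmented
into equal-count deciles (sizes differ by at most one; boundary ties break
by gene id, logged in the documentation rather than silently). Decile
membership matrices mark non-whitelisted genes `NA`. The planted-shift
condition (5 tissues, 400 genes, 20 up / 20 down at 2 log2 units, distinct
per-dataset distortions) recovers at least 18 of 20 per direction in the
extreme summed deciles across 10 seeds.

## What the generators emulate — and what they do not

All generators are pure functions of a spec plus seed.

`generate_cohort`: negative-binomial counts,
$\mathrm{Var} = \mu + \phi\mu^2$, gamma-distributed dispersions (matching the
VST's trend model, which makes the trend-recovery test possible), lognormal
library sizes, per-gene tissue and batch offsets, planted age/sex effects in
log2-per-sd units, and correlated blocks through a Gaussian copula on the
latent log-means ($\rho = \sin(\pi\tau/2)$, the copula inversion of the
Kendall target) — chosen over factor models for direct control of rank
correlation targets. Block genes get a high baseline and small dispersion so
the latent correlation survives counting noise; targets above $|\tau| =
0.95$ are rejected as infeasible. The cohort shape mirrors the reference
cohort at desk scale: roughly 2:1 male, ages near 52.8 (sd 12.9) truncated
to 20–70, three batches, at most a few hundred samples and a few thousand
genes. Subjects span tissues (one sample per subject per tissue) so
multi-tissue subject scores are well-defined.

`generate_paired_proteome`: lognormal abundances over a shared bivariate
latent with Pearson $r = 2\sin(\pi\rho_s/6)$, giving realized Spearman
correlations within about $\pm 0.05$ of target at 2000 pairs.

`generate_cancer_trio`: shared per-tissue baselines, planted $\pm$2-log2
shifts in cancer, and an independent monotone distortion
($a\cdot\eta + b$ in log space, $a$ lognormal) per dataset before sampling.
Because the distortion precedes the count noise, "identical vs distinct
distortions" yields different random draws; monotone invariance is instead
verified deterministically at the mean-rank level.

`generate_lung_cohort`: a latent severity score (means 0 / 0.15 / 0.47 /
1.63 for normal / ventilator / acute injury / fibrosis — the observed effect
ordering, with within-group sd 0.3) loads positively on program 1 and
negatively on program 2, plus per-source batch offsets (one reference batch,
two study batches) and low-variance filler genes that the variance filter
should reject. Disease-by-cluster agreement is scored over fibrosis and
normal samples only: acute-injury and ventilator samples are intermediate by
construction (and in the real phenomenon), so counting them against the
pipeline would misread the design. One caveat the null tests respect: the
reference batch contains no fibrosis samples, so under zero effect sizes a
whole-cohort clustering still aligns with disease composition through the
batch offsets; the decoupling check therefore runs within the study batches.

What none of this emulates: GC/length biases, sample contamination,
zero-inflation beyond the NB, real gene-gene networks (only planted blocks),
or real matrisome gene identities. Passing tests demonstrate that the
machinery recovers known structure under its stated model, not that the
model captures every property of real cohorts.

## Numerical choices and degenerate inputs

- Problem sizes in tests and the acceptance script are desk scale by
  design (≤ 5000 genes, ≤ 200 samples per run); they exercise the same code
  paths as cohort-scale data.
- Kendall correlations use tau-b (tie-corrected); Spearman uses average
  ranks. Abundance data tie at detection limits, so tie handling is not
  optional.
- Wilcoxon group tests are exact for small tie-free samples
  ($n + m \le 20$), normal-approximated with tie correction otherwise; Holm
  corrects across the supplied gene list.
- Constant vectors make rank correlations undefined: flagged `NA` with a
  warning, and constant profiles are excluded from correlation matrices.
- Empty high-variance filter results, empty whitelists, all-zero-MAD
  clusters, rank-deficient designs (reported with the aliased columns
  named), and k exceeding the sample count are all hard errors, not silent
  degradations.
- Missing categorical covariates become an explicit level; missing numeric
  covariates exclude a sample only from models that need them. Nothing is
  imputed.

## A walkthrough

```{r example, eval = FALSE}
sim <- generate_cohort(cohort_spec(
  n_tissues = 1, samples_per_tissue = 100, n_genes = 300,
  correlated_blocks = list(list(size = 12, tau = 0.6)), seed = 1))
v <- vst_transform(sim$counts)
hv <- high_variance_filter(v, mean_min = 5, var_min = 1.5)
cs <- cut_clusters(v[hv, ])
sc <- cluster_score(v, sim$samples, cs$clusters[[1]])
fit <- association_models(cbind(sc, sex = sim$samples$sex,
                                bmi = sim$samples$bmi),
                          "score", c("sex", "bmi"))
```

## Known limitations

- The VST omits gene-wise dispersion shrinkage; per-gene transformed values
  differ in the tails from a shrinkage-based implementation, though all
  rank-based downstream results are unaffected.
- Mixed-model p-values are Wald approximations; with very few subjects they
  are anti-conservative.
- The tau-critical formula is a normal approximation; below ~8 samples its
  permutation accuracy degrades (the tests pin it to within 0.03 of a
  20,000-shuffle null at n = 12).
- The permutation verdict's nominal size assumes a background pool much
  larger than the category; with pools within an order of magnitude of the
  category size, expect mild anti-conservatism.
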