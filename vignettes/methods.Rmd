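---
title: "Models and methods in isletqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in isletqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletqtl)
```

isletqtl maps genetic effects on alternative splicing and gene
expression in cis, and integrates those maps with GWAS summary
statistics through enrichment testing, fine-mapping, colocalization and
TWAS. This vignette describes the statistical models, the defaults and
why they were chosen, what the synthetic-data generator does and does
not emulate, and the numerical choices that matter for reproducing
results.

## Phenotypes

**Splicing.** Junction-spanning read counts are filtered (at least 5
reads in at least 10% of samples), junctions longer than 500 kb are
dropped, and the remainder are clustered: two junctions belong to the
same cluster when they share a donor or acceptor coordinate on the same
chromosome and strand (connected components of the shared-site graph).
Clusters need at least two junctions and at least 30 reads in total.
The splicing phenotype of junction $j$ in sample $s$ is its percent
spliced in,
$\mathrm{PSI}_{js} = c_{js} / \sum_{k \in \mathrm{cluster}(j)} c_{ks}$,
with a missing value when the cluster total is zero; junctions missing
in more than half the samples are dropped. The cluster read threshold
is interpreted as total reads summed over all samples (a per-sample
variant can be configured). PSI values are standardized per junction by
a rank-based inverse-normal transform,
$\Phi^{-1}((r_{js} - 0.5)/n)$ with average ranks for ties and
median-imputation of missing values before ranking. Rank-inverse-normal
is standard practice in QTL mapping; it makes the permutation scheme
exact under exchangeability and removes any dependence on the raw PSI
scale. Whether standardization should precede or follow batch
adjustment is a genuinely open ordering question; the pipeline
standardizes first and then batch-adjusts, which removes planted batch
structure exactly in simulation.

**Expression.** Gene counts are filtered (at least 5 reads in at least
10% of samples within every cohort), CPM-normalized via edgeR and
log2-transformed with a pseudocount of 1.

**Batch adjustment.** Known batches are removed by a per-feature
location–scale adjustment: each batch is centered at its own mean and
rescaled to the pooled residual standard deviation, and the grand mean
is restored. This replaces empirical-Bayes batch correction (ComBat):
with tens to hundreds of simulated features per run there is little to
be gained from shrinkage across features, the location–scale form
removes the planted batch structure exactly, and the substitution keeps
the pipeline free of any fitting step whose behavior would have to be
re-validated here. The limitation is real: on small real datasets
ComBat's shrinkage is better-behaved per feature.

**Covariates.** Principal components of the phenotype matrix (15 for
expression, 5 for splicing in the study-scale configuration; the demo
pipeline uses 5 and 3 at its smaller feature counts) are computed on
feature-standardized values with a deterministic sign convention (the
largest-magnitude loading of each component is positive).

## cis-QTL mapping

Variants are tested within TSS ± 500 kb for expression and junction
± 50 kb for splicing. For each feature the phenotype and each dosage
column are residualized on the covariates plus an intercept; slope, t
and two-sided p come from the simple regression of residuals with
$df = n - n_{\mathrm{cov}} - 2$, which equals the full multiple
regression by the Frisch–Waugh theorem (verified against `lm()` in the
tests). Missing dosages are mean-imputed inside the computation only
and never stored.

**Permutation pass.** The covariate-residualized phenotype is permuted
$B = 1000$ times with genotypes and covariates held fixed — the scheme
used by the standard QTL mapping tools whose behavior this package
reproduces. The best nominal p of each permutation is collected;
the empirical p-value is $(r+1)/(B+1)$, and a Beta$(a,b)$ distribution
fitted to the $B$ permutation minima by maximum likelihood (Newton
iterations on $(\log a, \log b)$, method-of-moments start, tolerance
1e-8, at most 100 iterations, with a flagged moments fallback)
interpolates beyond the $1/(B+1)$ resolution:
$p_\beta = F_{\mathrm{Beta}(a,b)}(p_{\min})$. Under a window of $M$
independent null variants the minimum is Beta$(1, M)$; the fit
recovering $b \approx M$ is a calibration check in the tests. Permuted
p-values are clamped to $[10^{-12}, 1-10^{-12}]$ before fitting, and
$p_\beta$ is floored at the smallest positive double so it is never 0.

**Per-feature permutation streams** are derived by hashing the feature
id together with the master seed, so results do not change when
features are added or removed.

**Multiple testing.** Storey q-values with a single fixed
$\lambda = 0.5$: $\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda) m)$
clipped to $(0,1]$, and
$q_i = \hat\pi_0 \min_{p_j \ge p_i} (m p_j / \mathrm{rank}_j)$. The
spline smoother used by the qvalue package is deliberately not
implemented: at the feature counts involved the difference is
negligible and the fixed-λ estimator is deterministic. With
$\hat\pi_0 = 1$ the q-values reduce to Benjamini–Hochberg (asserted in
the tests). Features are significant at $q \le 0.01$.

**Hierarchical nominal thresholds.** The genome-wide threshold $p_t$ is
the beta-approximated empirical p of the feature whose q is closest to
the FDR level (ties toward the smaller p; the reference implementation
in the field may differ by one feature at the boundary, which is why
the tie rule is stated). Each significant feature's nominal cutoff is
the back-transform $F^{-1}_{\mathrm{Beta}(a,b)}(p_t)$, and its
nominally significant variants are those at or below that cutoff. Leads
are chosen by smallest p, then smallest position, then id — the tie
order is a package convention, stated because no reference defines one.
Features whose cis window contains no polymorphic variant are reported
with $q = 1$ rather than dropped.

**Effect sizes.** ΔPSI is the difference in median raw (not
standardized) PSI between homozygous-alternate and homozygous-reference
carriers of the lead variant, with the heterozygote median substituting
when no homozygous-alternate samples exist; within each cluster only
the junction with the best q is reported.

## The LD-matched control-variant null

QTL variants are not exchangeable with random variants: they cluster in
LD blocks and have distinctive allele frequencies. Inflation of GWAS
signal among QTL variants is therefore judged against control sets that
preserve the query's regional footprint. LD blocks are inferred by a
greedy scan (a new block opens when a variant's maximum r² with the
previous 50 variants falls below 0.1; blocks tile each chromosome).
For each block containing query variants the bp span of those variants
is recorded; per permutation, intervals of those sizes are placed
uniformly at random, non-overlapping, outside all query-bearing blocks
and outside blacklist/MHC-analog exclusions, and exactly $|query|$
control variants are sampled from candidates inside the placed
intervals. When the placed intervals contain fewer candidates than
needed (a boundary effect at matched variant density), additional
median-size intervals are placed; set size and exclusion compliance are
never relaxed. Shuffling whole-block sizes instead of query spans is
available as a configured alternative.

The QQ comparison restricts to MAF ≥ 5%, plots observed sorted
$-\log_{10} p$ against expected $-\log_{10}((i-0.5)/n)$, and draws a
rank-wise 2.5%/97.5% envelope over the control sets. The enrichment
flag is raised when the majority of the top-decile ranks exceed the
upper envelope. A weaker rule (any single exceedance among the top
ranks) was rejected after measurement: a pointwise 97.5% envelope is
exceeded somewhere in the top decile by chance often enough to give a
~10% false-flag rate, while the majority rule measures 2.5% on null
queries and still flags every planted-enrichment scenario in the
calibration suite. The fraction is configurable.

Annotation enrichment uses the same control sets: a lead hits an
annotation when it or any proxy (r² ≥ 0.7 within 50 kb) overlaps it;
fold change is observed hits over mean control hits and the empirical p
is $(\#\{ \mathrm{controls} \ge \mathrm{obs}\} + 1)/(B+1)$. The full
covariate-adjusted logistic enrichment model of GARFIELD is out of
scope; the three QTL p-value strata (5e-3, 5e-5, 5e-7) are supported as
query filters.

## Fine-mapping

Under the restriction of one causal variant per locus, the joint
multivariate-normal likelihood used by CAVIAR factorizes so that the
posterior over causal configurations reduces to per-variant Wakefield
approximate Bayes factors with a uniform prior:
$\log \mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 r z^2$,
$r = W/(W + \mathrm{se}^2)$, and
$\mathrm{CPP}_j = \mathrm{ABF}_j / \sum_k \mathrm{ABF}_k$. This is the
standard single-causal equivalence; it diverges from CAVIAR only in
not modeling the LD of the non-causal configuration, which the c = 1
restriction makes irrelevant. The default prior variance is
$W = 0.04$ (effect SD 0.2 on a standardized phenotype; the same value
is used on the log-odds scale for case–control GWAS). The 95% credible
set is the smallest CPP-descending prefix reaching 0.95, with CPP ties
broken by genomic position for determinism. Credible-set coverage is
validated by simulation: with correctly specified LD and lead
non-centrality 6 over 1000 loci of 100 variants (block LD ρ = 0.9),
the planted causal falls inside the set in about 98–99% of loci.

Conditional analysis follows the summary-statistic formula
$z_{j|C} = (z_j - R_{jC} R_{CC}^{-1} z_C) / \sqrt{1 - R_{jC} R_{CC}^{-1} R_{Cj}}$,
with a ridge of 1e-6 on $R_{CC}$ when singular and a collinearity flag
for denominators below 0.05.

## Colocalization

Per-variant Wakefield log ABFs for the two traits are combined in log
space into the five single-causal hypotheses (none / trait 1 only /
trait 2 only / two distinct variants / one shared variant) with fixed
per-variant priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. The
reference tool the study used estimates its priors genome-wide by
empirical Bayes; fixed coloc-style priors were chosen here because the
synthetic cohorts contain too few loci for a stable genome-wide
estimate, and the report records which mode produced each posterior.
H3's sum over ordered pairs of distinct variants is computed stably as
$\log(e^{S_1 + S_2} - e^{S_{12}})$ with log-sum-exp terms. Eligibility
follows the study's gating: a signal is tested only when a GWAS
credible-set variant with CPP ≥ 0.01 is in LD (r² ≥ 0.6) with a lead
QTL, with a fallback (any variant at GWAS p ≤ 5e-5 in such LD) when
credible sets are unavailable. The testing region is the 1 Mb window
centered on the GWAS lead; the stated variant-inclusion clause is
ambiguous between a filter and a requirement and is implemented as a
requirement — the region must contain at least one variant at
p ≤ 5e-5, and all shared region variants enter the computation (the
hard-filter reading is available by flag). A locus colocalizes when the
shared-variant posterior is at least 0.8. ABF prior SDs default to 0.15
for quantitative traits and 0.2 for case–control.

## TWAS

Cis prediction weights are fitted on covariate-residualized phenotypes
with three candidate models: `top1` (all weight on the best marginal
variant), ridge with the penalty chosen by generalized cross-validation,
and lasso (glmnet, penalty at the CV minimum chosen on an independent
fold split so the scoring folds stay honest). Of the five FUSION
models, blup is statistically equivalent to ridge here and bslmm
requires MCMC; both are omitted and the winner among the three is the
highest k-fold cross-validated R², replacing FUSION's
profile-likelihood heritability test with the same intent. Features
with cv R² ≤ 0.01 are excluded as non-heritable; on pure-noise
phenotypes the null cv R² distribution puts roughly a tenth of its mass
above that gate at 20-variant windows, so the exclusion rate is about
90%. The association statistic is
$z_{\mathrm{TWAS}} = w^\top z / \sqrt{w^\top R w}$ with the LD matrix
$R$ from the same genotype panel used for training, Bonferroni
correction over tested features, a colocalization gate (shared-variant
PP ≥ 0.6) and known/novel locus classification (r² ≥ 0.1 with, or
< 500 kb from, a known lead). The study's Bonferroni denominators
(5804 junctions, 2851 genes) count features passing FUSION's
heritability check; the analogous count here is features passing the cv
R² gate, a mapping that is documented rather than asserted identical.

## The synthetic-data generator

The generator exists so that every downstream claim can be checked
against planted, recorded truth; its defaults are the study conditions
the tests run under.

* **Genotypes**: haplotype alleles within an LD block follow a
  first-order Markov chain with stationary frequency equal to the
  block's allele frequency (drawn from MAF 0.1–0.5) and correlation
  ρ = 0.9 between adjacent markers; dosages are sums of two independent
  haplotypes, so adjacent-marker dosage correlation is also ρ and r²
  analytically ρ². Blocks of 20 variants at 1 kb spacing are
  independent; 300 samples by default, matching a realistically sized
  eQTL cohort.
* **Splicing**: cluster totals are negative binomial (mean 60, size
  10 — overdispersion typical of junction counts) and junction counts
  are multinomial with proportions softmax(base logits + β·dosage +
  batch offset). The softmax-logit parameterization gives a clean
  planted PSI shift with multinomial noise. Junction boundaries sit on
  the variant grid so splice-site annotation windows can contain
  genotyped variants — the configuration of scientific interest.
* **Expression**: Gaussian log2 expression with an additive dosage
  effect in residual-SD units, per-batch offsets, two-fold library-size
  variation and Poisson counts at typical bulk depth (median hundreds
  of reads), deep enough that the planted log-scale effect survives
  quantification essentially undistorted.
* **GWAS**: z-scores from the standard summary-statistic model
  $z \sim N(R\lambda, R)$ with one nonzero entry
  $\sqrt{n}\,\beta$ at the causal variant; betas and standard errors
  are back-filled via $\mathrm{se} = 1/\sqrt{2f(1-f)n}$. This
  matches what fine-mapping and colocalization assume, deliberately
  isolating method correctness from model misspecification (a
  misspecified-LD variant is a config option).
* **Annotations**: splice-site (±8 bp), exon, intron, promoter and
  enhancer classes occupying mutually exclusive genic space, plus one
  blacklist and one MHC-analog interval per genome so the
  control-shuffle exclusion logic is exercised.

What the generator does not emulate — read-level alignment noise,
imputation uncertainty, population structure, relatedness, multi-causal
loci, isoform-level regulation — bounds what passing tests show:
correctness and calibration of the statistical machinery under its
stated assumptions, not robustness to every artifact of real data.

## Problem sizes

The test suite runs the full discovery procedure at the study scale for
the calibration checks (1000 features × 1000 permutations × 300
samples; 1000 fine-mapped loci) and a compact end-to-end demonstration
(250 samples, 24 clusters, 24 genes, 200 permutations, 6 GWAS loci
split shared/linked/distinct), sizes chosen so a complete run is
comfortable on a laptop while keeping every planted-truth check
well-powered.

## Known limitations

Single-causal fine-mapping cannot represent allelic series; the
conditional-z machinery is provided for two-signal loci but is not fed
back into colocalization. The q-value π0 estimate with a fixed λ is
slightly conservative when the alternative fraction is large. The
effector table nominates features by the union of two gated routes and
inherits both routes' thresholds; its false-nomination count on
synthetic truth is reported by the pipeline rather than bounded a
priori.
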