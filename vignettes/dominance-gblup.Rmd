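---
title: "Genomic evaluation with additive and dominance effects: models and methods"
author: "gblupd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation with additive and dominance effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupd)
```

## The problem

Routine dairy genetic evaluations rank animals on additive breeding values
(BV) and ignore dominance, the within-locus interaction between the two
alleles an animal carries. Dominance deviations (DV) are not transmitted to
offspring on average, but they do contribute to an animal's **own**
performance: for decisions about the cow herself — culling, mate allocation,
predicting her next lactation — the total genetic value TGV = BV + DV is the
more relevant quantity. With dense SNP genotypes the dominance relationship
between animals can be computed directly from markers, making
animal-level dominance estimable even in populations (like dairy cattle)
with almost no full-sib families.

`gblupd` implements the complete analysis chain for this question on
repeated-record traits: genomic relationship matrices, REML variance
components, genetic-value prediction, a boundary-corrected model-comparison
test, genomic inbreeding, and a family-aware cross-validation of predictive
ability — plus a half-sib population simulator with known truth, so every
step can be verified on data where the right answer is known.

## Models

For a vector $\mathbf{y}$ of (pre-adjusted) repeated records the two
competing models are

$$\textbf{A:}\quad \mathbf{y} = \mathbf{1}\mu + \mathbf{W u} +
\mathbf{W pe} + \mathbf{e}$$

$$\textbf{A+D:}\quad \mathbf{y} = \mathbf{1}\mu + \mathbf{W u} +
\mathbf{W d} + \mathbf{W pe} + \mathbf{e}$$

with $\mathbf{W}$ the record-to-animal incidence matrix and independent
random effects

$$\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_a), \quad
\mathbf{d} \sim N(0, \mathbf{D}\sigma^2_d), \quad
\mathbf{pe} \sim N(0, \mathbf{I}\sigma^2_{pe}), \quad
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e).$$

The permanent-environmental term $\mathbf{pe}$ is an iid animal effect that
captures everything repeatable about an animal that is not captured by the
markers. It is essential here: with repeated records and no explicit
dominance term, the animal-level dominance signal is largely absorbed into
$\sigma^2_{pe}$, so omitting $\mathbf{pe}$ from a single-record analysis
inflates apparent dominance. The package keeps the term for animals with a
single record too (it is then confounded with the residual; the REML
estimator must remain — and is tested to remain — stable there).

$\mu$ is the only fixed effect. Real contemporary-group effects are assumed
removed upstream; `adjust_phenotypes()` provides the generic ordinary
least-squares pre-adjustment (fit records on covariates, keep residuals)
that mirrors that two-step practice.

## Relationship matrices and codings

With $p_i$ the frequency of the counted (A) allele at SNP $i$ and
$q_i = 1 - p_i$:

* additive codes $\mathbf{Z}$: $-2p_i$, $q_i - p_i$, $2q_i$ for aa, Aa, AA
  (equivalently $x - 2p_i$ for allele count $x$);
* dominance codes $\mathbf{M}$: $-2p_i^2$, $2p_iq_i$, $-2q_i^2$;
* $\mathbf{G} = \mathbf{ZZ}'/\sum_i 2p_iq_i$ and
  $\mathbf{D} = \mathbf{MM}'/\sum_i (2p_iq_i)^2$.

Under Hardy–Weinberg proportions the expectations of $z$, $m$ and $z\,m$
are all exactly zero for any $p$ (the tests assert this algebraically on a
grid of frequencies), which is what makes $\sigma^2_a$ and $\sigma^2_d$
unconfounded in this parameterization and puts both on the base-population
scale.

Numerical choices made here, each with a reason:

* **Allele frequencies** default to the observed frequencies over *all*
  supplied animals (training and validation together), because validation
  genotypes are deliberately kept inside $\mathbf{G}$/$\mathbf{D}$ during
  cross-validation. A frequency vector can be supplied to override this.
* **Monomorphic SNPs** are dropped from numerators, denominators and from
  the inbreeding average — any other choice divides by zero.
* **Exact centering is a property of G only.** Because the additive codes
  use estimated frequencies, column sums of $\mathbf{Z}$ — and hence row
  sums of $\mathbf{G}$ — are zero to machine precision. The dominance
  column sums instead measure the sample's deviation from Hardy–Weinberg
  proportions, so rows of $\mathbf{D}$ are centred only in expectation; the
  average off-diagonal of $\mathbf{D}$ shrinks as $1/n$. The test suite
  asserts the exact property for $\mathbf{G}$ and the decaying one for
  $\mathbf{D}$.
* Symmetry is enforced by averaging ($K \leftarrow (K + K')/2$) after the
  cross-product; a ridge of $10^{-8}\times$ the mean diagonal is applied
  only if a Cholesky factorization fails, and a message is emitted.

## Genomic inbreeding

Two per-animal measures: the proportion of homozygous SNPs, and the
inbreeding part of the genomic self-relationship

$$G_F = \frac{1}{N}\sum_i
\frac{x_i^2 - (1+2p_i)x_i + 2p_i^2}{2p_i(1-p_i)},$$

where $x_i$ counts the **most common** allele — a different convention from
the $\mathbf{Z}$/$\mathbf{M}$ codings, which count the designated A allele;
the two are deliberately decoupled. A fully heterozygous animal has
$G_F = -1$ at $p = 0.5$, a fully homozygous one $+1$, and when every SNP has
$p = 0.5$ the identity $\operatorname{diag}(\mathbf{G}) = 1 + G_F$ holds
exactly. Correlating estimated dominance deviations with either measure
quantifies inbreeding depression at the animal level: under directional
dominance, more-homozygous animals gain less from dominance.

## REML estimation

Variance components are estimated by restricted maximum likelihood. The
likelihood is evaluated on an exact orthogonal decomposition of the records:
within-animal contrasts ($n - q$ of them, iid with variance $\sigma^2_e$)
and the animal means
$\bar{\mathbf{y}} \sim N(\mathbf{1}\mu, \boldsymbol{\Sigma})$ with

$$\boldsymbol{\Sigma} = \sigma^2_a\mathbf{G} + \sigma^2_d\mathbf{D} +
\sigma^2_{pe}\mathbf{I} + \sigma^2_e\,\mathrm{diag}(1/n_i),$$

so every iteration factorizes a $q \times q$ matrix ($q$ = number of
phenotyped animals) regardless of how many records each animal has. This is
a factorization of the full likelihood, not an approximation; the tests
confirm equality with a dense record-level construction of
$\mathbf{V} = \mathbf{W K W}' + \mathbf{I}\sigma^2_e$ to $10^{-8}$.

The optimizer is the field's standard recipe:

* 5 EM iterations to warm up (monotone, safe far from the optimum), then
  average-information (AI) updates;
* Levenberg–Marquardt damping of the AI matrix (escalating
  $\lambda \in \{0, 0.1, 1, 10, 100\}$) with step-halving, and a monotone EM
  fallback — flat ridges in $(\sigma^2_d, \sigma^2_{pe})$ are common in
  half-sib data and undamped AI steps can stall on them;
* components stepping negative are floored at zero; a component resting on
  the boundary with a negative score is excluded from the step (KKT), and
  after 3 consecutive boundary iterations it is fixed there;
* convergence requires a relative log-likelihood change below $10^{-8}$ and
  a relative component change below $10^{-6}$, with a 200-iteration cap.

Standard errors are square roots of the diagonal of the inverse AI matrix
at the optimum. Components fixed at the zero boundary get `NA` in the
reported `se` (a boundary estimate has no symmetric sampling
interpretation); the full-curvature values, boundary components included,
are kept in `se_all` for diagnostics such as parameter-recovery checks.

**Identifiability caveat.** In paternal half-sib populations the dominance
relationship between half-sibs is near zero, so $\mathbf{D}$ is close to an
identity — exactly the covariance of $\mathbf{pe}$. Separating
$\sigma^2_d$ from $\sigma^2_{pe}$ then rests on the modest off-diagonal
structure of $\mathbf{D}$ and on repeated records, and $\hat\sigma^2_d$
frequently lands on the zero boundary at moderate sample sizes even when
true dominance exists. This is a property of the design, not of the
algorithm, and is why large datasets are needed for dominance in practice.

## Model comparison and derived ratios

Because $\sigma^2_d = 0$ lies on the boundary of the parameter space, the
likelihood-ratio statistic $2(\log L_{A+D} - \log L_A)$ is referred to the
50:50 mixture of $\chi^2_0$ and $\chi^2_1$:
$p = \tfrac12 \Pr(\chi^2_1 \ge \text{stat})$ for a positive statistic and
$p = 1$ at zero. The $\chi^2_1$ critical value at $P = 0.01$ therefore marks
the top 0.005 of the mixture null, making the conventional reading of the
test conservative. Simulation under $\sigma^2_d = 0$ (200 replicates in the
test suite) confirms the empirical size stays at or below the nominal 5%.

From fitted components the package derives $\sigma^2_p$ (sum of all
components), $h^2_a = \sigma^2_a/\sigma^2_p$,
$h^2_d = \sigma^2_d/\sigma^2_p$, the dominance share of genetic variance
$\sigma^2_d/(\sigma^2_a+\sigma^2_d)$, and the repeatability
$(\sigma^2_a+\sigma^2_d+\sigma^2_{pe})/\sigma^2_p$. No standard errors are
attached to these ratios (a delta-method SE would suggest more precision
than the boundary-prone components support); the study report carries them
as point values and `verify_report()` re-derives each one from the raw
components.

## Cross-validation design

Fivefold cross-validation with two family-aware constraints: whole paternal
half-sib families are confined to single folds (largest family first into
the currently smallest fold, seeded tie-break), and — when dam metadata
exists — dams are co-assigned with their daughters, so no validation animal
has a half-sib or a daughter in training. Genotypes of validation animals
stay in $\mathbf{G}$/$\mathbf{D}$; their phenotypes are excluded, and
variance components are re-estimated within every training set to avoid any
leakage through the estimates themselves.

Validation animals are compared on their per-animal mean adjusted
phenotype (the animal is the prediction unit; the aggregation of repeated
records is a package choice). Per fold and model the package computes
correlations of the phenotype with BV, DV and TGV, the regression slope of
phenotype on genetic value (1 is ideal; deviations indicate inflation or
shrinkage), and the MSE of prediction. Across folds: means, standard errors
($sd/\sqrt{k}$), paired two-sample t tests comparing the two models'
correlations and MSEs, and one-sample t tests of the slopes against 1 —
the classic paired-over-folds design with $k-1$ degrees of freedom.
Zero-variance differences are reported as $p = 1$ with a degenerate flag
rather than an error. Re-ranking among selection candidates is summarized
by Spearman correlations (midranks for ties) between model-A BV and
model-A+D TGV within the top 10/25/50/75/100% of animals ranked by BV; the
direction flag flips the ranking for traits where smaller is better (e.g.
calving interval).

## The simulator: what it emulates and what it does not

`sim_herd()` generates the study conditions end to end, all randomness
flowing from one seed (the caller's RNG state is never touched):

* minor allele frequencies uniform on [0.05, 0.5] by default;
* unrelated sires drawn at Hardy–Weinberg equilibrium; each daughter gets
  one gamete from her sire and one population gamete, giving the expected
  0.25 additive relationship within paternal half-sib families (dam
  genotypes are not materialized — population gametes suffice for that
  expectation, and the target populations have negligible full-sib
  content);
* Gaussian per-SNP effects with equal variance before rescaling, rescaled
  through the coding expectations so that $\sum 2p_iq_i a_i^2$ and
  $\sum (2p_iq_i)^2 d_i^2$ hit the additive and dominance variance targets
  exactly; a nonzero mean dominance effect makes dominance directional
  (inducing inbreeding depression), and the spread around that mean is
  rescaled by solving the implied quadratic so the variance target is still
  met;
* records $y = \mu + BV + DV + pe + e$ with $pe$ drawn once per animal and
  $e$ per record.

The default configuration — 20 sires × 50 daughters, 2000 SNPs, 2 records
per cow, components $(0.25, 0.05, 0.10, 0.60)$ so $\sigma^2_p = 1$ — is the
package's reference design for parameter-recovery testing: realistic
family sizes for AI-bred dairy populations and a dominance share of
phenotypic variance (5%) in the range reported for yield traits. The
simulator deliberately omits linkage disequilibrium, multi-generation
pedigrees, selection, genotyping error and imputation error. Passing tests
on simulated data therefore validate the estimator and the pipeline
machinery — not the behaviour of these methods under real LD structure,
historical selection, or imperfect genotypes.

Data-edit rules for real records ship as configuration
(`edit_rules()`): calving interval valid on [290, 550] days with values in
[551, 762] capped at 551; milk, fat and protein yields kept on
[2000, 15000] L, [50, 800] kg and [45, 600] kg.

## Problem sizes used in the shipped checks

The test suite exercises: dense-oracle equivalence at $n \le 30$ records;
parameter recovery at the reference design (1000 cows × 2 records, 2000
SNPs); null calibration of the mixture test over 200 replicates of 300 cows
× 500 SNPs; and a dominance-containing cross-validation at 1500 cows × 2000
SNPs with a 10% dominance share. These sizes were chosen so the full chain
(simulation through CV) demonstrates its statistical properties while a
complete run of the suite stays interactive on a single workstation core;
the collapsed likelihood makes each REML fit scale with the number of
animals, not records.

## Known limitations

* Single-trait, single fixed effect ($\mu$): multi-trait models and general
  fixed-effect structures are out of scope; pre-adjust phenotypes instead.
* The dominance parameterization is the genotypic-coding one above;
  alternative codings (e.g. classical/heterosis parameterizations) give
  different $\sigma^2_d$ estimates and are not offered.
* No epistasis, no SNP-effect back-solving, no sparse/approximate GRM
  algebra — matrices are dense, practical to a few thousand animals.
* Ratio estimates carry no standard errors (see above).
* The forward-in-time validation designs used for bulls (daughter yield
  deviations) are not implemented; the cross-validation here predicts cow
  phenotypes.
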