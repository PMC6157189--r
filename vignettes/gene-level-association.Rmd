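---
title: "Adaptive gene-level association testing in pedigrees: models and methods"
author: "pedaSPU authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive gene-level association testing in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedaSPU)
```

## The problem

Genome-wide association studies on family cohorts measure a quantitative
trait on related individuals, so single-SNP and gene-level tests must account
for the covariance that relatedness induces. pedaSPU tests each gene — a set
of p SNPs — for association with the trait under a linear mixed model (LMM),
combining the per-SNP evidence adaptively so that power does not hinge on
guessing in advance whether many SNPs carry small, same-direction effects or
one SNP carries most of the signal.

## The model

For individual $i$ with covariates $X_i$ (intercept, and by default a
sex-like and an age-like covariate) and gene dosages $G_i$:

$$y_i = X_i\alpha + G_i\beta + b_i + \varepsilon_i, \qquad
  b \sim N(0, \tau\Psi), \quad \varepsilon \sim N(0, \phi I),$$

where $\Psi$ is the $n\times n$ genetic relationship matrix on the
correlation scale (unit diagonal, $\approx 0.5$ for full sibs and
parent–offspring, $\approx 0$ for unrelated pairs). The null hypothesis per
gene is $H_0:\beta = 0$.

$\Psi$ is either supplied (`loadKinship()`) or estimated by
`estimateKinship()` as the Pearson correlation between two subjects' dosage
profiles over a seeded random subset of SNPs (default 20,000), after
centering each SNP at its sample mean. The centering matters: the spread of
allele frequencies across SNPs is a profile component shared by all
subjects, and correlating raw dosages inflates even unrelated pairs to
around 0.15 under typical MAF distributions, whereas the centered estimator
puts full sibs near 0.5 and unrelated pairs near 0 as the model intends. A
fully standardized GRM is available via `method = "grm"`; the diagonal is
pinned to 1 in both cases. The estimate is passed
through `makePSD()` (eigenvalue clipping at $10^{-8}$) so that
$\tau\Psi + \phi I$ is always invertible for $\tau \ge 0$.

## Null-model fitting

All tests derive from one covariates-only fit, $y = X\alpha + b +
\varepsilon$ (`fitNull()`). For Gaussian traits, penalized quasi-likelihood
coincides with the ordinary likelihood, so we maximize ML (default) or REML
directly rather than iterating a quasi-likelihood scheme. Eigendecomposing
$\Psi = Q D Q'$ reduces the problem to one dimension: at each variance ratio
$\lambda = \tau/\phi$ the GLS coefficients and the profiled $\phi$ are closed
form, and the profile likelihood is maximized over a $\log_{10}$ grid on
$\lambda \in \{0\} \cup [10^{-6}, 10^{6}]$ (quarter-decade steps) followed by
golden-section refinement to tolerance $10^{-9}$ on $\log_{10}\lambda$. The
boundary $\hat\tau = 0$ is admissible and flagged, not an error; with
$\Psi = I$ the components are unidentifiable and the tie-break keeps
$\hat\tau = 0$, making the fit collapse exactly to OLS (ML scaling). A
near-perfect fit ($\hat\phi$ at its floor) raises a `degenerate` flag.

The score machinery uses the working residual
$\hat\Sigma^{-1}(y - X\hat\alpha)$, which equals
$(y - X\hat\alpha - \hat b)/\hat\phi$; `nullResidualCheck()` verifies this
identity and the orthogonality $X'\hat\Sigma^{-1}(y - X\hat\alpha) = 0$ by
explicit dense computation — the property that makes the scores mean-zero
under the null.

## Scores and the SPU family

For a gene with dosage block $G$,

$$U = G'\hat\Sigma^{-1}(y - X\hat\alpha), \qquad
  V = G'PG, \quad
  P = \hat\Sigma^{-1} - \hat\Sigma^{-1}X(X'\hat\Sigma^{-1}X)^{-1}
      X'\hat\Sigma^{-1},$$

so $V$ accounts for estimation of $\alpha$; $(\hat\tau,\hat\phi)$ are held
fixed at their null estimates, the standard practice for mixed-model score
tests. Genotypes enter unstandardized and unweighted — this is a
common-variant method (the default filters keep MAF > 0.05, strictly) and no
MAF weighting is applied.

The sum-of-powered-score statistics are
$T_{SPU(\gamma)} = \sum_j U_j^\gamma$ (signed for odd $\gamma$) and
$T_{SPU(\infty)} = \max_j |U_j|$, over the conventional set
$\gamma \in \{1,\dots,8,\infty\}$. $\gamma = 1$ is the burden test,
$\gamma = 2$ the sum of squared scores (equivalently SKAT with the linear
kernel), and $\gamma = \infty$ matches UminP when the score variances are
equal — `equivalenceSuite()` checks all three against their analytic forms,
skipping the UminP comparison (reported `not-applicable`) whenever
`diag(V)` is not constant, since the equality only holds then. The
$SPU(\infty)$ statistic uses raw $|U_j|$; a variance-standardized variant is
deliberately not the default so the statistic matches its printed definition.

`aspuTest()` computes Monte-Carlo p-values from $B$ draws
$U^{(b)} \sim N(0, V)$ through an eigendecomposition square root (tolerant of
rank-deficient $V$, unlike Cholesky): $p_\gamma = (\#\{|T^{(b)}| \ge
|T_{obs}|\} + 1)/(B+1)$, ties counted (conservative), two-sided via $|\cdot|$
for every $\gamma$ (a no-op for even $\gamma$ and $\infty$). The adaptive
statistic is $\min_\gamma p_\gamma$, and its p-value reuses the same draws:
each draw's $p_\gamma^{(b)}$ is its leave-one-out rank among the other
$B - 1$ draws, and $p_{aSPU} = (\#\{\min_\gamma p^{(b)} \le \min_\gamma
p_\gamma\} + 1)/(B+1)$. The estimator $(\text{count}+1)/(B+1)$ keeps every
p-value in $[1/(B+1), 1]$, so a scan-level default of $B = 1000$ is paired
with an escalation rule: any gene with $p_{aSPU} < 5/B$ is retested at
$10\times B$ up to a cap (default $10^5$), so near-significant genes get
resolvable p-values without paying the large-$B$ cost genome-wide. Both the
leave-one-out ranking and the escalation rule are configuration, not
hard-wired.

The SPU(2)/SKAT analytic reference — the tail of
$\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of $V$ — is
computed in-package by Imhof's characteristic-function inversion
(`chisqMixturePvalue()`, adaptive quadrature), verified against the
chi-square special cases.

## The scan

`runScan()` fits the null model once — instrumented by `nullFitCount()` so
the single-fit contract is testable — then per gene: window assignment,
scores, aSPU, multivariate score test. Gene windows are
$[\mathrm{start} - 10{,}000,\ \mathrm{end} + 10{,}000]$ base pairs, both ends
inclusive (the boundary convention is ours; annotations state only a flank
width). Genes may overlap and share SNPs; they are tested independently with
no LD-aware deduplication. The Bonferroni threshold divides $\alpha$ by the
number of genes actually tested (those with $\ge 1$ SNP after filtering and
without numerical failure), not the annotation's row count. Per-gene seeds
derive from the master seed and a stable hash of the gene id, which makes
results invariant to gene order and lets any gene be reproduced standalone.
Coordinates are taken on whatever genome build the user's annotation uses;
BED input (0-based half-open) is converted to 1-based inclusive internally
and the convention is always named explicitly, never guessed.

## Genotype handling

`readGenotypes()` reads PLINK bed/bim/fam (SNP-major v1.00, hand-decoded
2-bit codec, since the round-trip with `writePlink()` is part of the test
surface) and VCF 4.x through vcfR. Dosages always count the minor allele,
re-oriented per SNP, so burden-test signs are comparable across SNPs.
Filters are strict on both sides — MAF > 0.05 and missingness < 1% — and
SNPs failing the missingness rule are dropped entirely; survivors have
sporadic missing calls imputed as independent Binomial(2, MAF) draws, the
Hardy–Weinberg-consistent and mean-preserving choice, deterministic given a
seed. Multiallelic sites are rejected unless `multiallelic = "drop"`;
half-missing or non-diploid calls are format errors naming the record and
sample.

## The simulator, and what passing tests show

`simulateGenotypes()` draws founder haplotypes under Hardy–Weinberg at MAFs
uniform on [0.05, 0.5] and transmits one uniformly chosen allele per parent
per SNP (sib-pair, nuclear, and three-generation structures). It returns the
pedigree-theoretic relationship matrix on the correlation scale alongside
the genotypes, computed by the tabular method, so kinship estimation has an
exact target. `simulateTrait()` generates $y = X\alpha + G\beta + b +
\varepsilon$ exactly as the model states.

Deliberate simplifications: SNPs are independent given the pedigree (no LD
and no recombination map), there is no population admixture beyond family
structure, and traits are exactly Gaussian. Passing tests therefore
demonstrate correctness of the algorithms under the model's own assumptions
— calibrated type-I error, the documented equivalences, parameter and
kinship recovery — not robustness to LD between neighbouring SNPs, trait
non-normality, or cryptic population structure, which real cohorts exhibit.

## Problem sizes and calibration of the validation suite

The statistical checks run at: 1,000 null replicates (100 sib-pair families,
$n = 200$, a 10-SNP gene, $\tau = \phi = 1$, $B = 1000$) for type-I error of
aSPU and the score test against the binomial 95% band at $\alpha = 0.05$;
500 replicates per power scenario; 200 replicates at $n = 500$, true
$\tau = 2$, for variance-component recovery; 5,000 SNPs for kinship
recovery. The two power scenarios fix their effect sizes a priori by an
analytic score-based calculation (the score mean under alternatives is
$V\beta$, giving the burden test's noncentrality in closed form and the
max-component test's power by multivariate-normal simulation): all ten SNPs
at $\beta = 0.15$ for the dense architecture, one SNP at $\beta = 0.8$ for
the sparse one — each sized for roughly 80% power of the favourable member
at $\alpha = 0.05$. These sizes keep the complete suite comfortably on one
CPU while leaving the binomial bands meaningful.

## Numerical choices and degenerate inputs

* Eigenvalue floors: $10^{-8}$ for PSD repair of $\Psi$; $10^{-10}$ of the
  top eigenvalue for the score-test pseudoinverse; $10^{-12}$ relative for
  declaring a SNP monomorphic (reported `NA` with a reason, never an abort).
* A gene whose $V$ has numerical rank 0 raises a classed
  `pedaSPU_undefined_test` condition; the scan catches it and reports the
  gene as missing.
* An empty post-filter SNP set is signalled by a classed warning, not an
  error, so pipelines skip cleanly.
* Ties between null draws and the observed statistic count toward
  exceedance (conservative p-values).
* All Monte-Carlo routines take explicit seeds and restore the caller's RNG
  state, so library calls never perturb a session's random stream.

## Known limitations

Single kinship random intercept only (no additional variance components, no
GxE), Gaussian traits only (no binary-trait GLMM), common variants without
MAF weighting, no negative/fractional $\gamma$ and no weighted aSPU variant,
no LD pruning or conditional analysis. Pedigree-expected kinship from `fam`
structure alone is out of scope — $\Psi$ comes from genotypes or from a file.
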