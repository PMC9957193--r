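---
title: "Methods: multi-kernel hybrid prediction with parental covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-kernel hybrid prediction with parental covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcov)
```

## The statistical model

The package fits Gaussian multi-kernel mixed models of the form

$$ y = X\beta + \sum_k u_k + \varepsilon, \qquad
   u_k \sim N(0, \sigma_k^2 K_k), \qquad
   \varepsilon \sim N(0, \sigma_\varepsilon^2 I), $$

where each $K_k$ is a records-by-records covariance kernel. For hybrid
prediction the kernels are built from a two-pool crossing design:
parental genomic relationship matrices $G_M = W_M W_M'/p$ and
$G_F = W_F W_F'/p$ (columns of $W$ centered and standardized), the
specific-combining-ability kernel
$H[i,j] = G_M[m_i, m_j]\,G_F[f_i, f_j]$ — the observed-cross sub-matrix
of the Kronecker product $G_M \otimes G_F$, never materialised in
full — and Hadamard products of genetic kernels with the environment
block kernel $Z_E Z_E'$ for genotype-by-environment interaction. Model
families A/C replace every genomic kernel by an identity over the same
entities, so one fitting engine serves all twelve models.

Key modelling assumptions: phenotypes are adjusted means (BLUEs) per
hybrid and environment, so records carry a single residual level; the
two parental pools are distinct heterotic groups, making male and
female GCA separate effects; traits are analysed one at a time, with
cross-trait information entering only through the parental covariates.

Environment main effects are treated as a *random* term with its own
variance $\sigma_E^2$, matching the distributional statement
$\beta_E \sim N(0, \sigma_E^2 I)$ of the model family; only the
intercept and the parental covariates are genuinely fixed (flat prior).
With three to a handful of environments a fixed-effect treatment would
differ little; the random treatment keeps every term in the same
sampler code path.

## Parental covariates

For each trait $t$, the mid-parent additive covariate is
$(P_{M,t} + P_{F,t})/2$ and the dominance covariate is
$|P_{M,t} - P_{F,t}|/2$. The source description of the dominance column
is ambiguous (it prints the same expression as the additive column
inside an absolute value); we default to the half absolute *difference*,
which is the standard mid-parent/heterosis construction — a parent pair
with identical values shows no dominance signal — and expose the
literal half absolute *sum* behind `dominance = "half_abs_sum"`. Both
are tested.

Covariate columns are centered but not scaled: centering lets the
intercept absorb their mean, and scaling is immaterial because the
coefficients carry a flat prior. Whether the original analysis centered
its covariates is unstated; centering-only is this package's documented
choice.

## The Gibbs sampler

Each kernel is eigendecomposed once, $K_k = U_k D_k U_k'$, truncating
eigenvalues below $10^{-10}$ times the largest (rank-deficient kernels
such as identity expansions and Hadamard products are the norm, not the
exception). Because the retained eigenvector blocks are orthonormal,
every full conditional of the transformed coefficients is diagonal, so
one iteration costs two matrix-vector products per term. Variance
components get scaled-inverse-chi-square priors with 5 degrees of
freedom and scales chosen so the prior mode splits half the observed
response variance equally across the random terms, the other half going
to the residual — the standard default of Bayesian ridge/RKHS software.
The fixed-effect block uses a flat prior with a $10^{-8}$ relative
ridge on $X'X$ so that degenerate columns (e.g. an all-zero dominance
column after centering) cannot break the Cholesky factor.

Masked records are treated as missing data: each iteration imputes them
from $N(\hat y_i, \sigma_\varepsilon^2)$, which is exactly how
cross-validation predictions are produced. The reported prediction is
the running posterior mean of the *conditional mean* $\hat y_i$ (the
Rao–Blackwellised version of averaging the noisy imputed draws): it has
the same expectation and a much smaller Monte-Carlo error. All
randomness flows through R's RNG, so a seed makes a fit reproducible
bit-for-bit; the sampler aborts with a diagnostic if a variance draw
becomes non-finite.

Defaults are 12,000 iterations, 2,000 burn-in, thinning 5 — deliberately
conservative for a single fit. The iteration counts BGLR-style software
was actually run with in the motivating study are not stated anywhere;
ours are package defaults, not a claim about the original analysis.

A closed-form check accompanies the sampler: `blup_oracle()` solves the
mixed model exactly for *known* variance components via
$V = \sum_k \sigma_k^2 K_k + \sigma_\varepsilon^2 I$ (with a $10^{-8}$
relative diagonal jitter against singularity), GLS for $\beta$, and
kernel extrapolation for held-out records. With the sampler's variances
fixed at the same values, its posterior-mean predictions must converge
to the oracle's — one of the package's acceptance-level tests.

One ambiguity in the source model statements deserves a note: the
non-genomic families are written with an identity kernel for the SCA
main effect but a *genomic* $H$ inside the SCA-by-environment
interaction. We read that as a typographical slip and use identity
kernels for every non-genomic term; `literal_uH = TRUE` in
`assemble_terms()` reproduces the literal reading.

## Cross-validation and model comparison

`make_folds()` shuffles hybrids under a seed and assigns them
round-robin, so fold sizes differ by at most one; all records of a
hybrid share its fold, which is what makes held-out lines "untested"
while every environment stays "tested". `compare_models()` reuses one
fold assignment (and one set of kernel eigendecompositions per family)
across all covariate modes, giving a paired comparison; reports carry a
hash of the fold assignment so pairing can be asserted.

"The average of the folds" can mean two things; we report both: the
record-pooled MSE (each test record weighted equally — the default used
in the relative-efficiency tables) and the unweighted mean of per-fold
MSEs. "Global" means pooled over all environments' test records.
Relative efficiencies are `RE = MSE_reference / MSE_candidate`, shown
to 3 decimals with percent gains `(RE − 1)·100` to 1 decimal.

## The synthetic data generator

`simulate_hybrid_data()` emulates the structure of a multi-year hybrid
wheat trial, scaled down roughly tenfold: 6 males × 40 females, 300
markers, three environments with 70/65/120 hybrid records and about a
third of each year's hybrids carried over from the previous year, three
traits with genetic correlation 0.5. Parents are fully homozygous
inbreds (dosage $2\cdot\mathrm{Bernoulli}(q)$, $q \sim U(0.1, 0.9)$; a
heterozygous option exists). Default variance components
($\sigma_E^2 = 2$, GCA $0.4 + 0.4$, SCA $0.2$, interactions
$0.05/0.05/0.1$, residual $1$) give a per-record heritability near
0.45 with GCA dominating SCA, as in elite line crosses. Parental
phenotypes are each parent's own additive value plus noise of variance
0.1 (reliability ≈ 0.8, plausible for replicated-trial BLUEs) — this is
the single knob that makes mid-parent covariates informative, and it is
the generator's point: SCA and interaction effects are drawn from the
model's *own* kernels (Cholesky factors of $H$ and the Hadamard
kernels), so parameter recovery by the sampler is a well-posed
question, and an additive-only limit exists in which mid-parent
covariates are perfect predictors.

What the generator does **not** emulate: linkage disequilibrium and
genetic maps, selection and drift, dominance/epistasis at the marker
level, heterosis physiology, and real phenotype error structure.
Passing tests on synthetic data therefore demonstrate internal
consistency of the machinery and directional behaviour of the model
comparisons — not field-data effect sizes.

## Validation problem sizes

The shipped checks run at sizes chosen to exercise every code path
while staying desk-sized: kernel oracles on ≥ 50 randomized instances
(≤ 10 parents per pool); sampler-vs-oracle agreement at n = 40 with
10,000 iterations; heritability recovery at n = 400 (three seeds);
and the directional covariate study on ten replicates of the default
generator conditions with 7-fold CV for families A and C at 1,200
iterations per fit. The short chains in the CV study are an analysis
choice: the comparison is paired, and chain noise affects both arms of
every relative efficiency equally; single-model fits keep the
conservative 12,000-iteration default.

## Known limitations

* Gaussian responses only; no BayesB/LASSO-type marker priors, and no
  joint multi-trait likelihood (correlated traits contribute only
  through covariates).
* The sampler's Monte-Carlo standard errors ignore autocorrelation;
  they are indicative, not inferential.
* Kernels are not rescaled beyond the `/p` of the GRM (no division by
  the mean diagonal); variance components are therefore on the scale of
  the kernels as built.
* Fold construction is a plain seeded partition; no stratification by
  the overlap structure between years.
* The VCF importer handles biallelic GT records only — multiallelic
  records are counted and skipped.
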