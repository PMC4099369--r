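---
title: "Binned similarity regression for heritability: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned similarity regression for heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsreg)
```

## The estimation problem

Narrow-sense heritability is the fraction of phenotypic variance
attributable to additive genetic effects,
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$. With genome-wide markers,
the standard route is the single-kernel linear mixed model
$y = \mu 1 + a + e$, $a \sim N(0, \Theta\sigma^2_a)$,
$e \sim N(0, I\sigma^2_e)$, where $\Theta$ is the genomic relationship
matrix (GRM), fitted by REML. REML scales poorly: the covariance matrix is
$n \times n$, and fitting requires repeated factorizations.

`sdsreg` implements a moment alternative built on a classical observation:
under the purely additive model with no shared environment, the phenotypic
covariance of a pair of individuals equals $\theta_{ij}\sigma^2_a$. Two
pairwise indexes expose this:

* **Covariance form** (`model = "sds2"`). The centered cross-product
  $s_{ij} = (y_i - \bar y)(y_j - \bar y)$ has expectation (up to a
  centering term of order $1/n$) $\theta_{ij}\sigma^2_a$, so the ordinary
  least-squares slope of $s_{ij}$ on $\hat\theta_{ij}$ estimates
  $\sigma^2_a$, and the slope of $s_{ij}/\hat\sigma^2_p$ estimates $h^2$
  directly.
* **Difference form** (`model = "sds1"`). The half squared difference
  $d_{ij} = (y_i - y_j)^2/2$ satisfies
  $E[d_{ij}] = \sigma^2_p - \theta_{ij}\sigma^2_a$: intercept
  $\sigma^2_p$, slope $-\sigma^2_a$, and $\hat h^2 = -\beta/\alpha$. Some
  authors work with the raw squared difference; the `double_diff` flag
  reproduces that convention (intercept $2\sigma^2_p$, slope
  $-2\sigma^2_a$; the reported variance fields are rescaled back).

The two forms are algebraically two views of the same decomposition; on any
sample they satisfy the exact identity
`mean(d) + mean(s) = S^2 (n-1)/n`. Their finite-sample fits differ, which
is why both are exposed and cross-checked in the test suite rather than
collapsed into one.

Regressing over all $n(n-1)/2$ pairs (Ritland's procedure, `ritland()`)
costs quadratic memory. The scalable estimator instead partitions the
relatedness axis into `n_bins` equal-width bins, averages the index within
each bin, and regresses bin means on bin means: residual noise averages out
within bins, and the regression always runs over at most `n_bins` points
regardless of $n$.

## Tunable parameters

* `n_bins` (default **1000**, dimensionless): the number of equal-width
  relatedness bins. The default follows the convention of the published analyses this
  package reproduces; with $10^5$–$10^9$ pairs, occupancy
  per bin is ample and results are insensitive to moderate changes.
* `range_mode` (default **"data"**): bins span the observed relatedness
  range. Marker-estimated GRMs contain negative values and values above 1,
  so the data-driven range loses no pairs. `"unit"` spans $[0, 1]$ with
  out-of-range values clipped into the end bins, matching the common
  description of relatedness as ranging 0–1; replicated comparisons during
  development showed the two modes agree within Monte-Carlo noise on the
  simulation designs below.
* Free intercept: the covariance-form regression keeps its intercept
  ($\alpha$) rather than forcing it through the origin. Theory says
  $\alpha = 0$ when no pairs share environment; the fitted intercept is
  reported as a diagnostic of that assumption (`summary()` prints it).
* Unweighted bin fit: a count-weighted (WLS) fit was considered and
  rejected. The relatedness distribution of a large sample is strongly
  skewed toward zero, so count weights concentrate nearly all weight in
  the near-zero bins and collapse the fit back to the un-binned
  regression; the informative signal lives in the sparse high-relatedness
  tail.
* No clamping: $\hat h^2$ from the similarity regression may be negative
  or exceed 1 and is reported as is. Truncation before averaging over
  replicates or bootstrap resamples would bias summaries; the REML
  baseline, by contrast, is constrained to $[0, 1]$ by its
  parameterization, which is the behaviour likelihood software exhibits.

## The REML baseline

`greml()` fits the same mixed model by restricted maximum likelihood using
one spectral decomposition $\Theta = U\Lambda U'$: in the rotated basis the
covariance is diagonal in the ratio $h^2$, the intercept and total variance
profile out in closed form, and a bounded scalar optimization (tolerance
`1e-8` on $h^2$) finds the optimum. For a single GRM this has the same
optimum as the AI-REML iterations used by mainstream tools, without the
iteration schedule; only the intercept is fitted as a fixed effect because
every experiment in scope has $\mu$ as its only fixed effect. Eigenvalues
below `1e-8` are clipped (marker GRMs with $m < n$ are rank deficient by
construction; the fit warns once, with a condition class tests can catch).
When all eigenvalues are equal — $\Theta \propto I$ — the likelihood
identifies only $\sigma^2_a + \sigma^2_e$; the fit flags
`identifiable = FALSE` and returns `NA` components rather than an arbitrary
split. `greml_direct()` re-maximizes the explicit dense-covariance
likelihood over a grid with local refinement; it exists to validate the
spectral path (the suite requires agreement to $10^{-6}$ on $n = 30$
fixtures and likelihood-value agreement at random parameter points to
$10^{-8}$).

## What the simulator emulates

`sim_ar1_population()` generates the calibration populations used in the
reproduction study:

* **Relatedness**: individuals ordered by descent with genetic correlation
  $\theta_a^{|i-j|}$ (default $\theta_a = 0.95$), produced by the
  stationary recursion
  $z_i = \theta_a z_{i-1} + \sqrt{1-\theta_a^2}\,\varepsilon_i$ on a
  latent Gaussian. This is the unique linear recursion with standard-normal
  marginals and nearest-neighbour correlation $\theta_a$. One sample thus
  contains the full relatedness spectrum, from near-clones to effectively
  unrelated pairs — a caricature of elite crop-breeding panels, not of
  human cohorts.
* **Genotypes**: the latent values are cut at the standard-normal quartiles
  $\pm 0.67449$, coding 0/1/2 with 1:2:1 proportions at every locus.
  Boundary values (measure zero) map upward. Markers are independent: no
  linkage disequilibrium.
* **Trait**: `causal_fraction` (default 0.10) of the markers are causal,
  drawn uniformly without replacement. Effects $u \sim N(0, I)$ act
  through the standardized causal genotypes,
  $a = \sqrt{h^2}\,W_c u/\sqrt{m_c}$, and $e \sim N(0, (1-h^2)I)$, so
  $\sigma^2_p = 1$ and $\sigma^2_a = h^2$ *in expectation*. The default
  deliberately does **not** rescale $a$ to hit $h^2$ exactly per
  replicate: genetic sampling variation is the quantity the realized
  heritability `var(a)/(var(a)+var(e))` is designed to gauge, and under
  strong relatedness the sample variance of `a` sits systematically below
  $\sigma^2_a$ (about 8% low at $n = 500$, $\theta_a = 0.95$), which is
  visible in realized means falling slightly below the nominal $h^2$ in
  small samples. `rescale = TRUE` switches to exact per-replicate scaling
  for users who want the genetic variance pinned.
* **Estimation GRM**: built from *all* markers, causal and irrelevant
  alike, as an analyst without oracle knowledge would.

What passing the simulation tests does **not** show about real data: no
LD, no MAF spectrum (allele frequencies concentrate near 1/2 by
construction), no genotyping error or missingness, no shared environment,
no dominance or epistasis, and a relatedness structure far denser than
outbred populations provide. The simulator validates the estimator's
statistical mechanics, not its robustness to real-data pathologies.

With only $m_c = m/10$ causal markers, the genetic variance has roughly
$m_c$ effective degrees of freedom, so at low marker density (e.g.
$m = 200$, $m_c = 20$) realized heritability disperses widely across
replicates and its mean drops a further 1–2 points below the attenuated
expectation (the variance ratio is concave in `var(a)`). This is a real
property of the sparse-causal design, worth keeping in mind when comparing
replicate summaries across marker densities.

## Numerical choices

* Binning uses half-open intervals $[e_k, e_{k+1})$ with the final bin
  closed: interior edge ties go upward and the global maximum stays in the
  last bin. Empty bins are dropped from the regression (their count is
  visible in `n_bins_used`).
* The binned and un-binned fits use the closed-form two-coefficient OLS
  solution; the suite checks it against `lm()` to $10^{-12}$ and verifies
  that an exactly affine index recovers the true slope under every binning.
* $\hat\sigma^2_p$ is the divisor-$(n-1)$ sample variance. The covariance
  form computes $\hat h^2$ both as slope$/\hat\sigma^2_p$ and as the slope
  of the standardized index, and errors if they disagree beyond $10^{-10}$
  (they are equal by linearity; the check guards the implementation).
* GRMs are symmetrized by averaging with their transpose to remove
  floating-point asymmetry; monomorphic markers are dropped with a warning
  before standardization (mean-imputation would silently shrink
  relatedness).
* The delete-duplicate bootstrap (`sds_boot()`) draws $n$ individuals with
  replacement and drops duplicates before re-estimating, so resampled GRMs
  stay non-singular for the REML path; trait centering is redone inside
  every resample. Resamples whose estimator fails are skipped with a
  warning; more than 50% failures abort.
* All replicated studies derive per-replicate seeds from one master seed,
  so whole studies are bit-reproducible.

## Problem sizes used in the shipped checks

The reproduction suite runs the smaller published cells at full replicate
count — 100 replicates at $(h^2, n, m)$ = (0.2, 500, 200), (0.8, 500,
2000), (0.5, 1000, 2000), the realized-heritability cell (0.5, 5000, 200),
single-population relatedness checks up to $n = 10000$ at $m = 200$ and
$n = 5000$ at $m = 2000$, and high-density checks at $m = 20000$ for
$n \le 2000$. The published $n = 50000$ run is cluster-scale (reported at hours per
replicate set); the $n = 5000$ cells stand in
for large-$n$ behaviour at desk scale, and the suite verifies the
qualitative signature (estimator SD shrinking with $n$) alongside the
quantitative cells.

## Known limitations

* The intercept diagnostic is reported but not turned into a formal test;
  shared-environment violations bias the slope and are invisible to the
  fit itself.
* The binned estimator's standard error is obtained by bootstrap only; no
  analytic sampling variance is provided (the pair-level errors are
  dependent, so the naive OLS variance would be wrong).
* `greml()` handles exactly one random effect; multi-kernel models
  (dominance, epistasis kernels) are out of scope.
* At very high relatedness and tiny causal counts, `sds1`'s fitted
  intercept can be non-positive on unlucky resamples; the estimate is then
  flagged invalid rather than silently used.
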