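# sdsreg

Estimation of additive genetic variance and narrow-sense heritability from
genome-wide marker data by **binned similarity regression**, with a
spectral single-GRM REML baseline, an AR1 population simulator for
calibration, delete-duplicate bootstrap intervals, and GCTA binary GRM
interchange.

## Who this is for

Quantitative geneticists and breeders who need h² (and σ²ₐ) from samples
large enough that likelihood-based mixed-model fitting becomes infeasible —
the covariance matrix is n × n, and REML iterations on it run out of
memory long before the data stop growing. The regression estimator here
needs only the lower triangle of the genomic relationship matrix streamed
into a fixed number of bins, so its cost is essentially flat in sample
size once the GRM exists.

## The method

For individuals *i*, *j* with genomic relatedness θ̂ᵢⱼ (VanRaden-type GRM,
Θ̂ = WW′/m from unit-variance standardized genotypes), the purely additive
model with no shared environment implies

- covariance form: E[(yᵢ − ȳ)(yⱼ − ȳ)] ≈ θᵢⱼ σ²ₐ — the OLS slope of the
  centered cross-product on θ̂ estimates σ²ₐ, and the slope of the
  standardized cross-product estimates h² directly;
- difference form: E[(yᵢ − yⱼ)²/2] = σ²ₚ − θᵢⱼ σ²ₐ — intercept σ²ₚ,
  slope −σ²ₐ, h² = −β/α.

Instead of regressing over all n(n−1)/2 pairs (Ritland's classical
procedure, also provided), the relatedness axis is divided into 1000
equal-width bins and bin means are regressed on bin means: pair-level noise
averages out within bins and the regression never sees more than 1000
points, whatever the sample size. A restricted-maximum-likelihood fit of
the same single-kernel mixed model (one eigendecomposition, profile
likelihood in h² ∈ [0, 1]) serves as the baseline the regression is
compared against.

## Worked example

```r
library(sdsreg)
pop <- sim_ar1_population(n = 500, m = 2000, h2 = 0.5, seed = 2025)
pop
#> Simulated AR1 population: n = 500, m = 2000, h2 = 0.5, theta_a = 0.95
#>   200 causal markers; realized h2 = 0.5593

K <- compute_grm(pop$genotypes)
K
#> GRM: 500 individuals (source: marker, 2000 markers)
#>   diagonal mean 0.9635; off-diagonal mean -0.0019, range [-0.1511, 0.8954]

fit <- sds(pop$y, K)          # binned covariance-form regression
fit
#> Similarity regression (sds2_binned), n = 500 (124750 pairs, 963 occupied bins)
#>   sigma2_a = 0.6082   sigma2_p = 1.0029   h2 = 0.6064

greml(pop$y, K)               # spectral REML baseline
#> Single-GRM REML fit, n = 500
#>   sigma2_a = 0.6265   sigma2_e = 0.4294   h2 = 0.5933
#>   restricted log-likelihood = -614.7033

sds_boot(pop$y, K, B = 200, estimator = "sds2", seed = 1)
#> Delete-duplicate bootstrap (sds2), 200 resamples (0 failed)
#>   sd = 0.0742   95% CI = 0.4872 to 0.7970
#>   mean unique individuals per resample = 316.5
```

Reading the numbers: this replicate's realized heritability (the variance
ratio of the drawn genetic and residual effects) is 0.559 — genetic
sampling at n = 500 scatters replicates around the nominal 0.5 — and both
estimators track it (SDS 0.606, REML 0.593) rather than the nominal value.
The regression's intercept (−0.046, see `summary(fit)`) is a diagnostic:
it should be near zero when no pairs share environment. The bootstrap
resamples individuals with replacement and drops duplicates (hence ~316
unique individuals per resample) so that resampled GRMs stay non-singular
for REML.

Replicated calibration studies, the relatedness-accuracy experiment, and
plain-text/GCTA-binary I/O:

```r
sim_study(h2 = 0.2, n = 500, m = 200, reps = 100,
          methods = c("sds2", "reml"), seed = 42)   # Monte-Carlo summary table
grm_accuracy(n = 200, m = 200, seed = 1)            # cor(estimated, theoretical AR1 GRM)
write_grm_gcta(K, "mygrm"); read_grm_gcta("mygrm")  # GCTA .grm.bin/.grm.id triple
```

A thin command-line wrapper over these functions is installed at
`system.file("cli", "sdsreg", package = "sdsreg")` with subcommands
`simulate`, `grm`, `estimate`, `table1`, `figure1`.

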