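# mrbridge

Two-sample, bidirectional Mendelian randomisation (MR) from GWAS summary
statistics, built for analyses linking body-constitution traits (BMI, waist
circumference, body fat percentage) with hearing-loss liabilities
(sensorineural, noise-induced and age-related hearing impairment) — and for
any other exposure/outcome pair shipped as summary-statistic tables. The
package runs entirely offline: instrument construction, allele
harmonisation, five causal estimators, heterogeneity and pleiotropy
diagnostics, single-causal-variant colocalisation, and statistical power
calculations, validated against a built-in synthetic GWAS generator with
known ground truth.

## Who it is for

Genetic epidemiologists who have exposure and outcome GWAS summary
statistics (variant, alleles, frequency, beta, se, p, n) plus an LD matrix
for the candidate instruments, and who want a reproducible, config-driven
MR analysis with a full audit trail — without network access to clumping or
proxy services.

## The model

For variant *j*, let b̂ₓⱼ (se σₓⱼ) be its association with the exposure and
b̂ᵧⱼ (se σᵧⱼ) with the outcome. Each variant's Wald ratio is
θ̂ⱼ = b̂ᵧⱼ / b̂ₓⱼ with first-order se σᵧⱼ/|b̂ₓⱼ|. The headline estimator is
the inverse-variance-weighted (IVW) meta-analysis of the Wald ratios under a
multiplicative random-effects model: weighted regression of b̂ᵧ on b̂ₓ
through the origin with weights 1/σᵧ², the standard error inflated by
√max(1, Q/(k−1)) where Q is Cochran's Q. Sensitivity estimators relax the
exclusion-restriction assumption in different directions:

- **MR-Egger** — weighted regression with an intercept; the intercept
  estimates directional pleiotropy.
- **Weighted median** — consistent when ≥ 50% of the weight comes from
  valid instruments.
- **Weighted mode** — consistent when the largest cluster of instruments
  is valid.
- **MR-PRESSO** — residual-sum-of-squares global pleiotropy test with
  per-variant outlier detection and a distortion test.

Colocalisation over a genomic window uses Wakefield approximate Bayes
factors per variant and trait — log ABF = ½log(1−r) + z²r/2 with
r = W/(W+σ²) — accumulated by log-sum-exp into posterior probabilities for
the five hypotheses H0 (no causal variant) … H4 (one shared causal
variant); PP(H4) > 0.8 is the conventional colocalisation bound. Power is
summarised as the minimum detectable OR per 1 SD of the exposure,
exp[(z₁₋α/₂+z_power)/(√(n·R²)·√r̄/(1+r̄))] with r̄ the control:case ratio.

## Worked example

```r
library(mrbridge)

# synthetic forward analysis: continuous exposure (n = 360k) against a
# binary outcome (n = 252,719, 7.64% cases), true effect 0.2 log-OR/SD
sim <- simulate_mr_dataset(mr_truth(theta = 0.2, J = 50, seed = 42))
h   <- harmonise(sim$exposure, sim$outcome)
fit <- mr_fit(h, seed = 42, n_boot = 1000)
summary(fit)
```

```
Two-sample MR fit: 50 instrument(s)
          method estimate      se   ci_low ci_high    pval  k
         ivw_mre   0.1844 0.08409  0.01962  0.3492 0.02829 50
           egger   0.2376 0.13740 -0.03162  0.5069 0.08367 50
 weighted_median   0.2342 0.12540 -0.01156  0.4800 0.06179 50
   weighted_mode   0.2274 0.43160 -0.61850  1.0730 0.59820 50

Heterogeneity: Q = 38.32 on 49 df, p = 0.864, I2 = 0.0%
Egger intercept: -0.0013 (se 0.0027, p = 0.624)
```

All four estimators land near the generating effect of 0.2; the IVW 95% CI
(0.020, 0.349) excludes zero, Cochran's Q finds no heterogeneity, and the
Egger intercept is compatible with no directional pleiotropy. On the log-OR
scale `exp(0.1844) ≈ 1.20` is the odds ratio per SD of exposure.

Colocalisation of a simulated shared-causal region:

```r
reg <- simulate_region(region_truth(scenario = "shared", seed = 42))
coloc_pp(reg$exposure, reg$outcome)
#> Colocalisation over 200 shared variants (p1=0.0001, p2=0.0001, p12=1e-05)
#>   H0 H1 H2 H3 H4
#>    0  0  0  0  1
#> Colocalised (PP_H4 > 0.8): TRUE; top shared-causal candidate: rs16_0100 (100.0%)
```

Design power for a real configuration — instruments explaining 1.51% of
exposure variance against an outcome GWAS of 252,719 with 19,313 cases:

```r
min_detectable_or(0.0151, 252719, 19313, 233406)$or_2dp
#> [1] 1.19
```

Whole analyses run from a YAML configuration (`run_bidirectional()`),
which writes `estimates.tsv`, `diagnostics.tsv`, `single_snp.tsv`,
`loo.tsv`, `funnel.tsv`, `power.tsv`, `coloc.tsv` and a `manifest.json`
recording every threshold, seed and per-variant harmonisation decision.

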