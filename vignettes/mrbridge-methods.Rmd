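---
title: "Methods: two-sample bidirectional MR with colocalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample bidirectional MR with colocalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbridge)
```

## The inference problem

Two-sample Mendelian randomisation treats genetic variants as instrumental
variables for a modifiable exposure: a variant that shifts the exposure,
is independent of confounders, and affects the outcome only through the
exposure identifies the causal effect from summary statistics alone. The
package was built around bidirectional analyses between adult body
constitution (BMI, waist circumference, body fat percentage — continuous,
SD-standardised) and hearing-loss liabilities (sensorineural,
noise-induced, age-related — binary, log-odds scale), where "forward" and
"reverse" are merely direction labels: the engine is direction-agnostic
and the directionality lives in configuration.

The three instrument assumptions cannot all be verified from summary
data, so the package treats estimation and diagnosis as one unit: every
fit carries its heterogeneity statistics, the Egger intercept, and — when
enough instruments exist — MR-PRESSO outlier analysis.

## Instrument construction

Candidates pass a genome-wide threshold (default `5e-8`). When fewer than
`min_count` (default 13) qualify — the situation for sparse hearing-loss
GWAS, where one outcome yields only a dozen genome-wide hits and another
none — selection relaxes to a fallback threshold (default `5e-5`) and the
relaxation is flagged in the result and the manifest. `min_count = 13` is
our configurable reading of "enough instruments for sensitivity
analyses": the smallest count that makes a 12-hit set relax.

Clumping is greedy by ascending p-value (ties broken lexicographically by
rsid for reproducibility): a candidate is kept iff its LD r² with every
already-kept variant within a 10,000 kb window on the same chromosome is
≤ 0.001. The LD matrix is user-supplied (square or long-format TSV); the
package deliberately performs no online LD lookups, so analyses are fully
offline and testable. Candidates absent from the matrix are excluded with
reason `no_ld_info`, never silently kept. Instruments missing from the
outcome GWAS may be replaced by the highest-r² proxy with r² ≥ 0.9.
Because r² carries no sign, a proxy's orientation cannot be read off the
LD matrix; the pipeline orients proxies by allele-frequency agreement
(the same closest-frequency rule used for palindromic variants) and skips
the substitution when frequencies are unavailable. This is a known
limitation relative to signed-LD (D′) aware tools.

Per-variant instrument strength uses the standardised-trait
approximation r² = 2·eaf·(1−eaf)·β² and F = r²(n−2)/(1−r²); F > 10 is
the conventional weak-instrument gate. The formula presumes an
SD-standardised continuous exposure, so no r² is computed for binary
exposures in the reverse direction — the honest statement is that
detectable effect sizes are unavailable there, not a number.

## Harmonisation

Outcome rows are aligned to the exposure effect allele: direct match,
allele swap (beta sign flipped, frequency complemented), strand
complement, or both. Palindromic (A/T, C/G) variants cannot be resolved
from alleles; they are kept only when the exposure MAF ≤ 0.4 and the
strand is inferred by whichever of the outcome frequency and its
complement is closer to the exposure frequency. A palindromic variant
without an outcome frequency is excluded rather than guessed, as is any
variant whose alleles are incompatible (`allele_mismatch`) — the
conservative reading of standard harmonisation guidance. Variants with
imputation info < 0.9 are excluded when an info column exists; an absent
info column is treated as a pass with a logged message, since major
consortium exports differ on whether they ship it. Every decision lands
in an audit log whose kept+flipped+excluded counts exactly partition the
intersection, a property the tests assert.

## Estimators

All estimators operate on the harmonised per-variant pairs
(b̂ₓⱼ, σₓⱼ, b̂ᵧⱼ, σᵧⱼ); binary-outcome effects stay on the log-OR scale
internally and are exponentiated only in the reporting tables.

- **Wald ratio** b̂ᵧ/b̂ₓ with first-order se σᵧ/|b̂ₓ|. Variants with
  b̂ₓ = 0 are removed upstream with a warning.
- **IVW, multiplicative random effects**: weighted least squares through
  the origin, weights 1/σᵧ². The residual overdispersion factor
  max(1, Q/(k−1)) scales the standard error — floored at 1 so
  heterogeneity can widen but never narrow the interval, the common
  implementation convention. With k = 1 the code returns the Wald ratio
  verbatim, an exact degeneracy the tests check bit-for-bit.
- **MR-Egger**: intercept-including weighted regression after orienting
  all variants to non-negative b̂ₓ; overdispersion floored at 1 with k−2
  df. Requires k ≥ 3 — a two-point regression with an intercept has no
  residual df and is refused rather than approximated.
- **Weighted median**: the 50th percentile of the ratio distribution
  under inverse-variance weights, linearly interpolated over cumulative
  normalised weights; se by parametric bootstrap (per-variant betas
  redrawn from their sampling normals, seed-controlled).
- **Weighted mode**: argmax of a weighted Gaussian kernel density over
  the ratios; bandwidth is the modified Silverman rule
  0.9·min(sd, mad)·k^(−1/5) times a user factor (default 1); se by the
  same parametric bootstrap.

Intervals and p-values use normal quantiles throughout. Bootstrap
replicates default to 1000 in the API; the large validation studies use
200 per fit, which changes the se estimate's own noise, not the
estimator. Seeds are mandatory in the pipeline configuration, so a rerun
of an identical config reproduces every table byte-identically.

## Diagnostics

Cochran's Q uses first-order weights b̂ₓ²/σᵧ² on the Wald-ratio scale
(second-order weights are a documented non-choice: the source analyses
name only "Cochran's Q"), with df = k−1, I² = max(0, (Q−df)/Q), and
heterogeneity flagged at p < 0.05. Heterogeneity is reported, never used
to switch models: the multiplicative random-effects IVW is always the
headline.

MR-PRESSO computes each variant's standardised residual against the
leave-one-out IVW expectation, refers the weighted residual sum of
squares to a parametric null (both betas redrawn; 1000 simulations by
default), and uses the +1 empirical-p convention so the global p lives in
[1/(n_sim+1), 1]. Per-variant outlier p-values are Bonferroni-corrected;
the distortion test compares the all-variant and outlier-corrected
estimates against random same-size removals. Outliers are reported by
rsid. The k ≥ 4 precondition is surfaced as a typed error — the reason
sparse traits need relaxed instrument thresholds in the first place.

## Colocalisation

`coloc_pp()` implements single-causal-variant colocalisation from
Wakefield log approximate Bayes factors, accumulated by log-sum-exp
(H3's cross-term sum is computed as a stable log-difference). Per-variant
priors default to p1 = p2 = 1e-4 and p12 = 1e-5, and PP(H4) > 0.8 is the
decision bound. ABF effect-prior SDs default to 0.2 for continuous traits
and 0.15 for binary (log-odds) traits — the cited framework's
conventions, configurable. Case-control standard errors are taken
directly from the summary statistics; no outcome-SD reconstruction is
attempted. The tests verify that log-space accumulation matches naive
linear-space summation to 1e-10 on small regions, that posteriors are
order-invariant, and that p12 → 0 forces PP(H4) → 0.

Regions are 1-based inclusive with the genome build carried as metadata;
a build mismatch is an error, never a silent conversion. The analysis
that motivated the module examines the FTO locus
(chr16:53,737,875–54,155,853, hg19), exposed as `fto_region()`. Because a
shared causal variant at a locus can justify removing that locus's
instrument from the reverse direction, the pipeline supports per-analysis
exclusion lists with LD-aware expansion (anything at r² ≥ 0.8 to a listed
variant, configurable). The mechanism is rsid-agnostic: it implements the
exclusion rule without adjudicating which member of a perfect-LD clique
is "the" causal variant.

## Power

`min_detectable_or()` inverts the standard binary-outcome power
approximation: β_min = (z₁₋α/₂+z_power)/(√(n·R²)·√r̄/(1+r̄)) with r̄ the
control:case ratio of the **outcome** GWAS (√r̄/(1+r̄) = √(v(1−v)) for
case fraction v). The closed form was verified against all nine rows of
the published design table it mirrors before being wired in; only the
outcome-side sample size reproduces that table, so the outcome-based form
is adopted. Printed ORs round half-up to 2 decimals. `power_at_or()` is
the forward form; the pair round-trips to 1e-10.

## The synthetic-data generator

`simulate_mr_dataset()` emulates the statistical structure of the target
designs rather than any real cohort: J independent instruments with
MAF ~ U(0.05, 0.5); true exposure effects half-normal with scale 0.021 —
reported on the exposure-increasing allele, as instrument lists
conventionally are, which is also what makes directional pleiotropy a
testable Egger-intercept signal; exposure se = 1/√(2·maf(1−maf)·n) for an
SD-standardised trait with n = 360,000 (biobank scale, giving mean
per-variant F near 60, matching the 52–67 range of the motivating
analyses); outcome true effects θ·b̂ₓ plus optional per-variant direct
effects; binary outcomes on the log-odds scale with
se = 1/√(2·maf(1−maf)·n·v(1−v)), defaults n = 252,719 and v = 0.0764
(FinnGen-scale case imbalance). Direct effects are drawn once per variant
and shared between the balanced and directional scenarios (the
directional mean is added on top), so the two calibration arms differ
only in the parameter under test. The binary channel uses the normal
approximation on the log-odds scale rather than individual-level
logistic sampling — adequate at these sample sizes and fast at desk
scale.

`simulate_region()` draws regional z-scores as MVN with AR(1) correlation
Σ = ρ^|i−j| (default ρ = 0.9) and mean λ·Σ·e_causal; λ = 12 emulates a
strong biobank-scale regional hit. Scenario labels map one-to-one onto
H0–H4. What the generator does **not** emulate: realistic human LD maps,
reference allele-frequency spectra, sample overlap between studies, and
selection effects in instrument discovery (no winner's-curse filtering is
applied). Passing calibration on synthetic data therefore demonstrates
correctness of the estimators under their own assumptions, not robustness
to every pathology of real GWAS data.

## Validation-study dimensions

The built-in studies (`recovery_study()`, `egger_calibration_study()`,
`presso_study()`, `coloc_scenario_study()`) run at J = 50 instruments with
200 replicates for estimator coverage and Egger calibration, 100
replicates at 1000 PRESSO simulations for outlier detection, and 50
replicates per scenario at J = 200 variants for colocalisation — sizes at
which Monte Carlo error is small relative to the tolerances being
checked while a full run completes in a few minutes on one CPU. The
directional-pleiotropy arm uses direct-effect sd 0.02 and mean 0.02 (one
tenth of the θ = 0.2 effect scale).

## Known limitations

- No Steiger filtering, multivariable MR, or non-linear/subgroup MR.
- No VCF parsing, reference-FASTA lookup or genome-build liftover.
- Proxy orientation from r² + frequency only (no signed D′).
- Binary-exposure instrument strength (reverse direction) is not
  computed, by design.
- The colocalisation model assumes at most one causal variant per trait
  per region; multi-causal fine-mapping is out of scope.
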