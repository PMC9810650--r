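---
title: "Assessing analyte fidelity with rxCOV: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing analyte fidelity with rxCOV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxcov)
```

## The problem

Immunoassays compare an analyte's expression between two sample groups in
the presence of stochastic assay-associated noise: biological
heterogeneity, preanalytical variation, operator effects, cross-reactivity.
When the between-group difference is small or the signal-to-noise regime is
low, a two-group test can declare significance that is purely a noise
artifact — or miss a real difference for the same reason. Fidelity, as used
throughout this package, is the property that the measured differential
expression genuinely exceeds what the assay's own noise can produce.
Establishing it is a precondition for any downstream statistics, including
power analysis and effect-size reporting, and is distinct from effect-size
metrics such as Cohen's d, which quantify magnitude rather than validity.

## Model and metric

Two random variables X, Y describe an analyte's expression in the two
groups; X', Y' are repeat measurements on second aliquots of the same
samples. Because a repeat of the same sample differs from its primary
measurement only through assay noise, the absolute differences
N_X = |X − X'| and N_Y = |Y − Y'| measure that noise directly, and the
worst case of the two, N = max(N_X, N_Y), is a deliberately conservative
noise variable. The differential expression is Z = |X − Y|. Both are
ratio-scale: zero expression is well-defined, which is what licenses the
metric below (and restricts it to assays where that is true).

For a positive pair of effect-size measures the relative-change function
f(m_Z, m_N) = log10(m_Z / m_N) is zero iff they are equal, signed by their
order, monotone, and invariant under a common rescaling — so it is
unit-free. A printed statement of homogeneity (scaling f by the same factor
as its arguments) cannot hold for a log-ratio; the property the function
actually possesses, and the one this package asserts and tests, is scale
*invariance*. Applying f to the mean pair and the standard-deviation pair
and adding the two (logs turn products into sums) gives

$$\mathrm{rxCOV}(Z, N) = \log_{10}\frac{\mu_Z}{\mu_N} +
  \log_{10}\frac{\sigma_Z}{\sigma_N} =
  \log_{10}\frac{\sigma_Z/\mu_N}{\sigma_N/\mu_Z},$$

a ratio of two cross coefficients of variation: each dispersion is
standardized by the other variable's mean. The implementation evaluates the
cross-COV form and reports the mean and dispersion terms separately, so the
additivity identity is verified numerically (to < 1e-9) rather than being
true by construction. Fidelity is `high` iff rxCOV > 0; exact zero is
classified `low`, because at zero the two effect sizes are
indistinguishable.

The metric is smooth on (0, ∞)^4 — each partial derivative is the
hyperbola ±1/(x ln 10) — so small changes in the four statistics produce
small changes in the verdict. The test suite confirms the derivatives by
central finite differences at random interior points (tolerance 1e-6, step
1e-4·x, for which the theoretical truncation error is ~1e-8).

## Estimators

* **moment** (default): arithmetic mean and sample standard deviation with
  the n − 1 denominator. The convention is not dictated by the mathematics;
  n − 1 is chosen because assay groups are small and it is the default of
  the statistical environments practitioners use.
* **robust**: median and interquartile range (Q3 − Q1, linear interpolation
  between order statistics, `stats::quantile` type 7), for skewed data.
  Fixed and documented so results are bit-reproducible across environments.

Degenerate statistics (any of μ_Z, μ_N, σ_Z, σ_N equal to zero) are a hard
error naming the offender — no epsilon floors, since silently perturbing a
fidelity metric defeats its purpose. In batch mode the error becomes a
per-analyte `status` so a panel is always screened end-to-end. One special
case is separated: when every repeat difference is exactly zero the assay
is noise-free and fidelity is trivially high; the row reports
`status = "noise_free"` with no finite rxCOV rather than a fabricated
number. A fully constant analyte, by contrast, is degenerate (the Z check
takes precedence).

## Paired and unpaired designs

Paired data use Z = |x_i − y_i| on aligned samples (equivalently
max − min, the lattice identity). Unpaired data redefine Z at the summary
level: location |μ_X − μ_Y|, dispersion √(σ_X² + σ_Y²). Noise is always
paired (a repeat aliquot belongs to its sample). For the robust estimator
in unpaired mode the two IQRs are combined in quadrature by analogy with
the moment formula; this combination is an extension chosen here — the
robust substitution is otherwise defined only estimator-wise — and is
flagged as such to users.

For unequal group sizes the max-of-noise variable has no canonical
sample-level realization, so two are offered: `elementwise_max` for
aligned groups, and the default for unpaired analysis,
`cross_product_max`, which enumerates max(nx_i, ny_j) over all i×j pairs —
the exact empirical distribution of the max of two independent noise
draws. The cross-product multiset is then summarized with the same
estimator as everything else.

Moving from the paired to the unpaired reading of the same data can only
decrease μ_Z and increase σ_Z, so the induced change
ΔrxCOV = log10(1 + Δμ_Z/μ_Z) + log10(1 + Δσ_Z/σ_Z) is evaluated on
[−d, 0] × [0, d]. For deviations up to 50% the surface is bounded in
(−0.301, 0.176]: the metric is sensitive to the pairing assumption but
stably so. Monotonicity makes the extrema corner values, which the grid
simply confirms.

## The noise-injection simulation

The simulator emulates hypothetical cytokine expression in two groups with
additive, γ-scaled noise: d = s + γ·n, where s is drawn once per scenario
and n fresh per measurement. Each measurement is drawn twice with
independent noise (primary and repeat aliquot), so the realized noise
variable is γ|n − n'| — for Normal(0, σ_n) base noise a half-normal with
mean 2γσ_n/√π and sd γσ_n√(2 − 4/π), which the suite verifies by Monte
Carlo at 200 000 draws within 1%. Observed expressions are clipped at zero
(ratio-scale data) with clip counts recorded, so ill-posed scenarios are
detectable.

The canonical scenario — the package's reference conditions, chosen once —
is n = 12 samples per group, s_X ~ Normal(10, 2), s_Y ~ Normal(12.5, 2)
(a clean-signal difference detectable at the 95% level at this n), base
noise Normal(0, 1) (scenario 1) or Normal(0.2, 1.1) (scenario 2), seeds
recorded in every output. These are artifact defaults: the underlying
published experiments did not print their distributions, so no numeric
curve is treated as an external truth; only structural claims are.

A γ-scan holds the clean signals fixed and, per γ on a strictly positive
increasing grid, rebuilds the noisy data, computes rxCOV (paired Z,
elementwise-max N) and a two-group p-value (Welch's t by default —
configurable to Student's t or Mann–Whitney; the choice of default follows
common practice for possibly unequal variances). γ = 0 is excluded: as
noise vanishes the metric diverges to +∞, so a finite value there has no
meaning under this model. Fresh noise per γ is the default; a fixed-draw
mode scales one base realization across the grid instead.

Two thresholds are extracted by linear interpolation between grid points:
γ* where the rxCOV track first crosses zero downward (an exact grid-point
zero returns that point; later re-crossings are attached as a warning
list), and γ_sig where the p-value track first crosses α upward. Beyond γ*
the noise dominates; any significant p-value there is flagged `spurious`
in the scan table.

## Replication

Averaging R independent replicates of each measurement divides the
effective noise scale by √R while leaving the signal untouched, so the
whole scan at replicate count R equals (in distribution) the R = 1 scan
with γ shrunk by √R, and γ* shifts right by √R. `replicate_study()`
demonstrates this; the suite checks γ*(4)/γ*(1) ∈ [1.5, 2.5] at
n = 2000/group. For real data `replicate_sufficiency()` applies the
operational rule: average replicates 1..R cumulatively and return the
smallest R with rxCOV > 0, or an explicit "insufficient at max R" verdict.

## Numerical and design choices

* **Problem sizes.** Distributional checks in the tests use
  n = 2000/group for scan-shape properties, 200 000 draws for the
  half-normal closed form, and a 0.25-spaced γ grid to 20 covering both the
  R = 1 and R = 4 thresholds of the canonical scenario; these sizes keep
  Monte-Carlo error well inside the asserted tolerances.
* **Track smoothing.** The rxCOV track approaches a shallow negative
  asymptote (≈ −0.2 for shared Normal(0, 1) noise, a constant the suite
  cross-checks against a brute-force Monte-Carlo oracle of the clipped
  noise-only limit), so near γ* the curve is flat enough that per-point
  Monte-Carlo jitter can re-cross zero. Threshold detection at acceptance
  scale therefore averages k = 3 noise realizations per γ (`k_smooth`,
  default 1 elsewhere; always recorded in outputs).
* **Determinism.** Every stochastic entry point takes a scenario seed;
  identical seeds give bit-identical scans, fixtures and CSVs (floats are
  serialized at 6 significant digits; manifests carry the seed and input
  digests).
* **Missing data.** Zeros are legal measurements; missing values are
  dropped with a logged count, never imputed. Malformed tables fail with
  structured validation errors listing offending rows.

## What the synthetic generator does and does not show

`make_fixture()` draws complete long-format tables (two groups, duplicate
aliquots, optional replicates) from the scenario model, so every pipeline
path — file I/O, batch screening, sufficiency analysis, CLI — is testable
without external data. The generator emulates additive, homoscedastic,
group-independent noise on normal or lognormal signals. Real immunoassay
noise can be concentration-dependent (heteroscedastic), correlated across
analytes on a plate, and bounded by detection limits; none of these are
modeled. Passing tests therefore demonstrate the correctness of the
metric's implementation and the qualitative phenomena (threshold behavior,
spurious significance, √R replication gains), not the calibration of any
particular real assay.

## Known limitations

* The metric presumes ratio-scale measurements; interval-scale readouts
  (where zero is arbitrary) are out of scope.
* No multiplicity correction is applied across analytes — the verdict is
  per-analyte by design, and fidelity is not a significance statement.
* The unpaired robust combination and the cross-product noise enumeration
  are documented interpretations where the underlying theory defines N
  only as a random-variable max.
* Plate-map (wide) imports, vendor export formats and plotting are out of
  scope; the CSV contract is the interface.
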