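---
title: "Validity analysis for multi-measure studies: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validity analysis for multi-measure studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(validnet)
```

`validnet` implements the statistical machinery of a psychometric
validation study in which several instruments measuring one construct are
compared on convergent validity, self–informant agreement, nomological
nets, profile similarity and retest reliability. This vignette explains
the models behind each stage, the parameters that matter, and the design
choices made where the methodology left room.

## Correlation machinery

All correlations are Pearson correlations on pairwise-complete
observations by default, with the number of complete pairs recorded per
cell. Pairwise deletion matches the common reporting practice of printing
a range of Ns under a correlation table; listwise deletion is available
via `use = "listwise"`. A cell with fewer than 4 complete pairs, or with
a constant column among them, is undefined and kept as `NA` rather than
silently dropped.

Averaging and comparison happen on the Fisher-z scale, `z = atanh(r)`,
which stabilizes the sampling variance at `1/(n-3)`. Before the
transform, `|r|` is clipped at `1 - 1e-12` (with a warning) because
`atanh(1)` is infinite; the round trip `tanh(atanh(r))` is exact to
`1e-9` for `|r| <= .999999`. The "average absolute correlation" of a set
of cells is `tanh(mean(atanh(|r|)))`. By convexity of `atanh` on `[0, 1)`
this z-based average is never smaller than the plain mean of `|r|` — a
property the test suite checks — so the two conventions are not
interchangeable and the package uses the z-based one throughout, as
validation reports conventionally do.

Two correlation matrices are compared by the mean absolute deviation of
corresponding cells (`matrix_mad()`) and by the chi-squared statistic

```
Q = sum_k (z1k - z2k)^2 / (1/(n1-3) + 1/(n2-3)),   df = #cells,
```

which follows a chi-squared distribution when the population matrices are
equal *and the compared cells are mutually independent*. That second
premise deserves emphasis: cells of a correlation matrix estimated on one
sample are themselves correlated, and simulation shows the test
over-rejects when the variables are substantially intercorrelated (about
7.5% at nominal 5% for four variables with ρ = .3 at n = 300), while it
is accurately calibrated when the compared coefficients are nearly
independent. The package replicates the conventional procedure rather
than correcting it, and likewise reports — but flags as "dependence
ignored" — comparisons of matrices estimated on the same subjects. For
symmetric matrices only the unique off-diagonal cells are compared, since
the diagonal is 1 by construction; a `df_mode = "full"` compatibility
option reproduces the k² degrees-of-freedom convention seen in some
published reports, without any claim about its statistical meaning.

Disattenuation divides an observed correlation by the square root of the
product of the two scores' reliabilities. Values above 1 are returned as
computed but flagged, since truncation would hide the diagnostic
information that the reliability inputs are too low.

## Double-entry profile similarity

Two profiles of correlations (e.g., the columns of a correlates ×
measures block for two measures) are compared by the double-entry
intraclass correlation: each pair is entered twice in reversed order and
the Pearson correlation of the doubled vectors taken, equivalently

```
ICC_DE = 2 sum (a_i - m)(b_i - m) / (sum (a_i - m)^2 + sum (b_i - m)^2),
```

with `m` the grand mean of the pooled `2k` values. The closed form and
the literal double-entry computation agree to `1e-10` on random profiles
(tested). ICC_DE is 1 only for identical profiles and −1 for profiles
mirrored around their common mean; unlike Pearson's r it is sensitive to
elevation: adding a constant to one profile strictly lowers it. For
positively related profiles ICC_DE never exceeds the Pearson correlation,
with equality when means and variances match. For *negatively* related
profiles no such magnitude ordering holds — the pooled-mean centering can
push ICC_DE below r — which is worth knowing when interpreting strongly
dissimilar profiles.

Profiles are Fisher-z transformed before comparison by default (the
convention of the tables the package reproduces); `transform = "none"`
gives raw-r comparisons. Profile pairs with missing cells are compared on
their shared complete subset, whose size is recorded. Profiles must share
at least 3 defined elements. Cross-study comparisons require the caller
to align measures and correlates explicitly by renaming columns — there
is no fuzzy name matching, because a silent wrong alignment is worse than
an error.

## Informant agreement

Informant ratings are aggregated per target by the arithmetic mean, with
the informant count carried forward. Rater consensus uses the one-way
random-effects decomposition: with between/within mean squares MSB and
MSW and effective rater count `k0 = (N - sum(k_i^2)/N) / (n_targets - 1)`
for unbalanced designs,

```
ICC(1)  = (MSB - MSW) / (MSB + (k0 - 1) MSW)
ICC(1,k) = (MSB - MSW) / MSB,
```

and ICC(1,k) equals the Spearman–Brown step-up of ICC(1) at `k = k0` on
balanced designs (verified to `1e-10` in the tests). Designs where every
target has a single rater have no within-target variance and error.

The standardized mean difference `d` between self and informant scores
uses the pooled standard deviation of the two score distributions as
denominator — the conventional reading of "standardized mean difference",
comparable across measures — with the difference-score variant `d_z`
available via `d_type = "dz"`; the two differ whenever the pairing is
informative, so the choice is explicit rather than hidden. Positive `d`
means self-ratings are higher. Zero-variance difference scores make the
paired t undefined; the result is flagged degenerate rather than
reported as infinite.

## Constrained-correlation likelihood-ratio tests

Whether two measures differ in their association with an external
variable is tested by comparing a saturated multivariate-normal
correlation structure with one constraining `corr(m1, y) = corr(m2, y)`.
The discrepancy is the ML fit function
`F = log|Σ| + tr(SΣ⁻¹) − log|S| − p`; the saturated model reproduces the
sample matrix S exactly (F = 0), so the test statistic is
`χ²(1) = N·F_constrained` with N the complete-case count (an `"n-1"`
scaling is switchable). The constrained optimum is found by BFGS over the
off-diagonal correlations on the `atanh` scale — a smooth unconstrained
parameterization in which the equality constraint is plain parameter
sharing — with positive-definiteness enforced by a barrier; a Nelder–Mead
polish runs if BFGS reports non-convergence, and a negative χ² beyond
`1e-6` (constrained fit beating saturated) is treated as an optimizer
failure and raised as an error. The statistic is invariant to affine
rescaling of any input variable, agrees with an independent brute-force
likelihood maximization to `1e-3` on 3-variable fixtures, is exactly zero
(≤ 1e-6) when the sample already satisfies the constraint, and its null
rejection rate at n = 300 is consistent with the nominal 5% level over
2000 simulated replicates — all asserted in the test suite.

By default each test models only the triple (m1, m2, y) — listwise
complete within the test, since the likelihood needs one joint sample.
A `vars_mode = "batch"` option includes all measures of the active batch
plus one correlate, mirroring the convention of entering all item scores
with unrestricted correlations; the saturated fits are identical
cell-wise either way, and the constrained fits differ only slightly.
`pairwise_difference_scan()` runs all within-batch measure pairs against
all correlates; batches exist because a total score should never be
tested against its own facets. Significance is declared at p < .001,
the conventional guard against the large number of pairwise tests, with
no further multiplicity correction.

## Quasi-simplex reliability

For a single item observed at three evenly spaced occasions, true scores
are assumed to follow a lag-1 autoregression with stability `s` while the
observed score adds measurement error with reliability `ρ`:

```
X_t = sqrt(ρ) T_t + sqrt(1-ρ) e_t,   T_{t+1} = s T_t + sqrt(1-s²) ζ_t.
```

The implied autocorrelations `r12 = r23 = ρs`, `r13 = ρs²` identify
`ρ = (r12 · r23) / r13` — the Heise estimator. The estimate is never
clamped; values outside `[0, 1]` and denominators `|r13| < .1` are
flagged, since they signal that the equal-spacing or constant-reliability
assumptions are strained. Lag correlations are estimated
pairwise-complete ("full" sample) or on the complete panel
(`sample = "panel"`); under MCAR attrition the two agree within sampling
error (tested).

Uncertainty is propagated by applying the formula to the three lower and
the three upper Fisher-z confidence bounds of the lag correlations. This
follows the common reporting convention literally, but because the lower
bound of the *denominator* enters the "lower" estimate, the resulting
interval is not a confidence interval with guaranteed coverage; a
first-order delta-method interval (treating the three lag correlations as
independent) is therefore reported alongside, clearly labeled. The
empirical coverage of the propagated interval is a reportable quantity,
not an asserted one.

## The synthetic-data generator

`latent_spec()` encodes a single-factor measurement model: a target's
standard-normal latent trait `L`, self scores
`X_m = sqrt(rel_m)(λ_m L + sqrt(1-λ_m²) u) + sqrt(1-rel_m) e`, so that
the implied inter-measure correlation is `λ_m λ_m' sqrt(rel_m rel_m')`
and a correlate with trait correlation `c` satisfies
`corr(X_m, C) = λ_m sqrt(rel_m) c`. Informants perceive the target
through a two-level model, `Q = vL + sqrt(g - v²) B_target +
sqrt(1-g) w_rater`: `v` (validity) and `g` (consensus, the ICC(1) of the
latent perceptions) are independently tunable, which matters because the
observable statistics — informant-consensus ICCs and self–informant
correlations — are distinct targets. The full implied correlation matrix
over self scores, correlates and single-informant scores is assembled by
`build_target_correlation()` and checked for positive semi-definiteness
before any sampling; rounding-level indefiniteness (minimum eigenvalue
above −1e−6) is repaired by eigenvalue clipping and rescaling, anything
worse errors with the variables most involved — silently repairing a
badly mis-specified structure would hide user mistakes.

Default study conditions mirror a typical contact-nomination design: the
informant-count distribution over 1–6 informants is (.603, .218, .099,
.062, .012, .006), and the three-wave design retains (1, .67, .67) of
subjects per wave, missing completely at random — reported retention
rates of such panels, with the dropout mechanism being the simplest
defensible choice since none is reported. Scores are emitted on a
continuous scale; an optional equal-probability discretization to a
k-point ordinal scale is available (`likert = k`), reflecting that the
underlying instruments are Likert-type while all the statistics treat
scores as continuous. The generator assumes identical measurement
structure for self and informant forms — third-person rewordings of the
same items — which is the natural reading absent contrary information.

What the generator does *not* emulate: item-level structure (so internal
consistency cannot be estimated from generated data — reliabilities are
inputs), non-normal margins beyond the optional discretization,
informant-selection effects (e.g., lonelier targets nominating fewer
informants), and non-random dropout. Passing tests on synthetic data
therefore demonstrate the estimators' correctness under the stated
model, not robustness to those real-data features.

## Problem sizes and numerical choices

The test suite checks Monte-Carlo properties at sizes chosen to make
sampling error small relative to the asserted tolerances: parameter
recovery of the quasi-simplex at n = 5000 over 200 seeds per (ρ, s) cell;
LRT null calibration over 2000 replicates at n = 300; matrix-test
calibration over 1000 replicate pairs. Large-sample convergence checks of
the generator run at n = 50,000 once each. Tie-breaks and degenerate
inputs are handled explicitly throughout: undefined cells are `NA` and
excluded with df reductions and warnings, zero-variance profiles and
difference scores error or flag rather than return NaN, and rounding to
2 decimals happens only at the presentation layer (half-away-from-zero,
as printed tables conventionally round).

## Known limitations

The matrix-equality χ² and the "dependence ignored" flag replicate a
conventional procedure whose assumptions are only approximately met in
typical applications; treat small p-values near the threshold with
caution. The bound-propagation interval for the Heise estimator has
unknown coverage. The constrained-correlation test assumes multivariate
normality of the modeled triple. And the bundled example tables are
printed (rounded) correlations, so statistics recomputed from them can
differ from values computed on raw data in the second decimal — one
published profile-similarity value (a self- vs informant-matrix ICC_DE
of .97) is not recoverable from the printed matrix it accompanies, the
recomputation giving .77 driven by one measure's much lower printed
informant correlations.
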