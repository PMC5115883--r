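---
title: "Supervised rule mining on discretized biomedical profiles: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised rule mining on discretized biomedical profiles: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nmrules)
```

This vignette documents the statistical model behind `nmrules`, the
conventions every numerical routine follows, and the scope and limits of
the synthetic-data generators. It is the reference for anyone who needs to
know *exactly* what the package computes.

## The data model

The unit of analysis is a **discretized dataset**: `n` subjects described
by `p` variables, each variable reduced to a small set of ordered bins
(ordinal, e.g. quantile-binned spectral buckets) or unordered levels
(nominal, e.g. sex), together with a binary outcome called the *target*
with two *modalities*. All mining and modelling operates on these integer
level codes; the original continuous measurements are gone after
preprocessing, by design. Discretization buys three things: robustness to
monotone distortions of the raw scale, a finite and fully enumerable
hypothesis space, and rules a clinician can read.

The reference geometry throughout the package is a cohort of 110 subjects,
184 spectral bucket variables in 10 bins each, and an 86/24 split between
the modalities `below60` and `at_least_60` (a renal-function threshold at
60 ml/min/1.73 m² of estimated glomerular filtration rate). These sizes
are the package's defaults, chosen so that defaults exercise a realistic
imbalanced clinical cohort; nothing in the code depends on them.

## NMR preprocessing

`preprocess_nmr()` turns binned spectra into a discretized dataset through
a fixed chain. Each step is available separately.

1. **Bucketing** (`bin_spectrum()`): intensities are summed into
   half-open, equidistant buckets `[left, left + 0.04)` ppm spanning
   `[0.16, 9.00)` — 221 buckets. Bucket assignment uses
   `floor((ppm - 0.16)/0.04 + 1e-9)`, the small tolerance keeping points
   that sit exactly on an edge (up to representation error) in the bucket
   to their right. Buckets are named by their left edge
   (`"bucket 3.16"`), so names are stable coordinates.
2. **Region exclusion** (`exclude_regions()`): the residual water
   (4.48–4.96 ppm) and urea (5.45–6.48 ppm) regions are removed. The
   default boundary rule is `"contained"`: a bucket is dropped only if it
   lies entirely inside an excluded region. With the standard grid this
   keeps the bucket starting at 5.44 ppm, which only partially overlaps
   the urea region, leaving **184** buckets. The alternatives
   `"any_overlap"` and `"midpoint"` drop that cut bucket (183 buckets).
   Full containment is the default because a partially overlapping bucket
   still carries signal from outside the artefact region.
3. **Integral normalization** (`normalize_integral()`): each spectrum is
   scaled so its buckets sum to 100, removing dilution differences
   between samples. An all-zero spectrum is an error naming the subject,
   never silently divided. Note the closure effect: after normalization a
   metabolite that is constant in absolute terms *will* appear
   differential if other metabolites shift, because only relative
   composition remains. This is a property of the method, not a bug, and
   the test suite asserts it.
4. **Pareto scaling** (`pareto_scale()`): each bucket is mean-centered
   and divided by the *square root* of its standard deviation, a
   compromise between no scaling (large peaks dominate) and unit-variance
   scaling (noise buckets inflated). The default standard deviation is
   the sample convention (`n - 1` denominator, matching `stats::sd`); a
   `"population"` option exists. Zero-variance buckets scale to 0.
5. **Quantile discretization** (`quantile_discretize()`): each bucket is
   cut at its own deciles (type-7 quantiles, R's default) into 10 bins,
   duplicate cut points merged, assignment by
   `findInterval(..., left.open = TRUE)` so bin `b` is the half-open
   interval `(q[b-1], q[b]]`. Codes are therefore invariant under any
   strictly monotone transformation of a bucket, and a constant bucket
   collapses to one bin.

Pareto scaling is retained before discretization for fidelity to the
standard metabolomics chain even though per-variable quantile binning is
itself invariant to it; the scaled matrix is also the natural input for
any side analyses on the continuous scale.

## Rule mining

A **rule** is a conjunction of one or two variable conditions together
with a target modality:

```
{variable: 'bucket 3.16'; condition: bins 1 to 4} -> below60
```

For an ordinal variable with `k` bins a condition is a *contiguous* bin
range — `k(k+1)/2` of them, 55 for `k = 10`. For a nominal variable it is
any non-empty level subset (`2^k - 1`); nominal variables must have at
most 6 levels, beyond which the user is asked to pre-group. A 2D rule
pairs conditions on two distinct variables: 55 × 55 = 3025 candidates per
ordinal pair. Enumeration is exhaustive and deterministic — no sampling,
no greedy search.

Rule quality is the one-proportion z-score. With `n_r` covered subjects of
which `m_r` belong to the rule's modality, and `p_0` the modality's
population share:

$$ z = \frac{m_r/n_r - p_0}{\sqrt{p_0 (1 - p_0) / n_r}} $$

A rule is kept if `modality_size` (= `m_r`) **≥ 10** and `z` **≥ 1.96**,
both inclusive. The z threshold is the one-sided 2.5% normal tail; the
size threshold guards the normal approximation and clinical relevance.
Both defaults are recorded in the ruleset's provenance and asserted by
the tests.

**Minimization** removes redundant nested rules: within each
(modality, variable set) group, a rule `R` is deleted if some rule on the
same variables with a *strictly larger* condition set has `z ≥ z(R)`, or
one with a *strictly smaller* condition set has `z > z(R)`. Ties thus
favor the larger (more general) rule, the filter is idempotent, and no
two surviving rules are nested. The implementation (indicator matrices,
range containment via `lo`/`hi` bounds, bitmasks for nominal subsets) is
verified against an exhaustive double-loop oracle.

## Predictive models

Three model types share one architecture — feature construction followed
by an L2-regularized logistic classifier:

* **`global`**: variables passing a per-variable chi-squared screen
  (levels × target table over occupied levels, Bonferroni-corrected
  `p ≤ α/m` with `m` the number of testable variables, `α = 0.05`) enter
  directly, ordinal codes as numbers and nominal levels one-hot.
* **`local_1d`**: 1D rules are mined *within the screened variables*; each
  rule becomes a binary membership feature.
* **`local_1and2d`**: as above with 1D and 2D rules.

Model complexity is the number of features (selected variables, or rules).
The classifier minimizes
`C · Σ log(1 + exp(−t·s)) + ½‖w‖²` with an unpenalized intercept — the
`C`-parameterization common in machine-learning toolkits, solved by a
damped Newton method with backtracking (tolerance 1e-8) and verified
against a quasi-Newton optimizer on the exact objective to 1e-5. If
screening selects nothing, the model falls back to an intercept-only
majority classifier with a warning rather than failing — on null data
that is the correct model.

Because the marginal chi-squared screen precedes mining, a purely
interactive signal whose margins are flat (see the balanced plants below)
is invisible to all three model types unless the candidate variables are
supplied explicitly via `build_model(..., variables = )`. This mirrors the
screening-then-mining economics of the pipeline and is deliberate.

## Evaluation protocol

`evaluate_model()` runs the full protocol: **100 random class-stratified
80/20 splits** (per-class test count `round(size × 0.2)` — 17 + 5 = 22
held-out subjects at the reference geometry). On each training split an
inner cross-validation (10 repeats of stratified 2-fold; 2 folds keep
enough minority subjects) picks `C` from
`{0.001, 0.01, 0.1, 1, 10, 100}` by mean validation F1, ties to the
smallest `C`. The final `C*` is the most frequent inner choice, and all
splits are re-fit at `C*`. Screening and mining are re-run inside every
fold and split, so no held-out subject ever influences feature
construction.

Reported quantities: mean/sd of **macro F1** (unweighted mean of the two
per-modality F1 scores; a class with no true positives scores 0), mean
complexity, and **Jaccard stability** — the mean pairwise
`|A∩B| / |A∪B|` of the selected feature sets across splits (two empty
sets count as 1). Frequency tables record how often each variable, exact
rule, and interacting variable pair (per modality) recurs, and bin-coverage
maps count rule occurrences per (modality, variable, bin).

Significance uses a **label-permutation test**: the statistic is the mean
test F1 over `n_perm_splits` splits of the *entire* pipeline at fixed
`C*`; it is recomputed for each permuted label vector and the add-one
p-value is `(1 + #{perm ≥ obs}) / (B + 1)`. The default
`n_perm_splits = 5` is a reduced-fidelity statistic chosen for runtime;
set it to `n_splits` for the full version. All randomness derives from
one master seed via sub-seed fan-out (`with_seed` restores the caller's
RNG state), so every report is bit-reproducible.

## Synthetic data: scope and limits

`synthetic_spec()` + `generate_dataset()` produce discretized cohorts with
known ground truth. Class counts are exact (default 86/24). Noise
variables are uniform over the bins independently of class. Two plant
types exist:

* **1D plants**: in the first modality a subject falls in the enriched
  bin range with probability `prob`; the second modality is mirrored into
  the complement. Both directions are therefore minable.
* **2D plants**: with probability `prob` a subject is placed in a corner
  of the low/high quadrant grid of a variable pair. *Balanced* plants put
  the first modality in the agreeing corners (low-low / high-high) and
  the second in the disagreeing ones, so every 1D margin stays uniform in
  both classes — the signal exists only in the interaction and is provably
  invisible to marginal screening. *Unbalanced* plants enrich one corner
  per class and also shift margins. Plants must not share variables, or
  the marginal-balance bookkeeping would be infeasible; the constructor
  refuses.

`generate_spectra()` emulates the upstream continuous data: sums of
Lorentzian peaks with class-dependent amplitude ratios, log-normal
subject-level dilution, multiplicative peak-level variation, additive
baseline noise, truncation at zero. It is a *statistical* emulation for
exercising the preprocessing chain end-to-end — it models neither
chemical-shift variation (peak positions are fixed), nor J-coupling
multiplets, nor pH-dependent shifts, nor correlated metabolite pools.
Conclusions about real spectra should not rest on it.

## Numerical conventions in one place

| Quantity | Convention |
|---|---|
| Bucket intervals | half-open `[left, left + width)`, tolerance 1e-9 at edges |
| Exclusion default | `"contained"` (drop only fully covered buckets) → 184 buckets |
| Median (imputation) | midpoint of central order statistics (`stats::median`) |
| Standard deviation | sample, `n − 1` (`stats::sd`); population available |
| Quantiles | type 7 (R default), duplicate edges merged |
| Bin assignment | `findInterval(..., left.open = TRUE)`: bins are `(q[b−1], q[b]]` |
| z threshold | ≥ 1.96, inclusive |
| Modality size | ≥ 10, inclusive |
| Minimization tie | larger (more general) rule survives |
| Logistic objective | `C·Σ log(1+exp(−t·s)) + ½‖w‖²`, intercept unpenalized |
| Inner-CV tie | smallest `C` |
| `C*` | modal inner choice, smallest at ties |
| Test-set size | `round(class_size × 0.2)` per class |
| F1 | macro; zero-TP class scores 0 |
| Permutation p | add-one, `(1 + #{perm ≥ obs})/(B + 1)` |
| Jaccard of two empty sets | 1 |

## Limitations

* Exhaustive 2D mining over all ~17,000 variable pairs × 3025 candidates
  is feasible (about a minute at the reference geometry) but grows
  quadratically in `p`; the local models bound it via screening.
* The chi-squared screen is marginal, so marginally balanced interactions
  require explicit candidate variables (see above).
* Nominal conditions use 32-bit subset masks, capping nominal variables
  at 31 levels (and enumeration at 6 — beyond that, pre-group).
* The permutation test's reduced statistic (5 splits) trades variance for
  runtime; p-values near the threshold deserve `n_perm_splits = n_splits`.
* No missing-data handling beyond upfront median imputation
  (`impute_median()`) on the continuous scale.

## A minimal session

```{r example}
spec <- synthetic_spec(
  n_buckets = 30,
  planted_1d = list(list(var = 1, range = 1:5, prob = 0.9)))
gen <- generate_dataset(spec, seed = 1)
rs <- mine_rules(gen$dataset)
rs
head(format_rule(rs$rules))

cfg <- evaluation_config(n_splits = 10, c_grid = 1, seed = 1)
evaluate_model(gen$dataset, "local_1d", cfg)
```
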