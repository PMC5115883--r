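# nmrules

Exhaustive supervised rule mining and rule-based classification for
discretized multi-source biomedical data, with a complete ¹H-NMR
metabolomics preprocessing chain, a repeated stratified-holdout evaluation
protocol, and synthetic cohort generators with known ground truth.

## The scientific problem

Urinary NMR metabolomics produces hundreds of correlated spectral
variables per subject. In a typical clinical cohort — here the reference
geometry is 110 subjects, 184 spectral buckets, and an imbalanced binary
outcome (86 subjects with estimated glomerular filtration rate below
60 ml/min/1.73 m², 24 at or above) — the question is
not only *whether* the profile predicts the outcome, but *which readable
statements about it* do. `nmrules` answers with rules of the form

```
{variable: 'bucket 3.16'; condition: bins 1 to 4} -> below60
```

mined **exhaustively** over all contiguous bin ranges of every
quantile-discretized variable (55 conditions per 10-bin variable) and all
condition pairs of every variable pair (3025 per pair), scored by the
one-proportion z-statistic

z = (p̂ᵣ − p₀) / √(p₀(1 − p₀)/nᵣ),

kept when the rule covers at least 10 subjects of its target modality at
z ≥ 1.96, and minimized so that no kept rule is a redundant specialization
or generalization of a better one. Rules become binary features of an
L2-regularized logistic classifier; three model types (screened raw
variables, 1D rules, 1D + 2D rules) are compared by macro F1 over 100
stratified 80/20 resamples, with model complexity, selection stability
(Jaccard), and label-permutation significance reported alongside. Details
and all numerical conventions are in the vignette
(`vignettes/rule-mining-methods.Rmd`).

## Worked example

```r
library(nmrules)

# a synthetic cohort: 110 subjects (86/24), 30 bucket variables,
# one planted marginal signal in bins 1-5 at enrichment 0.9
spec <- synthetic_spec(n_buckets = 30,
  planted_1d = list(list(var = 1, range = 1:5, prob = 0.9)))
gen <- generate_dataset(spec, seed = 1)

rs <- mine_rules(gen$dataset)   # exhaustive 1D + 2D mining, minimized
rs
#> ruleset: 1299 rules (at_least_60=519, below60=780); thresholds: modality size >= 10, z >= 1.96
#>    {variable: 'bucket 0.16'; condition: bins 2 to 5} -> below60 (coverage 61, modality size 59, z 3.51)
#>    {variable: 'bucket 0.16'; condition: bins 6 to 10} -> at_least_60 (coverage 33, modality size 19, z 4.97)
#>    {variable: 'bucket 0.40'; condition: bins 4 to 7} -> at_least_60 (coverage 47, modality size 16, z 2.03)
#>    ...

# the planted variable ('bucket 0.16') tops the list in both directions;
# everything else is the expected z >= 1.96 noise tail of an exhaustive
# search, which is why classification uses screening + resampling:

cfg <- evaluation_config(n_splits = 10, c_grid = 1, seed = 1)
evaluate_model(gen$dataset, "local_1d", cfg)
#> evaluation_report (local_1d, 10 splits)
#>   F1 0.62 +/- 0.14 | complexity 2.0 | C* = 1 (freq 10) | stability 0.44 +/- 0.32
```

Starting from spectra instead of codes:

```r
sp <- generate_spectra(seed = 1)                    # Lorentzian-peak emulation
b  <- bin_spectrum(sp$ppm, sp$signal)               # 0.04 ppm buckets
ds <- preprocess_nmr(b$edges, b$intensity, sp$target)
# exclusion (water/urea) -> 184 buckets, integral normalization to 100,
# pareto scaling, per-bucket decile discretization
```

## Command-line interface

An executable wrapper ships in `inst/cli/nmrules.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","nmrules.R",package="nmrules"))')" \
  simulate --out-data d.csv --out-meta m.csv --out-truth t.jsonl --seed 7
# subcommands: simulate | mine | fit | evaluate | report   (--help for options)
```

Every run writes a JSON log (seed, options, package version) next to its
outputs; `evaluate` emits the summary, per-run, variable-frequency,
bin-coverage and interaction-matrix tables as CSV plus a JSON report.

## License

MIT (see `LICENSE`).
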