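# bbrsm

Box-Behnken response-surface optimization for extraction and assay studies.

Natural-product chemists optimizing an extraction face a common problem:
several process factors (solvent strength, temperature, solid-to-solvent
ratio, time), several competing responses (yield, polyphenol content,
enzyme-inhibition and radical-scavenging rates), and a run budget of a few
dozen experiments. The standard answer is a three-level Box-Behnken design
(BBD) analysed by response-surface methodology (RSM). bbrsm implements that
workflow end to end, in R, with every stage testable against known ground
truth:

* **Design** — BBD construction for 3–7 factors with replicated center
  points, exact coded/natural unit conversion, structural validation.
* **Responses** — extraction yield, total polyphenol content (gallic-acid
  equivalents), enzyme inhibition (PTP-1B, α-glucosidase) and radical
  scavenging (ABTS/DPPH) rates from raw weights and absorbances.
* **Model** — the full second-order polynomial in coded units
  *y* = *b*₀ + Σ*bᵢxᵢ* + Σ*bᵢᵢxᵢ*² + Σ*bᵢⱼxᵢxⱼ*, fitted by OLS, with the
  complete ANOVA: model/residual partition, pure error from the center
  replicates, lack-of-fit F test, R², adjusted R², per-term t tests.
* **Optimization** — exact stationary-point analysis, deterministic
  multi-start box-constrained maximization over the coded cube, and joint
  multi-response optimization via Derringer–Suich desirability.
* **Quantification** — linear calibration, one-point external-standard
  content computation, and RRT/RPA system-suitability RSDs for multi-peak
  chromatograms.
* **Simulation** — seeded generators for every input type with known truth
  (surfaces + Gaussian noise, assay plates, lognormal-noise injections,
  calibration series).

A complete published four-factor study (29 runs, five responses, plus its
12-component UPLC quantification table) ships with the package as
`herbal_extraction_study()` / `herbal_uplc_components()` and is used in the
examples and tests.

## Worked example

```r
library(bbrsm)

study <- herbal_extraction_study()
coded <- code_runs(study$runs, study$factors)
fit <- fit_quadratic(coded[names(study$factors)], coded$yield,
                     response = "yield", factors = study$factors)
rsm_anova(fit)
#> Analysis of variance — response 'yield'
#>       source     ss df    ms     f       p
#>        model 321.42 14 22.96 10.37 <0.0001
#>     residual  31.00 14  2.21    NA    <NA>
#>   pure error   1.17  4  0.29    NA    <NA>
#>  lack of fit  29.83 10  2.98 10.24  0.0192
#>        total 352.41 28    NA    NA    <NA>
#> R2 = 0.9120   adj. R2 = 0.8241
```

The model explains 91% of the variation in yield; the lack-of-fit test
(F = 10.24 against pure error from the five replicated center runs) warns
that the quadratic is not a perfect description of this response, which is
worth knowing before trusting its optimum. Significance flags and the
factor influence ranking follow the coded linear coefficients:

```r
significant_terms(fit)
#> [1] "temperature_c"   "solvent_ratio"   "ethanol_pct^2"
#> [4] "temperature_c^2" "solvent_ratio^2"
influence_ranking(fit)
#> [1] "solvent_ratio" "temperature_c" "ethanol_pct"   "time_h"
#> attr(,"ties")
#> [1] FALSE
```

The whole study — five fits, five single-response optima, and the joint
desirability optimum — runs through one call:

```r
res <- run_pipeline(study$runs, study$factors, out_dir = "analysis")
res$joint
#> <rsm_optimum> value = 0.785
#>   coded:   ethanol_pct = 0.085, temperature_c = 0.135, solvent_ratio = 0.247, time_h = -0.017
#>   natural: ethanol_pct = 51.70, temperature_c = 71.35, solvent_ratio = 22.47, time_h = 2.98
round(res$joint$predictions, 2)
#>  yield    tpc  ptp1b   aglu   abts
#>  39.76  47.73  85.54  96.21  77.39
```

The joint optimum — about 52% ethanol at 71 °C, 1:22 solid-to-solvent, 3 h
— is the single condition that balances all five responses; the
`predictions` are the model values there (e.g. 39.8% yield, 77.4% ABTS
scavenging). `out_dir` receives model JSONs, a markdown ANOVA report,
optima CSVs and a run log.

See the vignette (`vignettes/bbrsm-methods.Rmd`) for the statistical
details, defaults and limitations.

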