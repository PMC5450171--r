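---
title: "Response-surface methods in bbrsm: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface methods in bbrsm: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbrsm)
```

bbrsm analyses three-level Box-Behnken experiments of the kind used to
optimize natural-product extractions: a handful of process factors (solvent
strength, temperature, solid-to-solvent ratio, time), a modest run budget,
and several responses measured per run — gravimetric yield, a colorimetric
polyphenol content, enzyme-inhibition rates, radical-scavenging rates. This
vignette explains the statistical machinery, the defaults, and what the
package's own simulations do and do not demonstrate.

## The design and the coding convention

Every factor is specified by its natural low/center/high levels
(`factor_spec()`), assumed equally spaced; analysis happens in *coded units*

$$x = \frac{\xi - \xi_\mathrm{center}}{(\xi_\mathrm{high} - \xi_\mathrm{low})/2},$$

so the levels map to $-1, 0, +1$. Coding makes coefficients directly
comparable across factors (the basis of the "influence ranking") and keeps
the model matrix well conditioned. `decode_value()` inverts the map exactly;
values beyond $\pm 1$ are permitted — the polynomial extends everywhere —
but flagged, because the fitted surface is only an approximation inside the
design region.

A Box-Behnken design for $k$ factors runs, for each of the $k(k-1)/2$ factor
pairs, the four $(\pm 1, \pm 1)$ combinations with all other factors at
center, plus $n_c$ replicated all-center runs: $2k(k-1) + n_c$ runs in all
(29 for $k = 4$, $n_c = 5$, as in the bundled study). Every coded column
sums to zero and distinct columns are orthogonal; `validate_bbd()` checks
these invariants exactly, since they are integer arithmetic. The package
generates runs in a fixed deterministic order (pairs lexicographic, centers
last). Physical experiments randomize run order to protect against drift;
randomization has no effect on the least-squares fit, so reproducibility of
generated tables was given priority, with an optional seeded shuffle for
users who want randomized work lists.

## The second-order model and its ANOVA

For each response the package fits, by ordinary least squares, the full
second-order polynomial in coded units

$$y = b_0 + \sum_i b_i x_i + \sum_i b_{ii} x_i^2 + \sum_{i<j} b_{ij} x_i x_j
      + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2)\ \text{iid},$$

with $1 + k(k+3)/2$ coefficients (15 for $k=4$). No term selection is
performed. Dropping non-significant terms would change every reported
quantity and is not standard practice in response-surface work, where the
full model is reported with per-term significance flags instead. Per-term
standard errors use the unscaled covariance $(X'X)^{-1}$ times the residual
mean square; two-sided p-values use the $t$ distribution on the residual
degrees of freedom, which for single-degree terms is equivalent to the
partial F test. The default significance level is $\alpha = 0.05$.

The ANOVA (`rsm_anova()`) partitions

$$SS_\mathrm{total} = SS_\mathrm{model} + SS_\mathrm{residual}, \qquad
  SS_\mathrm{residual} = SS_\mathrm{lack\ of\ fit} + SS_\mathrm{pure\ error}.$$

Pure error comes from exact replicate runs — in a BBD, the center points:
$SS_\mathrm{pe} = \sum_g \sum_{r}(y_{gr} - \bar y_g)^2$ over replicate
groups, with $\sum_g (n_g - 1)$ degrees of freedom. It estimates
experimental noise free of any modelling assumption, and the lack-of-fit F
ratio $MS_\mathrm{lof}/MS_\mathrm{pe}$ tests whether the quadratic form is
adequate. With no replicated runs the partition is undefined and the rows
are omitted with a warning rather than silently merged. p-values are always
computed from the exact F distribution, never from printed look-up tables.

```{r anova}
study <- herbal_extraction_study()
coded <- code_runs(study$runs, study$factors)
fit <- fit_quadratic(coded[names(study$factors)], coded$yield,
                     response = "yield", factors = study$factors)
rsm_anova(fit)
```

## Optimization over the design region

The fitted quadratic is cheap to analyse exactly. `stationary_point()`
solves $\nabla y = b + Hx = 0$ (Hessian $H$: $2 b_{ii}$ diagonal, $b_{ij}$
off-diagonal) and classifies the point by the eigenvalue signs; eigenvalues
within $10^{-10}$ of the spectral radius of zero are treated as singular and
reported as "degenerate" rather than inverted. Real multi-response surfaces
are frequently saddles, so the reported optimum is always a *constrained*
optimum over a box, by default the coded cube $[-1,1]^k$ — predictions
outside it extrapolate (the bundled study's alpha-glucosidase surface
already exceeds 100% inhibition at a corner, a reminder that the polynomial
is local).

`maximize_in_box()` uses a deterministic multi-start scheme: every point of
the $\{-1,0,+1\}^k$ lattice (clipped to the box), plus the stationary point
when interior, each polished by box-constrained BFGS with the analytic
gradient. For a quadratic objective in a box this is effectively exhaustive
— the start lattice contains all design points, so the result can never fall
below the best model prediction at a design point, and the tests verify
agreement with a dense grid oracle. No randomness is involved, so results
are exactly reproducible.

Joint optimization of several responses uses Derringer–Suich desirability:
each response is mapped to $d \in [0,1]$ by a power-weighted ramp between
two anchors and the objective is the geometric mean
$D = (\prod d_i)^{1/m}$, which is maximized by the same multi-start scheme
plus a coarse-lattice prescan (the ramps make $D$ only piecewise smooth).
The default anchors are each response's achievable range over the box —
computed exactly by minimizing and maximizing each surface — with goal
"maximize" and weight 1. This "as good as each response can be" default is
deliberately neutral; anchors, goals and weights are all overridable, and
the geometric mean means any response at its worst anchor vetoes the
candidate point. On the bundled study the joint optimum lands at ethanol
51.7%, 71.4 °C, ratio 1:22.5, 3.0 h — essentially the study's reported
joint condition — while the five single-response box optima sit at cube
corners far from it, which is why the package reports both.

## Chromatographic quantification

The UPLC module treats integrated peak tables, not raw signal. Calibration
lines are ordinary least squares with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$
(defined as 0 for constant areas, where the ratio is 0/0); contents are
computed by the one-point external-standard ratio — the procedure actually
used for the bundled component table — with the calibration line used for
linearity and range validation only. Solution volume, dilution and extract
mass are explicit arguments because content in percent w/w is meaningless
without them. System suitability follows pharmacopoeial convention:
relative retention times and relative peak areas against a designated
reference peak, summarized by percent RSD with the sample ($n-1$) standard
deviation. The reference peak's rows are identically zero by construction —
a useful self-check that the report is wired correctly.

## The synthetic-data generators

Each generator draws from the exact error model the corresponding analysis
assumes, with a mandatory seed and no hidden global RNG state:

* `gen_bbd_experiment()`: responses are the true surface plus iid Gaussian
  noise; center replicates share a mean, so pure-error MS estimates
  $\sigma^2$ (verified in the tests by a chi-square expectation check over
  500 seeds).
* `gen_assay_plate()`: sample absorbances $A_c (1 - IR/100) + N(0, sd)$.
* `gen_injections()`: areas multiplied by iid lognormal factors with unit
  mean and specified CV (areas stay positive); retention times jittered with
  Gaussian noise. Note that relative peak areas share the reference-peak
  denominator, which correlates the per-peak RSDs within a report — the
  test oracle for the RSD band models this explicitly.
* `gen_calibration()`: evenly spaced standards on a known line plus Gaussian
  area noise.

These emulate the stochastic structure the estimators assume, which is the
point: they make every stage testable against known truth. They do *not*
emulate heteroscedastic assay noise, absorbance saturation, drift across an
injection sequence, peak-integration errors, or model misspecification
(curvature beyond second order). A passing recovery test therefore
demonstrates that the estimators are correct under their own assumptions,
not that the quadratic model is adequate for any particular real
extraction — that is what the lack-of-fit test is for on real data.

## Simulation sizes and numerical choices

The bundled verification studies use sizes chosen to pin down the relevant
statistics tightly while staying interactive: 200 seeded replicates for
coefficient bias and 95%-interval coverage (bias bounded by three standard
errors of the simulation mean; coverage required in [0.90, 0.99]), 100
seeds for the end-to-end surface-then-optimum recovery study at noise sd
0.8 (matching the bundled study's pure-error scale), 500 seeds for the
pure-error expectation check, and a $21^4$ grid oracle for optimization.

Other numerical conventions, collected in one place:

* Exact-arithmetic invariants (column sums, orthogonality, replicate
  detection) are asserted exactly; least-squares identities at relative
  $10^{-8}$.
* Influence rankings break ties by original factor order and set a `ties`
  attribute with a warning, rather than pretending an order.
* Optimizer results are clamped to the box to remove $10^{-9}$-scale
  excursions from the quadratic-programming polish.
* Reports round coefficients to 2 decimals and $R^2$ to 4, matching the
  conventional presentation; JSON artifacts keep full double precision and
  fixed formatting so reruns are byte-identical.

## Known limitations

* Only Box-Behnken designs are constructed; central-composite,
  Plackett-Burman and optimal designs are out of scope, as are blocking and
  split-plot error structures.
* The model is always the full quadratic: no Box-Cox transforms, ridge
  penalties, or robust loss.
* Desirability is the only multi-response criterion; there is no ridge
  analysis or Pareto enumeration.
* The UPLC module starts from integrated peak tables; peak detection,
  integration and compound identification are upstream of this package.
* The bundled study's published per-response coefficient tables contain a
  small number of internal inconsistencies with its own printed run table
  (sign and value typos in two panels); the package reproduces what the
  printed data support and documents the rest in its test expectations.
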