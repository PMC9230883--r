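---
title: "Total-error validation with accuracy profiles: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-error validation with accuracy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accprof)
```

## The validation model

A quantitative assay is validated on a hierarchical design: `p` independent
series (days), `m` concentration levels, `n` replicates per series and level.
Calibration standards (aqueous) establish the response function of each day;
validation standards (prepared in the sample matrix) are back-calculated
through their own day's fit. At level `j` the back-calculated concentrations
follow, to a good approximation, a one-way random-effects model

> x = mu_j + series effect + replicate error,

with between-series variance sigma2_B and within-series variance sigma2_W.
The method-of-moments (ANOVA) estimates are `MS_within` and
`max(0, (MS_between - MS_within)/n)`; the negative branch of the moment
estimator is truncated at zero, the standard practice that keeps all
downstream formulas well defined.

Total error combines trueness and precision into one question: where will a
*future single measurement* land? The beta-expectation tolerance interval

> bias(%) +/- Q_t(nu; (1+beta)/2) * sqrt(1 + 1/(p n B^2)) * s_R

with `B^2 = (R+1)/(nR+1)`, `R = sigma2_B/sigma2_W`, Satterthwaite-type
fractional degrees of freedom
`nu = (R+1)^2 / ((R + 1/n)^2/(p-1) + (1 - 1/n)/(pn))`, and `s_R` the
intermediate-precision RSD, is expected to contain a proportion `beta` of
future results. The assay is valid over the range where the interval stays
inside the acceptance limits `+/- lambda`.

Two points deserve emphasis because the field's notation is slippery:

* the RSD entering the interval multiplier is the **intermediate-precision**
  RSD (within *plus* between components), not the repeatability RSD — only
  this choice reproduces published interval tables from their bias/s_r/s_R
  rows;
* `nu` is used fractionally; the t quantile is evaluated at the (1+beta)/2
  point without rounding the degrees of freedom.

`beta_eti()` implements the interval, `variance_components()` the ANOVA
estimates, `level_stats()` the per-level assembly, and `accuracy_profile()`
the complete table-to-decision pipeline.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `beta` | proportion of future results the interval should contain | 0.95 | the customary "95% of future results" guarantee |
| `lambda` | acceptance half-width, % relative error | 15 | the usual bioanalytical limit for this kind of assay |
| `p`, `n`, `m` | series, replicates, levels | 3, 3, 5 | the reference design (3 days x 3 replicates x 5 levels) |
| levels | nominal concentrations, ug/mL | 10, 50, 100, 300, 600 | 2-120% of a 500 ug/mL target (top level = 120%) |
| `model` | response function | `ols_linear` | preferred on ties: least transformation, least extrapolation |
| ME band | matrix-effect acceptability | 90-110% | slope-ratio variation attributable to day-to-day error |

## Decision logic

A level passes when its interval lies inside `[-lambda, lambda]`. The LLOQ is
the lowest concentration when the lowest level passes; otherwise the crossing
of the offending interval bound with its limit is interpolated **linearly on
the concentration axis** between the last failing and first passing level
(the ULOQ symmetrically from the top). No interpolation rule is canonical in
the literature; linear-in-concentration is the simplest defensible choice and
is only ever reported when an extreme level fails. When both bounds offend,
the later (more conservative) crossing is used. `lod_from_lloq()` applies the
conventional LOD = LLOQ/3.3; an independent chromatographic route via the
S/N = 3 criterion is available as `lod_from_sn()` — the two answer different
questions (profile-based quantitation floor vs raw detectability) and neither
is privileged.

## Response functions and inverse prediction

Four candidate calibration models are provided. The square-root model
transforms **both** axes (sqrt response on sqrt concentration) — the common
variance-stabilising reading of "regression after square root transformation";
r-squared is reported on the fitting scale. The single-point model averages
the replicate responses at the top design level and forces the origin. The
weighted model uses weights 1/concentration. Back-calculation always inverts
the fit on its own scale, and always through the **same series'** fit — the
day is the blocking unit, and per-day fit tables are what published
validations show. Negative inverse predictions from linear models are
returned as-is with a flag: near the quantitation floor a negative
back-calculated concentration is informative bias, not an error.

`select_response_function()` ranks candidates by (all levels passing, then
smallest maximum absolute interval bound), reports ties, and prefers the
unweighted linear model on exact ties.

## What the synthetic generator emulates — and what it does not

`truth_spec()`/`simulate_validation_dataset()` generate the reference study's
conditions: per-level true biases (+1.1, +3.9, -1.2, -3.0, -4.5%), per-level
within-series CVs (2.1, 2.7, 1.9, 1.5, 1.4%) and between-series CVs derived
as sqrt(s_R^2 - s_r^2) from intermediate-precision CVs (2.6, 3.0, 3.1, 2.4,
2.5%), an aqueous slope of 21.1e3 response units per ug/mL, and beta = 0.95,
lambda = 15%. Errors are multiplicative (relative) Normal on concentration,
matching RSD-denominated reporting; an additive alternative is available
behind the `error_model` flag.

Calibration standards get their own, much tighter error structure: a per-day
slope effect (default CV 0.26%) shared by all of that day's records, plus a
small replicate error (default CV 0.3%). These defaults are calibrated to the
reference assay's printed per-day calibration fits — slopes 21.07/21.13/21.18
x 10^3 (RSD 0.26%), intercepts within a few thousand response units, r-squared
0.9997-1.0000. Giving the calibrants the full validation-standard CVs would
contradict those printed fits and, through the intercept of the unweighted
fit, inflate the lowest level's apparent between-series variance several-fold.
Because the day-slope effect multiplies calibration and validation responses
alike, it cancels exactly in same-day back-calculation, as instrument state
should.

Features of real data the generator does **not** emulate: drift and
carry-over, heteroscedastic detector noise beyond the relative-error model,
day effects on bias (the truth spec allows per-level bias only, constant
across series), non-Normal error tails, and any pH- or matrix-dependent
response curvature. Passing tests therefore demonstrate that the statistics
are computed correctly and recover their generating values — not that any
particular real assay satisfies the model.

A consequence worth knowing: under the reference parameterization the printed
interval at the top level sits close to the -15% limit, so independently
resampled studies produce an all-pass profile only about a third of the time
(each level individually passes with probability roughly 0.75-0.85). A single
observed all-pass validation is entirely consistent with this truth; a
claimed *guarantee* of all-pass would not be.

## Coverage: the defining property

`coverage_experiment()` verifies the interval's defining property: over many
simulated datasets, the average fraction of fresh single results (each with
its own series effect) falling inside the interval equals beta. The
experiment operates on the concentration-scale error model directly — the
interval is a statement about the distribution of back-calculated results,
and the within-day calibration component is shared between calibration and
validation records and cancels in back-calculation. At the reference
parameterization the pooled empirical coverage is within a few tenths of a
percent of 95% (slightly conservative at levels where the between-series
component is small, because the truncated moment estimator never reports a
negative between-series variance; slightly liberal where it dominates).
Monte-Carlo sizes used in the tests and acceptance script — 500 datasets per
level x 200 future draws, and 1000 full-pipeline studies for parameter
recovery — keep the whole suite under a minute while bounding the MC standard
error of coverage near 0.1%.

## Chromatographic and dissolution conventions

* Plates use the EP/USP half-height formula `N = 5.54 (t_R / W_0.5)^2`;
  tailing the USP 5%-height definition `T_f = W_0.05/(2f)`. Both are computed
  from sub-sample linear interpolation of the baseline-corrected trace.
* The baseline is linear between the endpoints of the user's peak window; no
  automatic baseline modelling. Peak bounds sit where the corrected signal
  returns to within 3 x noise.
* S/N uses the pharmacopoeial peak-to-peak convention `2H/h` (RMS variant
  behind a flag). On a noiseless trace S/N is reported as `Inf` with a
  warning rather than an error.
* Simulated peaks are exponentially modified Gaussians parameterised so the
  peak area is invariant in the tail constant `tau`; `tau = 0` gives the pure
  Gaussian, and `tau/sigma` controls the tailing factor monotonically.
* Cumulative dissolution applies the standard withdrawal/replacement
  correction `%_i = 100 (C_i V(t_i) + V_s sum_{j<i} C_j) / dose`, which is
  exact for any sampling schedule, including across the stage change where
  the vessel volume doubles and the concentration halves (mass conserved).
  Replacement is with blank medium. The sample taken at the change time is
  treated as drawn *before* the medium addition (flag
  `sample_before_change`); the correction can be disabled to mimic analyses
  that ignore the ~2%-per-draw loss.
* The curve is not forced monotone — noise legitimately produces small dips —
  but decreases beyond a tolerance raise a warning.

## Numerical choices and degenerate inputs

* Negative between-series moment estimates truncate to zero (R = 0, B = 1).
* When the intermediate-precision RSD is exactly zero the interval
  degenerates to [bias, bias] without evaluating `nu` (avoids 0/0).
* Displayed percentages round half-away-from-zero; all internal computation
  and the JSON report keep full precision (17 significant digits, lossless
  double round-trip).
* Unbalanced tables are *accepted by the readers* and *rejected by the
  profile stage* with the findings from `validate_design()` — the ANOVA
  formulas assume balance, so the failure happens where the math requires it.
* Ties in response-function ranking keep candidate order, putting the
  unweighted linear model first.

## Known limitations

* Beta-expectation intervals only; no beta-content/gamma-confidence
  tolerance intervals, no uncertainty statement on the LLOQ itself, no
  outlier handling.
* The weighted model supports only 1/X weights; no quadratic or 4PL response
  functions.
* Single-analyte chromatograms; no deconvolution of overlapping peaks (a
  second resolved peak in the window triggers a warning and the taller one
  is used).
* No f1/f2 dissolution similarity statistics and no release-kinetics model
  fitting — the dissolution module reduces data, it does not model mechanism.
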