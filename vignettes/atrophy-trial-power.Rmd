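---
title: "Evaluating longitudinal atrophy measures: mixed models, reliability and trial power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating longitudinal atrophy measures: mixed models, reliability and trial power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophytrials)
```

## The problem

Serial structural MRI yields quantitative measures of brain atrophy —
percentage loss of whole-brain, hippocampal or (as expansion) ventricular
volume per year — that are widely used as outcome measures in trials of
disease-modifying therapy for Alzheimer's disease. Measurement techniques
differ, and the practical question when comparing them is: *how many
subjects would a trial need if its outcome were measured with this
technique?* Answering that requires a statistical chain: reliability
checks on intervals too short for real atrophy, mixed models that
decompose rate variability into between- and within-subject components,
a sample-size formula driven by a standardized effect size, and bootstrap
uncertainty for the resulting sample sizes. This package implements that
chain, together with a synthetic-data generator that reproduces the
statistical structure of the study design it was built around, so every
stage can be exercised and calibrated without any imaging data.

## Study design and measurement types

The default `study_design()` describes a two-year observational cohort:
46 Alzheimer's disease (AD) cases and 23 healthy controls seen at 0, 2,
6, 12, 26, 38, 52, 78 and 104 weeks, with two back-to-back scans at the
0-, 6- and 38-week visits. A fully attended schedule therefore has 12
scans and $12 \times 11 / 2 = 66$ unordered scan pairs, 63 of them
spanning distinct visits. Visit weeks convert to years at $7/365.25$.

Two kinds of measurement are modelled:

* **volumes** — one number per scan per structure (an *indirect* route to
  change, by subtracting two volumes);
* **direct changes** — one number per ordered scan pair, produced jointly
  from the registered image pair (boundary-shift-integral-style
  techniques), submitted in both the forward and backward direction.

All change quantities are analysed on the $100\ln(\text{volume})$ scale,
which approximates percent change while being multiplicatively symmetric;
indirect change is $c = 100\ln(V_r/V_b)$ and a direct volume delta enters
as $c = 100\ln((V_b+\Delta V)/V_b)$. Atrophy is negative on this scale;
ventricular expansion is positive.

## Reliability statistics

Over a same-day scan pair or a two-week revisit no measurable atrophy is
expected, so the mean standardized change should be zero; a one-sample
two-tailed t-test (`short_interval_test()`) quantifies bias. For direct
techniques two consistency properties are checked: **symmetry**
(`symmetry_difference()`), the relative disagreement between the forward
change and the negated backward change, and **transitivity**
(`transitivity_difference()`), the relative disagreement between the
direct baseline-to-12-month change and the sum of the chained
baseline-to-6-month and 6-to-12-month changes. Both are ratios against
the signed average change, exactly as defined; when the average change is
numerically zero (common in controls, where true change is small) the
ratio is flagged undefined and excluded with a count, rather than
redefined — outliers are instead tamed by summarizing with the median and
an exact binomial order-statistic confidence interval
(`median_with_ci()`). The order-statistic method was chosen because it is
assumption-free at these small group sizes; for $n < 6$ no 95% interval
exists and the range is reported with a warning.

## The two mixed models

**Repeated volumes.** For one group and structure, with $y_{ijk}$ the
$100\ln$ volume of subject $i$ at visit $j$, scan $k$:

$$y_{ijk} = \alpha_i + (\beta + b_i)\,t_{ij} + d_{ij} + e_{ijk},$$

with fixed subject intercepts $\alpha_i$, fixed mean rate $\beta$
(%/yr), random slopes $b_i \sim N(0,\sigma_b^2)$, random visit effects
$d_{ij} \sim N(0,\sigma_d^2)$ and within-visit scan error
$e_{ijk} \sim N(0,\sigma_e^2)$. The implied variance of a measured
difference over $\Delta t$ years is
$\Delta t^2\sigma_b^2 + 2\sigma_d^2 + 2\sigma_e^2$
(`predict_change_variance()`), and of a rate
$\sigma_b^2 + (2\sigma_d^2 + 2\sigma_e^2)/\Delta t^2$
(`predict_rate_variance()`): the within-subject part shrinks as
$1/\Delta t^2$ while $\sigma_b^2$ is the long-follow-up asymptote. The
aggregate within-subject variance is reported as
$\sigma_w^2 = 2\sigma_d^2 + 2\sigma_e^2$ so that the total rate variance
over $t$ years reads $\sigma_b^2 + \sigma_w^2/t^2$.

**Repeated direct changes.** The measured change $c_p$ over pair $p$
(visits $j_1 \to j_2$, scans $k_1 \to k_2$) is

$$c_p = (\beta + b_i)(t_{ij_2}-t_{ij_1}) - u_{ij_1} + u_{ij_2}
        - v_{ij_1k_1} + v_{ij_2k_2} + w_p,$$

where the random visit effects $u$ and scan effects $v$ enter *signed* —
negative at the pair's start, positive at its end — and are shared by
every pair touching that visit or scan, and $w_p$ is residual pair noise
(the reason direct measures are not perfectly additive, i.e. the source
of intransitivity). `build_pair_covariance()` materializes the implied
cross-pair covariance: entry $(p,q)$ is
$\sigma_b^2\Delta t_p \Delta t_q + \sigma_u^2 s_u(p,q) +
\sigma_v^2 s_v(p,q) + \sigma_w^2 \mathbb{1}[p=q]$ with $s_u, s_v$ the
signed-overlap sums. A same-day pair has variance
$2\sigma_v^2+\sigma_w^2$ (its visit effects cancel); two chained pairs
sharing a visit in opposite roles covary by $-\sigma_u^2$ (and by
$-\sigma_v^2$ more if they share the physical scan). The rate variance is
$\sigma_b^2 + (2\sigma_u^2 + 2\sigma_v^2 + \sigma_w^2)/\Delta t^2$
(`predict_rate_variance_direct()`).

### Estimation

Both models are fitted by **REML** (`fit_volume_model()`,
`fit_direct_model()`). REML rather than ML because the volume model
carries one fixed intercept per subject, and ML variance components would
be biased by that many nuisance parameters. The fixed effects are
profiled out by generalized least squares — for the volume model the
$(m+1)$-dimensional cross-product matrix has an arrow structure (one
intercept per subject plus the common slope) that is exploited blockwise —
and the restricted likelihood is maximized over log variance components
with its analytic gradient (both evaluated in compiled code). Numerical
choices:

* three starting points — a method-of-moments estimate, a tenth and
  tenfold of it — unless a warm start is supplied (bootstrap refits start
  from the full-data estimates, which is what makes thousands of refits
  cheap);
* convergence requires either optimizer-reported convergence at the best
  criterion value or stationarity of the analytic gradient there
  (relative tolerance $10^{-4}$ on the criterion scale); non-convergence
  is flagged, never silent;
* components driven to the lower boundary are truncated to exactly zero
  and flagged (`boundary = TRUE`), mirroring the known failure mode where
  a variance component is estimated at or near zero;
* a constrained variant (`constrain_between = TRUE`) holds
  $\sigma_b^2 = \sigma_d^2 = 0$ (volume) or $\sigma_b^2 = \sigma_u^2 = 0$
  (direct) — the fallback used for control-group models when bootstrap
  resamples fail to converge;
* degenerate inputs (a single subject, all scans at one time, only
  same-day pairs, unstandardized change scales) are rejected with
  diagnoses.

Only forward direct measures enter the fit: backward measures are
near-duplicates of the forward ones (exactly so for symmetric
techniques), and double entry would fabricate precision; they are used
by the symmetry statistic instead. Same-day pairs are retained since
they identify $\sigma_v^2$ and $\sigma_w^2$. Each (structure, group) is
fitted independently. The correctness anchor for both likelihoods is a
brute-force oracle in the test suite: the full dense covariance matrix
assembled entrywise and evaluated through the error-contrast form of the
restricted likelihood, which the blockwise implementation must match to
$10^{-6}$ on random small instances; the analytic gradients are checked
against Richardson-extrapolated differences of that oracle, and the
volume fit is cross-checked against lme4 on a simulated cohort.

## Effect sizes and trial sample sizes

For a two-visit trial (baseline and end of follow-up at $t \in
\{0.5, 1, 2\}$ years) testing a treatment that removes a fraction $f$
(default 25%) of the *excess* atrophy rate over healthy ageing:

$$ES = \frac{\beta_{Case} - \beta_{Control}}
            {\sqrt{\mathrm{Var}(rate_{Case})}}, \qquad
N_{\text{per arm}} = \frac{2\,(1.960 + 0.842)^2}{(f\,|ES|)^2},$$

with $\mathrm{Var}(rate_{Case})$ from the fitted case-group model at
follow-up $t$ (`effect_size()`, `required_sample_size()`,
`power_table()`). The case-group variance alone enters, and the control
model contributes only its mean rate. The printed two-decimal quantiles
1.960 and 0.842 (5% two-sided, 80% power) are the default so the formula
is reproduced literally; `exact_quantiles = TRUE` switches to
full-precision quantiles. Per-arm sizes are rounded up and doubled for
the total — a conservative convention, stated because rounding is
otherwise ambiguous.

## Bootstrap uncertainty and head-to-head comparisons

`bootstrap_effect_size_ci()` resamples subjects with replacement,
stratified by group so every resample keeps the original 46/23 split,
and recomputes the effect size through the full pipeline 2000 times (the
default). Intervals are **BCa**: percentile endpoints adjusted by a bias
correction $z_0$ (normal quantile of the fraction of resamples below the
point estimate) and an acceleration $a$ from a leave-one-*subject*-out
jackknife — the subject, not the observation, is the resampling unit.
Intervals are formed on the effect-size scale, where the bootstrap
distribution is closest to symmetric, and mapped monotonically through
the sample-size formula (the smaller $|ES|$ endpoint gives the larger
$N$). Resamples whose effect size flips sign relative to the point
estimate are counted and flagged, since the magnitude mapping is not
monotone through zero. If more than 1% of resamples fail, the
control-group model is refit in constrained form and the whole run
re-executed; failures persisting after the fallback are dropped from the
BCa computation with their count reported.

`head_to_head()` compares two techniques on the same subjects by the
paired differences in effect-size magnitude over *shared* resample
indices (same seed), declaring a difference significant at the 5% level
when more than 97.5% of paired comparisons favor one side. Ties split
evenly, so a technique against itself sits at exactly 0.5 and can never
be significant.

## The synthetic-data generator

`simulate_volume_dataset()` and `simulate_direct_dataset()` draw from
exactly the generative structures above — nothing more. Defaults encode
the study conditions: the 46/23 design; mean rates inside the published
modelled ranges (AD brain $-1.8$, ventricle $+7.0$, hippocampus $-4.0$
%/yr; controls at the range midpoints, $-0.51$, $+2.3$, $-0.9$);
between-subject and aggregate within-subject variance components from
reported per-technique tables for the AD group (e.g. whole brain
$\sigma_b^2 = 0.47$, $\sigma_w^2 = 0.19$ for a
boundary-shift-integral-style technique; ventricle direct
$\sigma_b^2 = 3.18$, $\sigma_w^2 = 0.82$ for a registration-flux-style
technique). Published tables report only the aggregate within-subject
variance, so a documented convention partitions it —
$2\sigma_d^2 : 2\sigma_e^2 = 0.6 : 0.4$ for volumes and
$2\sigma_u^2 : 2\sigma_v^2 : \sigma_w^2 = 0.5 : 0.3 : 0.2$ for direct
measures — both configurable in `atrophy_preset()`. Variance components
are shared between groups because the published components cover the AD
group only. Baseline levels (brain ~1100 ml, ventricles ~40 ml,
hippocampus ~3 ml) are order-of-magnitude nuisances that do not affect
rate inference. Attendance follows the reported pattern: complete
through 52 weeks, with each subject returning for the 78/104-week visits
with probability one half. Asymmetry noise for non-symmetric techniques
is assumed mean-zero, a choice rather than an established fact.

One master seed spawns an independent RNG substream per subject, so
altering one subject's attendance never perturbs another subject's
draws; and the subject slope $b_i$ is drawn first in both generators, so
volume and direct datasets simulated with the same seed describe the
*same* subjects — which is what makes matched-technique comparisons
meaningful.

What the generator deliberately does **not** emulate: images and
segmentation error mechanisms, scanner drift, non-linear trajectories,
heavy-tailed or outlier-prone measurement error, informative dropout,
and group differences in variance components. Tests passing on this
generator therefore demonstrate that the statistical machinery is
correct under the model's own assumptions — not that the model is
adequate for any particular real technique.

## A worked run

```{r example}
design <- study_design(n_cases = 20, n_controls = 10) # reduced for speed
vols <- simulate_volume_dataset(design, structure = "brain", seed = 1)
fit_ad <- fit_volume_model(vols[vols$group == "AD", ])
fit_hc <- fit_volume_model(vols[vols$group == "control", ])
fit_ad
power_table(fit_ad, fit_hc, structure = "brain", technique = "preset")
```

```{r bootstrap}
boot <- bootstrap_effect_size_ci(vols, es_pipeline("volume", 1),
                                 bootstrap_spec(200, seed = 2))
boot
```

`run_pipeline()` chains every stage (simulate or read, exclusions,
reliability scorecard, fits, power tables, bootstrap) and writes CSV
tables plus a reproducibility manifest; a thin command-line wrapper
around the same functions ships in `inst/cli/atrophytrials.R`.

## Calibration scale and limitations

The test suite fixes its own problem sizes as design choices: Monte-Carlo
variance checks use $10^4$ simulated subjects; parameter recovery uses
200 replicate cohorts of 100 subjects; bootstrap coverage uses 200
cohorts of 12 cases / 6 controls over a three-visit schedule at 500
resamples; the structural direct-vs-indirect comparison averages five
matched cohorts of 100 + 100 subjects, because a single cohort's
control-rate noise can flip the small 24-month difference even when the
variance structure is exactly as designed.

Known limitations, inherited from the framework's scope: only two-visit
trial designs (no interim visits), no missing-data or dropout
adjustment in the sample-size calculation, no joint modelling across
structures, mean-zero Gaussian components throughout, and sample-size
point estimates that depend on using all longitudinal data — so they are
best read comparatively, not as absolute trial budgets.
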