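# atrophytrials

Statistical evaluation of longitudinal brain-atrophy measurement
techniques: reliability statistics, restricted-maximum-likelihood (REML)
linear mixed models for repeated volumes and repeated "direct" change
measures, and clinical-trial sample sizes with BCa bootstrap uncertainty
and head-to-head technique comparisons. It is written for biostatisticians
and imaging methodologists who need to answer, on a common longitudinal
cohort design: *which measurement technique would let a
disease-modification trial enrol the fewest subjects, and how sure are we
of that ranking?*

The default study design mirrors a two-year AD/control cohort: 46
Alzheimer's disease cases and 23 healthy controls, visits at 0, 2, 6, 12,
26, 38, 52, 78 and 104 weeks, with back-to-back scans at three visits —
so a complete subject has 12 scans and 66 scan pairs. A synthetic-data
generator reproduces exactly this statistical structure, so the whole
pipeline is testable without imaging data.

## Models

All analysis is on the `100·ln(volume)` scale (≈ percent change,
multiplicatively symmetric). For one group, repeated volumes follow a
random-slope model with fixed subject effects and random visit/scan
effects:

    y_ijk = α_i + (β + b_i)·t_ij + d_ij + e_ijk,
    b_i ~ N(0, σ_b²),  d_ij ~ N(0, σ_d²),  e_ijk ~ N(0, σ_e²)

so a rate of change measured over Δt years has variance
`σ_b² + (2σ_d² + 2σ_e²)/Δt²`. Repeated direct change measures follow the
signed visit/scan effect model

    c_p = (β + b_i)·Δt_p − u_start + u_end − v_start + v_end + w_p

whose shared, signed `u` (visit) and `v` (scan) effects induce the
covariance between every pair of a subject's measurements, with rate
variance `σ_b² + (2σ_u² + 2σ_v² + σ_w²)/Δt²`. Both models are fitted by
REML with the fixed effects profiled out by generalized least squares and
an analytic criterion gradient (compiled with Rcpp/RcppArmadillo).

Fitted group models feed the trial calculation for a 25% slowing of the
excess atrophy rate over healthy ageing, at 80% power and two-sided 5%
significance:

    ES = (β_Case − β_Control) / sqrt(Var(rate_Case))
    N_per_arm = 2·(1.960 + 0.842)² / (0.25·|ES|)²

with 95% BCa bootstrap confidence intervals (2000 stratified
subject-level resamples, jackknife acceleration) computed on the
effect-size scale and mapped monotonically to sample sizes, and paired
head-to-head comparisons judged significant when more than 97.5% of
shared resamples favor one technique.

## Worked example

```r
library(atrophytrials)

design <- study_design()   # 46 AD / 23 controls, 9 visits, repeats at 0/6/38 wk
vols   <- simulate_volume_dataset(design, structure = "brain", seed = 1)
fit_ad <- fit_volume_model(vols[vols$group == "AD", ])
fit_hc <- fit_volume_model(vols[vols$group == "control", ])
fit_ad
#> Repeated-volume linear mixed model (REML)
#>   mean rate beta: -1.786 %/yr (SE 0.124)
#>   sigma2_b = 0.6592, sigma2_d = 0.05001, sigma2_e = 0.04128  (within sigma2_w = 0.1826)
#>   restricted log-lik -194.0430 | 46 subjects, 510 observations
```

The AD group loses 1.79% of brain volume per year (the generating preset
is −1.8), with between-subject rate variance 0.66 (%/yr)² and aggregate
within-subject variance 0.18 (%)². Turning the two fits into trial sizes:

```r
power_table(fit_ad, fit_hc, structure = "brain", technique = "preset")
#>   structure technique followup_years beta_case beta_control var_rate_case effect_size n_per_arm n_total
#> 1     brain    preset            0.5     -1.79        -0.41         1.390       -1.17       185     370
#> 2     brain    preset            1.0     -1.79        -0.41         0.842       -1.50       112     224
#> 3     brain    preset            2.0     -1.79        -0.41         0.705       -1.64        94     188
```

Sample sizes fall steeply from 6 to 12 months and only modestly from 12
to 24, because the within-subject variance shrinks as `1/Δt²` toward the
between-subject floor. Bootstrap uncertainty for the 12-month trial:

```r
bootstrap_effect_size_ci(vols, es_pipeline("volume", 1),
                         bootstrap_spec(2000, seed = 2))
#> Effect size -1.5 (95% BCa CI -2.041 to -0.9584)
#> Total sample size 224 (95% CI 122 to 548)
#> 0 of 2000 resamples failed
```

`reliability_scorecard()` produces the short-interval / symmetry /
transitivity summaries, `fit_direct_model()` the direct-change analogue,
`head_to_head()` paired technique comparisons, and `run_pipeline()`
chains everything (with CSV outputs and a reproducibility manifest) from
a `run_config()`; a thin CLI wrapper lives in
`inst/cli/atrophytrials.R`.

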