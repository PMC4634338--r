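# Effect sizes and required clinical-trial sample sizes from fitted group
# models, for a two-visit trial (baseline and end of follow-up) testing a
# proportional slowing of the excess atrophy rate relative to healthy
# ageing.

#' Standardized effect size of a disease-modifying treatment
#'
#' `ES = (beta_case - beta_control) / sqrt(var_rate_case)`: the
#' case-control difference in mean rate of change standardized by the
#' standard deviation of the case-group rate at the trial's follow-up
#' interval. The case-group variance alone enters the denominator (the
#' trial's outcome variability is assumed to mimic the patient cohort).
#'
#' @param beta_case,beta_control Mean rates of change, `%/yr`.
#' @param var_rate_case Variance of the case-group rate at the follow-up
#'   interval, `(%/yr)^2` (see [predict_rate_variance()]).
#' @return The signed effect size.
#' @export
effect_size <- function(beta_case, beta_control, var_rate_case) {
  if (any(var_rate_case <= 0)) stop("var_rate_case must be > 0")
  (beta_case - beta_control) / sqrt(var_rate_case)
}

#' Required sample size for a two-arm trial
#'
#' Per-arm sample size for 80% power at a two-sided 5% significance level
#' to detect a treatment that slows the excess rate of change by a
#' fraction `treatment_fraction` (default 25%):
#' `N = 2 * (z_{1-alpha/2} + z_{power})^2 / (treatment_fraction * ES)^2`,
#' with the conventional rounded quantiles 1.960 and 0.842 by default so
#' the printed formula is reproduced literally (set `exact_quantiles` for
#' full-precision normal quantiles). The per-arm size is rounded up to an
#' integer; the total is twice the per-arm size.
#'
#' @param es Effect size (see [effect_size()]); only its magnitude is
#'   used. Must be nonzero.
#' @param treatment_fraction Fractional slowing of the excess rate
#'   attributed to treatment.
#' @param power Target power.
#' @param alpha Two-sided significance level.
#' @param exact_quantiles Use `qnorm(1 - alpha/2)` and `qnorm(power)`
#'   instead of the printed 1.960 / 0.842.
#' @return A list with `n_per_arm`, `n_total`, and the unrounded
#'   `n_unrounded`.
#' @examples
#' required_sample_size(1) # per-arm 252 under the defaults
#' @export
required_sample_size <- function(es, treatment_fraction = 0.25, power = 0.80,
                                 alpha = 0.05, exact_quantiles = FALSE) {
  if (any(es == 0)) stop("effect size must be nonzero")
  if (treatment_fraction <= 0) stop("treatment_fraction must be > 0")
  z <- if (exact_quantiles) qnorm(1 - alpha / 2) + qnorm(power)
       else if (isTRUE(all.equal(c(power, alpha), c(0.80, 0.05)))) 1.960 + 0.842
       else qnorm(1 - alpha / 2) + qnorm(power)
  n <- 2 * z^2 / (treatment_fraction * abs(es))^2
  list(n_per_arm = ceiling(n), n_total = 2 * ceiling(n), n_unrounded = n)
}

#' Trial sample sizes across follow-up durations
#'
#' Combines a fitted case-group model and a fitted control-group model
#' into effect sizes and required sample sizes for two-visit trials of
#' several follow-up durations (default 6, 12 and 24 months). The
#' case-group rate variance at each follow-up comes from the fitted
#' model's variance decomposition ([predict_rate_variance()]); the control
#' model contributes only its mean rate.
#'
#' @param case_fit,control_fit Converged `"volume_lmm"` or `"direct_lmm"`
#'   fits for the case and control groups.
#' @param followups Follow-up durations in years.
#' @param treatment_fraction,power,alpha,exact_quantiles Passed to
#'   [required_sample_size()].
#' @param structure,technique Optional labels carried into the result.
#' @return A data.frame of class `"trial_power"`, one row per follow-up:
#'   `followup_years`, `beta_case`, `beta_control`, `var_rate_case`,
#'   `effect_size`, `n_per_arm`, `n_total`.
#' @export
power_table <- function(case_fit, control_fit, followups = c(0.5, 1, 2),
                        treatment_fraction = 0.25, power = 0.80,
                        alpha = 0.05, exact_quantiles = FALSE,
                        structure = NA_character_,
                        technique = NA_character_) {
  for (f in list(case_fit, control_fit))
    if (!is.null(f$converged) && !f$converged)
      stop("cannot compute sample sizes from a non-converged fit")
  if (any(followups <= 0)) stop("followups must be > 0 years")
  vr <- predict_rate_variance(case_fit, followups)
  es <- effect_size(case_fit$beta_hat, control_fit$beta_hat, vr)
  ns <- lapply(es, required_sample_size, treatment_fraction = treatment_fraction,
               power = power, alpha = alpha, exact_quantiles = exact_quantiles)
  out <- data.frame(structure = structure, technique = technique,
                    followup_years = followups,
                    beta_case = case_fit$beta_hat,
                    beta_control = control_fit$beta_hat,
                    var_rate_case = vr, effect_size = es,
                    n_per_arm = vapply(ns, `[[`, 0, "n_per_arm"),
                    n_total = vapply(ns, `[[`, 0, "n_total"))
  class(out) <- c("trial_power", "data.frame")
  out
}
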