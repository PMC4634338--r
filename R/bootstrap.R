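# Nonparametric bootstrap inference for sample-size estimates: BCa
# confidence intervals on the effect-size scale, mapped monotonically to
# sample-size intervals, and paired head-to-head comparisons between
# techniques over shared resamples.

#' Bootstrap specification
#'
#' @param n_resamples Number of bootstrap resamples (2000 by default).
#' @param seed Seed driving the resample draws (full determinism given
#'   `seed` and `n_resamples`).
#' @param fallback_threshold Fraction of failed resamples above which the
#'   control-group model is refitted in constrained form and the run is
#'   re-executed.
#' @return A list of class `"bootstrap_spec"`.
#' @export
bootstrap_spec <- function(n_resamples = 2000L, seed = 1L,
                           fallback_threshold = 0.01) {
  n_resamples <- as.integer(n_resamples)
  if (is.na(n_resamples) || n_resamples < 1L) stop("n_resamples must be >= 1")
  structure(list(n_resamples = n_resamples, seed = as.integer(seed),
                 fallback_threshold = fallback_threshold),
            class = "bootstrap_spec")
}

.fit_start <- function(fit) {
  if (inherits(fit, "volume_lmm"))
    c(fit$sigma2_b, fit$sigma2_d, fit$sigma2_e)
  else c(fit$sigma2_b, fit$sigma2_u, fit$sigma2_v, fit$sigma2_w)
}

#' Effect-size pipeline for bootstrap resampling
#'
#' Builds the closure that the bootstrap machinery repeatedly applies to
#' resampled datasets: fit the case and control models, predict the
#' case-group rate variance at the requested follow-up, and return the
#' effect size. Returns `NA` on any fit failure or non-convergence (the
#' bootstrap counts these). After the first successful call the fitted
#' variance components are cached and later calls use them as a single
#' warm start, which is what makes thousands of resample refits cheap.
#'
#' @param model `"volume"` (indirect measures) or `"direct"`.
#' @param followup_years Trial follow-up duration in years.
#' @return A function `f(data, constrain_control = FALSE)` mapping a
#'   record data.frame (with a `group` column holding `"AD"` and
#'   `"control"`) to a scalar effect size; `constrain_control` fits the
#'   control group with its between-subject components held at zero.
#' @export
es_pipeline <- function(model = c("volume", "direct"), followup_years = 1) {
  model <- match.arg(model)
  fitfun <- if (model == "volume") fit_volume_model else fit_direct_model
  warm_case <- NULL
  warm_control <- NULL
  f <- function(data, constrain_control = FALSE) {
    tryCatch({
      case <- fitfun(data[data$group == "AD", , drop = FALSE],
                     start = warm_case)
      ctrl <- fitfun(data[data$group == "control", , drop = FALSE],
                     constrain_between = constrain_control,
                     start = if (constrain_control) NULL else warm_control)
      if (!case$converged || !ctrl$converged) return(NA_real_)
      if (is.null(warm_case)) {
        warm_case <<- .fit_start(case)
        if (!constrain_control) warm_control <<- .fit_start(ctrl)
      }
      effect_size(case$beta_hat, ctrl$beta_hat,
                  predict_rate_variance(case, followup_years))
    }, error = function(e) NA_real_)
  }
  attr(f, "respawn") <- function() es_pipeline(model, followup_years)
  f
}

# Pre-draw all resampled subject multisets: stratified by group, each
# resample holding exactly the original number of subjects per group.
.draw_resamples <- function(data, spec) {
  by_group <- lapply(split(data$subject, data$group), unique)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_resamples), function(r)
    lapply(by_group, function(ids) sample(ids, length(ids), replace = TRUE)))
}

# Materialize one resampled dataset; duplicated subjects get distinct ids
# so each draw is a distinct statistical unit.
.resample_data <- function(data, sampled, rows_by_subject) {
  ids <- unlist(sampled, use.names = FALSE)
  new_ids <- make.unique(ids, sep = "#")
  rows <- rows_by_subject[ids]
  out <- data[unlist(rows, use.names = FALSE), , drop = FALSE]
  out$subject <- rep(new_ids, lengths(rows))
  rownames(out) <- NULL
  out
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Computes the BCa interval from a vector of bootstrap statistic values:
#' percentile endpoints adjusted by the bias correction `z0` (normal
#' quantile of the fraction of resamples below the point estimate) and the
#' acceleration `a` (from the jackknife skewness of the statistic). With
#' `z0 = 0` and `accel = 0` the interval reduces to the percentile
#' interval (order-statistic quantiles, type 6).
#'
#' @param theta_star Bootstrap replicate values (`NA` dropped).
#' @param theta_hat Point estimate on the full data.
#' @param theta_jack Jackknife (leave-one-unit-out) estimates; used to
#'   compute the acceleration unless `accel` is supplied.
#' @param conf Confidence level.
#' @param z0,accel Optional overrides of the bias correction and
#'   acceleration.
#' @return A list with `ci` (length-2), `z0`, `accel`.
#' @export
bca_interval <- function(theta_star, theta_hat, theta_jack = NULL,
                         conf = 0.95, z0 = NULL, accel = NULL) {
  ts <- theta_star[is.finite(theta_star)]
  b <- length(ts)
  if (b < 2L) stop("need at least two finite bootstrap values")
  if (all(ts == theta_hat))
    return(list(ci = c(theta_hat, theta_hat), z0 = 0, accel = 0))
  if (is.null(z0)) {
    prop <- mean(ts < theta_hat)
    prop <- min(max(prop, 1 / (b + 1)), b / (b + 1)) # avoid infinite z0
    z0 <- qnorm(prop)
  }
  if (is.null(accel)) {
    if (is.null(theta_jack)) {
      accel <- 0
    } else {
      tj <- theta_jack[is.finite(theta_jack)]
      dev <- mean(tj) - tj
      den <- sum(dev^2)^1.5
      accel <- if (den == 0) 0 else sum(dev^3) / (6 * den)
    }
  }
  alpha <- (1 - conf) / 2
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  ci <- unname(quantile(ts, adj, type = 6, names = FALSE))
  list(ci = ci, z0 = z0, accel = accel)
}

#' BCa confidence interval for an effect size and its sample size
#'
#' Resamples subjects with replacement within disease group (each
#' resample holds the original group sizes), recomputes the effect size
#' through `pipeline`, and forms the 95% BCa interval on the effect-size
#' scale -- the scale on which the bootstrap distribution is closest to
#' symmetric. The acceleration comes from a leave-one-subject-out
#' jackknife (the subject is the resampling unit). The sample-size
#' interval is obtained by mapping effect-size magnitudes through the
#' (monotone) sample-size formula, so the lower `|ES|` endpoint gives the
#' upper sample-size bound. If more than `fallback_threshold` of the
#' resamples fail, the control-group model is refitted in constrained
#' form (between-subject components held at zero) and the whole run is
#' re-executed; persistent failure is reported. Resamples whose sign
#' differs from the point estimate are counted in `sign_flips` (the
#' magnitude mapping is not monotone through zero).
#'
#' @param data Record data.frame with `subject` and `group` columns
#'   (volumes or forward changes, matching the pipeline's model).
#' @param pipeline An [es_pipeline()]-style closure.
#' @param spec A [bootstrap_spec()].
#' @param treatment_fraction,power,alpha,exact_quantiles Passed to
#'   [required_sample_size()] when mapping effect sizes to sample sizes.
#' @return An object of class `"bootstrap_es_ci"`: `es_hat`, `es_ci`,
#'   `n_total_hat`, `n_ci`, `n_failed`, `fallback`, `sign_flips`, `z0`,
#'   `accel`, `spec`.
#' @export
bootstrap_effect_size_ci <- function(data, pipeline, spec = bootstrap_spec(),
                                     treatment_fraction = 0.25, power = 0.80,
                                     alpha = 0.05, exact_quantiles = FALSE) {
  theta_hat <- pipeline(data)
  if (!is.finite(theta_hat))
    stop("pipeline failed on the full dataset")
  rows_by_subject <- split(seq_len(nrow(data)), data$subject)
  draws <- .draw_resamples(data, spec)
  run_all <- function(constrain)
    vapply(draws, function(s)
      pipeline(.resample_data(data, s, rows_by_subject),
               constrain_control = constrain), 0)

  fallback <- FALSE
  theta_star <- run_all(FALSE)
  n_failed <- sum(!is.finite(theta_star))
  if (n_failed / spec$n_resamples > spec$fallback_threshold) {
    fallback <- TRUE
    theta_hat <- pipeline(data, constrain_control = TRUE)
    if (!is.finite(theta_hat))
      stop("pipeline failed on the full dataset under the constrained fallback")
    theta_star <- run_all(TRUE)
    n_failed <- sum(!is.finite(theta_star))
    if (n_failed / spec$n_resamples > spec$fallback_threshold)
      warning("convergence failures persist in ",
              round(100 * n_failed / spec$n_resamples, 2),
              "% of resamples after the constrained fallback")
  }

  subjects <- unique(data$subject)
  theta_jack <- vapply(subjects, function(s)
    pipeline(data[data$subject != s, , drop = FALSE],
             constrain_control = fallback), 0)

  es_ci <- bca_interval(theta_star, theta_hat, theta_jack)
  abs_ci <- bca_interval(abs(theta_star), abs(theta_hat), abs(theta_jack))
  ok <- is.finite(theta_star)
  sign_flips <- sum(sign(theta_star[ok]) != sign(theta_hat))

  nss <- function(es)
    if (es <= 0) Inf
    else required_sample_size(es, treatment_fraction, power, alpha,
                              exact_quantiles)$n_total
  n_ci <- c(nss(abs_ci$ci[2]), nss(abs_ci$ci[1])) # larger |ES| -> smaller N

  structure(list(es_hat = theta_hat, es_ci = es_ci$ci,
                 n_total_hat = nss(abs(theta_hat)), n_ci = n_ci,
                 n_failed = n_failed, fallback = fallback,
                 sign_flips = sign_flips, z0 = es_ci$z0, accel = es_ci$accel,
                 theta_star = theta_star, spec = spec),
            class = "bootstrap_es_ci")
}

#' @export
print.bootstrap_es_ci <- function(x, ...) {
  cat(sprintf("Effect size %.4g (95%% BCa CI %.4g to %.4g)\n",
              x$es_hat, x$es_ci[1], x$es_ci[2]))
  cat(sprintf("Total sample size %s (95%% CI %s to %s)\n",
              format(x$n_total_hat), format(x$n_ci[1]), format(x$n_ci[2])))
  cat(sprintf("%d of %d resamples failed%s%s\n", x$n_failed,
              x$spec$n_resamples,
              if (x$fallback) "; constrained control fallback in effect" else "",
              if (x$sign_flips) sprintf("; %d sign flip(s)", x$sign_flips) else ""))
  invisible(x)
}

#' Paired head-to-head comparison of two techniques
#'
#' Compares two techniques' submissions on the same subjects by the
#' distribution of paired differences in effect-size magnitude over shared
#' bootstrap resamples: both datasets are resampled with identical subject
#' multisets (same seed), the effect size is recomputed for each, and a
#' technique is judged significantly better at the 5% level (two-sided)
#' when more than 97.5% of the paired comparisons favor it. Ties split
#' evenly, so a technique compared with itself sits at exactly 0.5.
#'
#' @param data_a,data_b Record data.frames for the two techniques,
#'   covering identical subject sets.
#' @param pipeline An [es_pipeline()] closure (re-instantiated internally
#'   for each technique so warm starts do not cross datasets).
#' @param spec A [bootstrap_spec()].
#' @param label_a,label_b Technique labels for reporting.
#' @return An object of class `"head_to_head"`: `fraction_favoring_a`,
#'   `significant`, `es_a`, `es_b`, `n_effective`, `n_failed`.
#' @export
head_to_head <- function(data_a, data_b, pipeline, spec = bootstrap_spec(),
                         label_a = "A", label_b = "B") {
  key <- function(d) sort(paste(d$subject, d$group))
  if (!identical(unique(key(data_a)), unique(key(data_b))))
    stop("the two datasets must cover identical subjects")
  respawn <- attr(pipeline, "respawn")
  pipe_a <- if (is.null(respawn)) pipeline else respawn()
  pipe_b <- if (is.null(respawn)) pipeline else respawn()

  es_a <- pipe_a(data_a); es_b <- pipe_b(data_b)
  if (!is.finite(es_a) || !is.finite(es_b))
    stop("pipeline failed on a full dataset")
  rows_a <- split(seq_len(nrow(data_a)), data_a$subject)
  rows_b <- split(seq_len(nrow(data_b)), data_b$subject)
  draws <- .draw_resamples(data_a, spec) # shared resample indices
  star_a <- vapply(draws, function(s)
    pipe_a(.resample_data(data_a, s, rows_a)), 0)
  star_b <- vapply(draws, function(s)
    pipe_b(.resample_data(data_b, s, rows_b)), 0)

  ok <- is.finite(star_a) & is.finite(star_b)
  d <- abs(star_a[ok]) - abs(star_b[ok])
  frac <- (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
  structure(list(label_a = label_a, label_b = label_b,
                 fraction_favoring_a = frac,
                 significant = frac > 0.975 || frac < 0.025,
                 es_a = es_a, es_b = es_b,
                 n_effective = sum(ok), n_failed = sum(!ok), spec = spec),
            class = "head_to_head")
}

#' @export
print.head_to_head <- function(x, ...) {
  cat(sprintf("Head-to-head %s vs %s: %.1f%% of %d paired resamples favor %s\n",
              x$label_a, x$label_b, 100 * x$fraction_favoring_a,
              x$n_effective,
              if (x$fraction_favoring_a >= 0.5) x$label_a else x$label_b))
  cat(if (x$significant) "Difference significant at the 5% level (97.5% rule)\n"
      else "No significant difference (97.5% rule)\n")
  invisible(x)
}
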