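# REML fit of the random-slope model with fixed subject effects and random
# visit/scan effects to repeated volume measurements of one group.

.volume_subject_blocks <- function(records) {
  records$y <- 100 * log(records$volume)
  split_idx <- split(seq_len(nrow(records)), records$subject)
  lapply(split_idx, function(ix) {
    r <- records[ix, ]
    list(t = as.numeric(r$time_years), visit = as.integer(r$visit),
         y = as.numeric(r$y))
  })
}

# Method-of-moments starting values for (sigma2_b, sigma2_d, sigma2_e).
.volume_mom_start <- function(blocks) {
  slopes <- c(); resid_var <- c(); sameday <- c()
  for (b in blocks) {
    if (length(unique(b$t)) >= 2L) {
      fit <- lm(b$y ~ b$t)
      slopes <- c(slopes, coef(fit)[2L])
      if (length(b$y) > 2L) resid_var <- c(resid_var, var(resid(fit)))
    }
    dup <- split(b$y, b$visit)
    dd <- vapply(dup[lengths(dup) == 2L], diff, 0)
    sameday <- c(sameday, dd)
  }
  rv <- if (length(resid_var)) mean(resid_var, na.rm = TRUE) else 1
  se2 <- if (length(sameday) >= 2L) var(sameday) / 2 else rv / 2
  sd2 <- max(rv - se2, 0.1 * rv)
  sb2 <- if (length(slopes) >= 2L) max(var(slopes) - rv, 0.1 * var(slopes)) else 1
  pmax(c(sb2, sd2, se2), 1e-4)
}

#' Fit the repeated-volume linear mixed model by REML
#'
#' Fits, to one group's repeated measurements of one structure, the
#' random-slope model with fixed subject intercepts and random visit and
#' scan effects: on the `100 * ln(volume)` outcome scale,
#' `y_ijk = alpha_i + (beta + b_i) t_ij + d_ij + e_ijk` with
#' `b_i ~ N(0, sigma2_b)`, `d_ij ~ N(0, sigma2_d)`,
#' `e_ijk ~ N(0, sigma2_e)`. The fixed effects (subject intercepts and the
#' mean rate `beta`) are profiled out by generalized least squares and the
#' restricted likelihood is maximized over the log variance components
#' from three starts (method-of-moments, a tenth, tenfold). Components
#' estimated at the lower boundary are truncated to zero and flagged.
#'
#' @param records Scan records for a single group and structure: a
#'   data.frame with columns `subject`, `visit`, `scan`, `volume` and
#'   `time_years` (or `weeks`, converted at 7/365.25).
#' @param constrain_between Hold `sigma2_b = sigma2_d = 0` (the fallback
#'   model used when the full model fails to converge in bootstrap
#'   resamples).
#' @param start Optional named numeric of starting variances
#'   `c(sigma2_b, sigma2_d, sigma2_e)`; when given, a single warm start is
#'   used (bootstrap refits start from the full-data estimates).
#' @return An object of class `"volume_lmm"` with elements `beta_hat`,
#'   `se_beta` (`%/yr`), `sigma2_b`, `sigma2_d`, `sigma2_e`, the aggregate
#'   within-subject variance `sigma2_w = 2*sigma2_d + 2*sigma2_e`,
#'   `alpha_hat` (per-subject intercepts, nuisance), `restricted_loglik`,
#'   `converged`, `boundary`, `n_subjects`, `n_obs`, `constrained`.
#' @seealso [predict_change_variance()], [predict_rate_variance()]
#' @export
fit_volume_model <- function(records, constrain_between = FALSE,
                             start = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("subject", "visit", "volume")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (!"time_years" %in% names(records)) {
    if (!"weeks" %in% names(records))
      stop("records need a time_years or weeks column")
    records$time_years <- records$weeks * 7 / 365.25
  }
  if (any(records$volume <= 0)) stop("volumes must be positive")
  if (length(unique(records$subject)) < 2L)
    stop("need at least two subjects")
  if (length(unique(records$time_years)) < 2L)
    stop("degenerate data: all measurements at the same time")
  if ("group" %in% names(records) && length(unique(records$group)) > 1L)
    stop("fit one group at a time")

  blocks <- .volume_subject_blocks(records)
  m <- length(blocks)

  free <- if (constrain_between) 3L else 1:3
  evalf <- function(lv) {
    s2 <- numeric(3L)
    s2[free] <- exp(lv)
    r <- volume_reml_cpp(blocks, s2[1L], s2[2L], s2[3L])
    if (!r$ok) return(list(crit = 1e10, grad = numeric(length(lv))))
    list(crit = r$crit, grad = (r$grad * s2)[free])
  }
  sv <- if (!is.null(start)) start[free] else .volume_mom_start(blocks)[free]
  opt <- .reml_optimize(evalf, sv, multi_start = is.null(start))
  sigma2 <- numeric(3L); sigma2[free] <- opt$sigma2
  raw <- numeric(3L); raw[free] <- opt$sigma2_raw
  final <- volume_reml_cpp(blocks, raw[1L], raw[2L], raw[3L])
  if (!final$ok) stop("REML evaluation failed at the optimum")

  structure(list(beta_hat = final$beta, se_beta = final$se_beta,
                 sigma2_b = sigma2[1L], sigma2_d = sigma2[2L],
                 sigma2_e = sigma2[3L],
                 sigma2_w = 2 * sigma2[2L] + 2 * sigma2[3L],
                 alpha_hat = setNames(as.numeric(final$alpha), names(blocks)),
                 restricted_loglik = -opt$crit / 2,
                 converged = opt$converged, boundary = opt$boundary,
                 n_subjects = m, n_obs = final$n,
                 constrained = constrain_between),
            class = "volume_lmm")
}

#' @export
print.volume_lmm <- function(x, ...) {
  cat("Repeated-volume linear mixed model (REML)\n")
  cat(sprintf("  mean rate beta: %.4g %%/yr (SE %.3g)\n", x$beta_hat, x$se_beta))
  cat(sprintf("  sigma2_b = %.4g, sigma2_d = %.4g, sigma2_e = %.4g  (within sigma2_w = %.4g)\n",
              x$sigma2_b, x$sigma2_d, x$sigma2_e, x$sigma2_w))
  cat(sprintf("  restricted log-lik %.4f | %d subjects, %d observations%s%s\n",
              x$restricted_loglik, x$n_subjects, x$n_obs,
              if (x$constrained) " | constrained (sigma2_b = sigma2_d = 0)" else "",
              if (x$boundary) " | boundary estimate(s)" else ""))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Model-implied variance of a measured difference
#'
#' For the repeated-volume model, the variance of the difference between
#' two measurements `dt` years apart is
#' `dt^2 * sigma2_b + 2 * sigma2_d + 2 * sigma2_e`.
#'
#' @param fit A `"volume_lmm"` fit (or any list with `sigma2_b`,
#'   `sigma2_d`, `sigma2_e`).
#' @param dt Time between the two measurements in years (`>= 0`);
#'   vectorized.
#' @return Variance of the measured change, `(%)^2`.
#' @export
predict_change_variance <- function(fit, dt) {
  if (any(dt < 0)) stop("dt must be >= 0")
  dt^2 * .comp(fit, "sigma2_b") + 2 * .comp(fit, "sigma2_d") +
    2 * .comp(fit, "sigma2_e")
}

#' Model-implied variance of a rate of change
#'
#' Variance of the rate derived from two measurements `dt` years apart.
#' For the volume model this is
#' `sigma2_b + (2*sigma2_d + 2*sigma2_e) / dt^2`; for the direct-change
#' model `sigma2_b + (2*sigma2_u + 2*sigma2_v + sigma2_w) / dt^2`. The
#' within-subject contribution shrinks as `1/dt^2` with longer follow-up
#' while the between-subject component `sigma2_b` is the `dt -> Inf`
#' asymptote.
#'
#' @param fit A `"volume_lmm"` or `"direct_lmm"` fit (or a plain list with
#'   the matching variance components).
#' @param dt Follow-up time in years (`> 0`); vectorized.
#' @return Variance of the rate, `(%/yr)^2`.
#' @export
predict_rate_variance <- function(fit, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  if (inherits(fit, "direct_lmm") ||
      (!inherits(fit, "volume_lmm") && !is.null(fit$sigma2_u)))
    return(predict_rate_variance_direct(fit, dt))
  .comp(fit, "sigma2_b") +
    (2 * .comp(fit, "sigma2_d") + 2 * .comp(fit, "sigma2_e")) / dt^2
}
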