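# REML fit of the signed visit/scan effect model for repeated direct
# measures of change -- the covariance between any two of a subject's pair
# measurements is induced by the shared subject slope, the shared signed
# visit effects and the shared signed scan effects.

# Signed incidence matrices for one subject's forward pairs.
# Su: pairs x visits with -1 at the start visit and +1 at the end visit
#     (zero row for a same-day pair, where the two cancel);
# Sv: pairs x scans with -1 at the start scan and +1 at the end scan.
.pair_signs <- function(pairs) {
  visits <- sort(unique(c(pairs$start_visit, pairs$end_visit)))
  scans <- unique(rbind(
    data.frame(visit = pairs$start_visit, scan = pairs$start_scan),
    data.frame(visit = pairs$end_visit, scan = pairs$end_scan)))
  scans <- scans[order(scans$visit, scans$scan), ]
  scan_key <- paste(scans$visit, scans$scan, sep = ":")
  np <- nrow(pairs)
  Su <- matrix(0, np, length(visits),
               dimnames = list(NULL, as.character(visits)))
  Sv <- matrix(0, np, length(scan_key), dimnames = list(NULL, scan_key))
  for (p in seq_len(np)) {
    sv <- as.character(pairs$start_visit[p])
    ev <- as.character(pairs$end_visit[p])
    Su[p, sv] <- Su[p, sv] - 1
    Su[p, ev] <- Su[p, ev] + 1
    sk <- paste(pairs$start_visit[p], pairs$start_scan[p], sep = ":")
    ek <- paste(pairs$end_visit[p], pairs$end_scan[p], sep = ":")
    if (sk == ek) stop("a pair's start and end scan coincide")
    Sv[p, sk] <- -1
    Sv[p, ek] <- 1
  }
  list(Su = Su, Sv = Sv)
}

#' Covariance matrix of one subject's direct change measurements
#'
#' Builds the model-implied covariance across a subject's forward pair
#' measurements: entry (p, q) is
#' `sigma2_b * dt_p * dt_q + sigma2_u * <visit sign overlap> +
#'  sigma2_v * <scan sign overlap> + sigma2_w * 1[p = q]`.
#' The diagonal of a distinct-visit pair is
#' `dt^2 sigma2_b + 2 sigma2_u + 2 sigma2_v + sigma2_w`; a same-day pair's
#' visit effects cancel, leaving `2 sigma2_v + sigma2_w`.
#'
#' @param pairs Forward pair rows for one subject: data.frame with columns
#'   `start_visit`, `start_scan`, `end_visit`, `end_scan`,
#'   `delta_t_years`.
#' @param params A [direct_params()] object (or list with the four
#'   variance components).
#' @return A symmetric positive semidefinite matrix, one row/column per
#'   pair.
#' @export
build_pair_covariance <- function(pairs, params) {
  stopifnot(is.data.frame(pairs),
            all(c("start_visit", "start_scan", "end_visit", "end_scan",
                  "delta_t_years") %in% names(pairs)))
  if ("subject" %in% names(pairs) && length(unique(pairs$subject)) > 1L)
    stop("build_pair_covariance operates on a single subject")
  sg <- .pair_signs(pairs)
  dt <- pairs$delta_t_years
  params$sigma2_b * tcrossprod(dt) +
    params$sigma2_u * tcrossprod(sg$Su) +
    params$sigma2_v * tcrossprod(sg$Sv) +
    params$sigma2_w * diag(nrow(pairs))
}

.direct_subject_blocks <- function(records) {
  split_idx <- split(seq_len(nrow(records)), records$subject)
  lapply(split_idx, function(ix) {
    r <- records[ix, ]
    sg <- .pair_signs(r)
    list(dt = as.numeric(r$delta_t_years), Su = sg$Su, Sv = sg$Sv,
         y = as.numeric(r$change))
  })
}

.direct_mom_start <- function(blocks) {
  rates <- c(); mean_rates <- c(); resid <- c()
  for (b in blocks) {
    far <- abs(b$dt) > 0.05
    if (any(far)) {
      rr <- b$y[far] / b$dt[far]
      rates <- c(rates, rr)
      mean_rates <- c(mean_rates, mean(rr))
    }
  }
  beta0 <- if (length(rates)) mean(rates) else 0
  for (b in blocks) resid <- c(resid, b$y - beta0 * b$dt)
  s2 <- max(var(resid), 1e-4)
  sb2 <- if (length(mean_rates) >= 2L)
    max(var(mean_rates), 0.05 * var(rates)) else 1
  pmax(c(sb2, s2 / 3, s2 / 3, s2 / 3), 1e-4)
}

#' Fit the repeated direct-change linear mixed model by REML
#'
#' Fits, to one group's forward direct change measures of one structure,
#' the model `c_p = (beta + b_i) dt_p - u_start + u_end - v_start + v_end
#' + w_p` with `b_i ~ N(0, sigma2_b)` (subject slopes), signed random
#' visit effects `u ~ N(0, sigma2_u)`, signed random scan effects
#' `v ~ N(0, sigma2_v)` and residual pair noise `w ~ N(0, sigma2_w)`. The
#' mean rate `beta` is profiled out by generalized least squares against
#' each subject's cross-pair covariance matrix (see
#' [build_pair_covariance()]) and the restricted likelihood is maximized
#' over the log variance components, with the same multi-start, tolerance
#' and boundary handling as [fit_volume_model()]. Only forward measures
#' enter the fit (backward measures are near-duplicates kept for symmetry
#' assessment); same-day pairs are included since they identify `sigma2_v`
#' and `sigma2_w`.
#'
#' @param records Forward pair-change records for one group and structure:
#'   columns `subject`, `start_visit`, `start_scan`, `end_visit`,
#'   `end_scan`, `delta_t_years`, `change` (on the `100 * ln` scale; see
#'   [read_changes()]). Rows with `direction != "forward"` are dropped.
#' @param constrain_between Hold `sigma2_b = sigma2_u = 0` (the bootstrap
#'   convergence fallback).
#' @param fix_zero Diagnostic constraint: character subset of
#'   `c("b", "u", "v", "w")` naming components held at zero (e.g. `"u"`
#'   for a likelihood-ratio test of the visit effects). Overrides
#'   `constrain_between` when given.
#' @param start Optional starting variances
#'   `c(sigma2_b, sigma2_u, sigma2_v, sigma2_w)` for a single warm start.
#' @return An object of class `"direct_lmm"`: `beta_hat`, `se_beta`,
#'   `sigma2_b`, `sigma2_u`, `sigma2_v`, `sigma2_w`, the aggregate
#'   within-subject variance `sigma2_within = 2*sigma2_u + 2*sigma2_v +
#'   sigma2_w`, `restricted_loglik`, `converged`, `boundary`,
#'   `n_subjects`, `n_pairs`, `constrained`.
#' @export
fit_direct_model <- function(records, constrain_between = FALSE,
                             fix_zero = NULL, start = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("subject", "start_visit", "start_scan", "end_visit", "end_scan",
            "delta_t_years", "change")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if ("direction" %in% names(records))
    records <- records[records$direction == "forward", , drop = FALSE]
  if ("change_kind" %in% names(records)) {
    kind <- unique(records$change_kind)
    if (!identical(kind, "ln"))
      stop("changes must be standardized to the 100*ln scale first ",
           "(see read_changes / c_direct)")
  }
  if ("group" %in% names(records) && length(unique(records$group)) > 1L)
    stop("fit one group at a time")
  tab <- table(records$subject)
  if (length(tab) < 2L || all(tab < 2L))
    stop("need at least two subjects with at least two pairs each")
  if (all(records$delta_t_years == 0))
    stop("rank-deficient design: no distinct-visit pairs, mean rate ",
         "unidentifiable")

  blocks <- .direct_subject_blocks(records)
  comps <- c("b", "u", "v", "w")
  fixed <- if (!is.null(fix_zero)) comps %in% fix_zero
           else if (constrain_between) c(TRUE, TRUE, FALSE, FALSE)
           else rep(FALSE, 4L)
  if (all(fixed)) stop("at least one variance component must be free")
  free <- which(!fixed)

  evalf <- function(lv) {
    s2 <- numeric(4L)
    s2[free] <- exp(lv)
    r <- direct_reml_cpp(blocks, s2[1L], s2[2L], s2[3L], s2[4L])
    if (!r$ok) return(list(crit = 1e10, grad = numeric(length(lv))))
    list(crit = r$crit, grad = (r$grad * s2)[free])
  }
  sv <- if (!is.null(start)) start[free] else .direct_mom_start(blocks)[free]
  opt <- .reml_optimize(evalf, sv, multi_start = is.null(start))
  sigma2 <- numeric(4L); sigma2[free] <- opt$sigma2
  raw <- numeric(4L); raw[free] <- opt$sigma2_raw
  final <- direct_reml_cpp(blocks, raw[1L], raw[2L], raw[3L], raw[4L])
  if (!final$ok) stop("REML evaluation failed at the optimum")

  structure(list(beta_hat = final$beta, se_beta = final$se_beta,
                 sigma2_b = sigma2[1L], sigma2_u = sigma2[2L],
                 sigma2_v = sigma2[3L], sigma2_w = sigma2[4L],
                 sigma2_within = 2 * sigma2[2L] + 2 * sigma2[3L] + sigma2[4L],
                 restricted_loglik = -opt$crit / 2,
                 converged = opt$converged, boundary = opt$boundary,
                 n_subjects = length(blocks), n_pairs = final$n,
                 constrained = constrain_between || !is.null(fix_zero)),
            class = "direct_lmm")
}

#' @export
print.direct_lmm <- function(x, ...) {
  cat("Repeated direct-change linear mixed model (REML)\n")
  cat(sprintf("  mean rate beta: %.4g %%/yr (SE %.3g)\n", x$beta_hat, x$se_beta))
  cat(sprintf("  sigma2_b = %.4g, sigma2_u = %.4g, sigma2_v = %.4g, sigma2_w = %.4g  (within = %.4g)\n",
              x$sigma2_b, x$sigma2_u, x$sigma2_v, x$sigma2_w, x$sigma2_within))
  cat(sprintf("  restricted log-lik %.4f | %d subjects, %d pairs%s%s\n",
              x$restricted_loglik, x$n_subjects, x$n_pairs,
              if (x$constrained) " | constrained" else "",
              if (x$boundary) " | boundary estimate(s)" else ""))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Model-implied rate variance for the direct-change model
#'
#' `sigma2_b + (2*sigma2_u + 2*sigma2_v + sigma2_w) / dt^2`: the variance
#' of a rate of change derived from a single direct measure over `dt`
#' years.
#'
#' @param fit A `"direct_lmm"` fit (or list with `sigma2_b`, `sigma2_u`,
#'   `sigma2_v`, `sigma2_w`).
#' @param dt Follow-up time in years (`> 0`); vectorized.
#' @return Variance of the rate, `(%/yr)^2`.
#' @export
predict_rate_variance_direct <- function(fit, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  .comp(fit, "sigma2_b") +
    (2 * .comp(fit, "sigma2_u") + 2 * .comp(fit, "sigma2_v") +
       .comp(fit, "sigma2_w")) / dt^2
}
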