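# Reliability statistics for atrophy measurement techniques: standardized
# short-interval change, forward/backward symmetry and chain transitivity.
# All standardized changes live on the 100*ln scale, which approximates a
# percent change but is multiplicatively symmetric.

#' Standardized indirect change between two volume measurements
#'
#' `100 * ln(V_r / V_b)`: the change from baseline volume `V_b` to repeat
#' volume `V_r`, standardized by the baseline and log-transformed.
#'
#' @param v_b,v_r Positive volumes (baseline, repeat); vectorized.
#' @return Standardized change in `%` (negative = loss).
#' @export
c_indirect <- function(v_b, v_r) {
  if (any(!is.finite(v_b)) || any(!is.finite(v_r)) ||
      any(v_b <= 0) || any(v_r <= 0))
    stop("volumes must be positive and finite")
  100 * log(v_r / v_b)
}

#' Standardized direct change from a volume delta
#'
#' `100 * ln((V_b + dV) / V_b)` for a direct measure of volume change `dV`
#' over a scan pair starting at baseline volume `V_b`.
#'
#' @param v_b Positive baseline volume; vectorized.
#' @param dv Direct change in the same volume units.
#' @return Standardized change in `%`.
#' @export
c_direct <- function(v_b, dv) {
  if (any(!is.finite(v_b)) || any(v_b <= 0)) stop("baseline volume must be positive")
  if (any(!is.finite(dv)) || any(v_b + dv <= 0))
    stop("implausible change: V_b + dV must be positive")
  100 * log((v_b + dv) / v_b)
}

#' Standardized direct change from a percent change
#'
#' `100 * ln(1 + dV% / 100)`, for techniques that report change as a
#' percentage of the start volume rather than in volume units.
#'
#' @param pct Percent change; must exceed -100.
#' @return Standardized change in `%` on the `100 * ln` scale.
#' @export
c_direct_percent <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= -100))
    stop("percent change must be > -100")
  100 * log1p(pct / 100)
}

#' One-sample test of zero mean short-interval change
#'
#' Over an interval too short for measurable atrophy (a same-day repeat
#' scan, or a two-week revisit) an unbiased technique should show mean
#' standardized change zero; this runs the two-tailed one-sample t-test of
#' that null with a 95% confidence interval.
#'
#' @param changes Numeric vector of standardized changes (`%`); `NA`
#'   dropped. At least two values required.
#' @return A list of class `"short_interval_test"`: `mean_change`, `ci95`,
#'   `t_stat`, `p_value`, `n`.
#' @export
short_interval_test <- function(changes) {
  changes <- changes[!is.na(changes)]
  n <- length(changes)
  if (n < 2L) stop("need at least two changes for a t-test")
  m <- mean(changes)
  if (sd(changes) == 0) {
    # degenerate: all values identical
    res <- list(mean_change = m, ci95 = c(m, m),
                t_stat = if (m == 0) NaN else sign(m) * Inf,
                p_value = if (m == 0) 1 else 0, n = n)
  } else {
    tt <- t.test(changes, mu = 0)
    res <- list(mean_change = m, ci95 = unname(tt$conf.int),
                t_stat = unname(tt$statistic), p_value = tt$p.value, n = n)
  }
  class(res) <- "short_interval_test"
  res
}

#' @export
print.short_interval_test <- function(x, ...) {
  cat(sprintf("Short-interval change: mean %.4g%% (95%% CI %.4g to %.4g), t = %.3g, p = %.3g, n = %d\n",
              x$mean_change, x$ci95[1], x$ci95[2], x$t_stat, x$p_value, x$n))
  invisible(x)
}

.ratio_difference <- function(num, denom, scale, tol = 1e-12) {
  undef <- !is.finite(denom) | abs(denom) < tol * scale | scale == 0
  out <- ifelse(undef, NA_real_, 100 * num / denom)
  n_undef <- sum(undef)
  if (n_undef > 0)
    message(n_undef, " value(s) with near-zero denominator flagged undefined")
  structure(out, n_undefined = n_undef)
}

#' Symmetry difference between forward and backward change measures
#'
#' For a scan pair measured in both directions, the relative disagreement
#' `100 * (fwd - neg_bwd) / (0.5 * (fwd + neg_bwd))`, where `neg_bwd` is
#' the negated backward measure (so a perfectly symmetric technique gives
#' 0 for every pair). Pairs whose signed average change is numerically zero
#' are flagged undefined (`NA`) and counted via the `n_undefined`
#' attribute, rather than producing unbounded ratios.
#'
#' @param fwd Forward change measure(s).
#' @param neg_bwd Negative of the backward measure(s).
#' @param tol Relative tolerance under which the denominator is treated as
#'   zero (against the pair's magnitude scale).
#' @return Percent symmetry differences, `NA` where undefined.
#' @export
symmetry_difference <- function(fwd, neg_bwd, tol = 1e-12) {
  stopifnot(length(fwd) == length(neg_bwd))
  .ratio_difference(fwd - neg_bwd, 0.5 * (fwd + neg_bwd),
                    pmax(abs(fwd), abs(neg_bwd)), tol)
}

#' Transitivity difference of chained direct change measures
#'
#' Compares the direct change over a long interval with the sum of the two
#' chained changes through an intermediate visit:
#' `100 * (c_ac - (c_ab + c_bc)) / (0.5 * (c_ac + c_ab + c_bc))`.
#' A perfectly additive (transitive) technique gives 0.
#'
#' @param c_ac Direct change A to C (e.g. baseline to 12 months).
#' @param c_ab,c_bc Chained changes A to B and B to C.
#' @param tol As in [symmetry_difference()].
#' @return Percent transitivity differences, `NA` where undefined.
#' @export
transitivity_difference <- function(c_ac, c_ab, c_bc, tol = 1e-12) {
  stopifnot(length(c_ac) == length(c_ab), length(c_ab) == length(c_bc))
  .ratio_difference(c_ac - (c_ab + c_bc), 0.5 * (c_ac + c_ab + c_bc),
                    pmax(abs(c_ac), abs(c_ab), abs(c_bc)), tol)
}

#' Median with an exact order-statistic confidence interval
#'
#' Symmetry and transitivity differences can blow up when the underlying
#' true change is near zero, so they are summarized by the median with a
#' 95% confidence interval from the exact binomial order-statistic method
#' (interval `(x_(j), x_(n-j+1))` with `j` the largest order index whose
#' one-sided binomial tail stays below `alpha/2`).
#'
#' @param values Numeric vector; `NA` dropped (count retained).
#' @param conf Confidence level.
#' @return A list of class `"median_ci"`: `median`, `ci95`, `n`,
#'   `n_missing`.
#' @export
median_with_ci <- function(values, conf = 0.95) {
  n_missing <- sum(is.na(values))
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n < 1L) stop("no non-missing values")
  med <- median(x)
  alpha <- (1 - conf) / 2
  if (n == 1L) {
    warning("single value: degenerate confidence interval")
    ci <- c(x, x)
  } else {
    j <- qbinom(alpha, n, 0.5)
    if (pbinom(j - 1, n, 0.5) > alpha) j <- j - 1L # enforce exact tail bound
    if (j < 1L) {
      warning("too few values for nominal coverage; reporting the range")
      j <- 1L
    }
    ci <- c(x[j], x[n - j + 1L])
  }
  structure(list(median = med, ci95 = ci, n = n, n_missing = n_missing),
            class = "median_ci")
}

#' @export
print.median_ci <- function(x, ...) {
  cat(sprintf("median %.4g%% (95%% CI %.4g to %.4g), n = %d\n",
              x$median, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

# Locate the visit index of a target week, NA if not in the schedule.
.visit_at_week <- function(design, week) {
  i <- which(design$visit_weeks == week)
  if (length(i) == 1L) i else NA_integer_
}

.changes_ln <- function(changes) {
  if (!"change_kind" %in% names(changes)) return(changes)
  kind <- unique(changes$change_kind)
  if (length(kind) != 1L) stop("mixed change_kind in records")
  if (kind == "percent") changes$change <- c_direct_percent(changes$change)
  else if (kind != "ln") stop("unknown change_kind: ", kind)
  changes$change_kind <- "ln"
  changes
}

#' Reliability scorecard for one technique
#'
#' Computes, per disease group (and structure), the full set of reliability
#' summaries: mean short-interval change over same-day repeat scans and the
#' two-week revisit (with one-sample t-tests), and median symmetry and
#' transitivity differences (with order-statistic confidence intervals).
#' Short-interval changes are taken from the identified baseline scan
#' (first visit, first scan) to (i) the second same-day baseline scan and
#' (ii) the two-week scan, computed indirectly from `volumes` when given,
#' otherwise from forward rows of `changes`. Symmetry uses the forward and
#' backward measures over the baseline to 52-week pair; transitivity
#' chains baseline to 26 weeks to 52 weeks against the direct baseline to
#' 52-week measure.
#'
#' @param volumes Volume records (see [simulate_volume_dataset()] /
#'   [read_volumes()]), or `NULL`.
#' @param changes Pair-change records (see [simulate_direct_dataset()] /
#'   [read_changes()]), or `NULL`.
#' @param design The [study_design()] the records follow.
#' @return A tidy data.frame with columns `group`, `structure`, `metric`,
#'   `estimate`, `ci_low`, `ci_high`, `n`, `p_value` (`NA` for median
#'   metrics), `n_undefined`.
#' @export
reliability_scorecard <- function(volumes = NULL, changes = NULL,
                                  design = study_design()) {
  if (is.null(volumes) && is.null(changes))
    stop("supply volume records, change records, or both")
  if (!is.null(changes)) changes <- .changes_ln(changes)
  v2 <- .visit_at_week(design, 2)
  v26 <- .visit_at_week(design, 26)
  v52 <- .visit_at_week(design, 52)
  rows <- list()
  add <- function(group, structure, metric, st) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, structure = structure, metric = metric,
      estimate = st$est, ci_low = st$ci[1], ci_high = st$ci[2],
      n = st$n, p_value = st$p, n_undefined = st$n_undef)
  }
  short_row <- function(ch) {
    tt <- short_interval_test(ch)
    list(est = tt$mean_change, ci = tt$ci95, n = tt$n, p = tt$p_value,
         n_undef = 0L)
  }
  med_row <- function(d) {
    # small groups fall back to range CIs; the warning is not useful here
    mc <- suppressWarnings(median_with_ci(d))
    list(est = mc$median, ci = mc$ci95, n = mc$n, p = NA_real_,
         n_undef = attr(d, "n_undefined") %||% sum(is.na(d)))
  }

  src <- if (!is.null(volumes)) volumes else changes
  for (structure in unique(src$structure)) {
    for (group in unique(src$group)) {
      # -- short-interval changes ------------------------------------------
      if (!is.null(volumes)) {
        vg <- volumes[volumes$group == group & volumes$structure == structure, ]
        base <- vg[vg$visit == 1L & vg$scan == 1L, c("subject", "volume")]
        grab <- function(visit, scan) {
          rep_ <- vg[vg$visit == visit & vg$scan == scan,
                     c("subject", "volume")]
          m <- merge(base, rep_, by = "subject")
          c_indirect(m$volume.x, m$volume.y)
        }
        if (1L %in% design$repeat_scan_visits)
          add(group, structure, "short_same_day", short_row(grab(1L, 2L)))
        if (!is.na(v2))
          add(group, structure, "short_two_week", short_row(grab(v2, 1L)))
      } else {
        cg <- changes[changes$group == group &
                        changes$structure == structure &
                        changes$direction == "forward", ]
        grab <- function(ev, ek) {
          cg$change[cg$start_visit == 1L & cg$start_scan == 1L &
                      cg$end_visit == ev & cg$end_scan == ek]
        }
        if (1L %in% design$repeat_scan_visits)
          add(group, structure, "short_same_day", short_row(grab(1L, 2L)))
        if (!is.na(v2))
          add(group, structure, "short_two_week", short_row(grab(v2, 1L)))
      }
      # -- symmetry / transitivity (direct measures only) ------------------
      if (!is.null(changes) && !is.na(v52)) {
        cg <- changes[changes$group == group & changes$structure == structure, ]
        pick <- function(dir, sv, sk, ev, ek) {
          r <- cg[cg$direction == dir & cg$start_visit == sv &
                    cg$start_scan == sk & cg$end_visit == ev &
                    cg$end_scan == ek, c("subject", "change")]
          setNames(r$change, r$subject)
        }
        fwd <- pick("forward", 1L, 1L, v52, 1L)
        bwd <- pick("backward", v52, 1L, 1L, 1L)
        sub <- intersect(names(fwd), names(bwd))
        if (length(sub))
          add(group, structure, "symmetry",
              med_row(symmetry_difference(fwd[sub], -bwd[sub])))
        if (!is.na(v26)) {
          c_ac <- pick("forward", 1L, 1L, v52, 1L)
          c_ab <- pick("forward", 1L, 1L, v26, 1L)
          c_bc <- pick("forward", v26, 1L, v52, 1L)
          sub <- Reduce(intersect, lapply(list(c_ac, c_ab, c_bc), names))
          if (length(sub))
            add(group, structure, "transitivity",
                med_row(transitivity_difference(c_ac[sub], c_ab[sub],
                                                c_bc[sub])))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
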