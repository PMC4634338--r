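# Synthetic longitudinal datasets with the exact generative structure the
# two mixed models assume. All simulation is on the 100*ln(volume) scale;
# raw volumes are obtained by exponentiation.

.subject_ids <- function(design) {
  c(sprintf("AD%02d", seq_len(design$n_cases)),
    sprintf("HC%02d", seq_len(design$n_controls)))
}

.subject_groups <- function(design) {
  c(rep("AD", design$n_cases), rep("control", design$n_controls))
}

# One independent RNG substream per subject: a master seed draws per-subject
# seeds, so changing one subject's attendance (or dropping a subject) never
# perturbs another subject's effects.
.subject_seeds <- function(design, seed) {
  set.seed(seed)
  n <- design$n_cases + design$n_controls
  sample.int(.Machine$integer.max - 1L, n)
}

# Default attendance rule: everyone completes the schedule through 52 weeks;
# each subject returns for the later (> 52-week) visits with probability 1/2.
# Drawn first inside the subject's substream.
.draw_attendance <- function(design) {
  late <- design$visit_weeks > 52
  if (!any(late)) return(rep(TRUE, design$n_visits))
  ifelse(late, runif(1L) < 0.5, TRUE)
}

.check_params_map <- function(params, cls) {
  if (inherits(params, cls)) params <- list(AD = params, control = params)
  if (!is.list(params) || !all(c("AD", "control") %in% names(params)))
    stop("params must be a single ", cls,
         " object or a list with elements 'AD' and 'control'")
  lapply(params[c("AD", "control")], function(p) {
    if (!inherits(p, cls)) stop("params elements must be ", cls, " objects")
    p
  })
}

#' Simulate a repeated-volume dataset
#'
#' Generates one structure's volume measurements for every subject and scan
#' of a study design under the random-slope, random-visit-effect model: on
#' the `100 * ln(volume)` scale,
#' `y = alpha_i + (beta + b_i) t_j + d_j + e_jk`, returning volumes by
#' exponentiation. Deterministic given `seed`, with an independent RNG
#' substream per subject.
#'
#' @param design A [study_design()].
#' @param params A [volume_params()] object (used for both groups) or a
#'   list with elements `AD` and `control`; `NULL` uses
#'   [atrophy_preset()] for `structure`.
#' @param structure Structure label stored in the records (also selects the
#'   preset when `params` is `NULL`).
#' @param attendance Optional logical matrix (subjects x visits, rows named
#'   by subject id) marking attended visits; `NULL` draws attendance from
#'   the default rule (complete through 52 weeks, 50% return later).
#' @param seed Integer master seed.
#' @return A data.frame of scan records with columns `subject`, `group`,
#'   `structure`, `visit`, `scan`, `weeks`, `time_years`, `volume`.
#' @examples
#' vols <- simulate_volume_dataset(study_design(n_cases = 4, n_controls = 2),
#'                                 seed = 1)
#' head(vols)
#' @export
simulate_volume_dataset <- function(design = study_design(), params = NULL,
                                    structure = "brain", attendance = NULL,
                                    seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(params))
    params <- list(AD = atrophy_preset(structure, "AD")$volume,
                   control = atrophy_preset(structure, "control")$volume)
  params <- .check_params_map(params, "volume_params")
  ids <- .subject_ids(design)
  groups <- .subject_groups(design)
  seeds <- .subject_seeds(design, seed)
  t_all <- visit_time_years(design, seq_len(design$n_visits))

  scan_cache <- list() # design_scans keyed by attendance pattern
  n_sub <- length(ids)
  visit_l <- vector("list", n_sub); scan_l <- vector("list", n_sub)
  y_l <- vector("list", n_sub); n_i <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(seeds[i])
    att <- if (is.null(attendance)) .draw_attendance(design)
           else as.logical(attendance[ids[i], ])
    p <- params[[groups[i]]]
    akey <- paste(which(att), collapse = ",")
    sc <- scan_cache[[akey]]
    if (is.null(sc)) sc <- scan_cache[[akey]] <- design_scans(design, which(att))
    # slope drawn first so volume and direct datasets simulated with the
    # same seed share each subject's underlying rate b_i
    b <- rnorm(1L, 0, sqrt(p$sigma2_b))
    alpha <- rnorm(1L, p$alpha_mean, p$alpha_sd)
    d <- setNames(rnorm(sum(att), 0, sqrt(p$sigma2_d)), which(att))
    e <- rnorm(nrow(sc), 0, sqrt(p$sigma2_e))
    y_l[[i]] <- alpha + (p$beta + b) * t_all[sc$visit] +
      unname(d[as.character(sc$visit)]) + e
    visit_l[[i]] <- sc$visit; scan_l[[i]] <- sc$scan; n_i[i] <- nrow(sc)
  }
  visit <- unlist(visit_l, use.names = FALSE)
  res <- data.frame(subject = rep(ids, n_i), group = rep(groups, n_i),
                    structure = structure, visit = visit,
                    scan = unlist(scan_l, use.names = FALSE),
                    weeks = design$visit_weeks[visit],
                    time_years = t_all[visit],
                    volume = exp(unlist(y_l, use.names = FALSE) / 100))
  rownames(res) <- NULL
  res
}

#' Simulate a repeated direct-change dataset
#'
#' Generates forward and backward direct change measures for every scan
#' pair of every subject under the signed visit/scan effect model: on the
#' `100 * ln` scale the forward change over pair `p` is
#' `c_p = (beta + b_i) dt_p - u_start + u_end - v_start + v_end + w_p`,
#' with one visit effect `u` per attended visit, one scan effect `v` per
#' scan and one residual `w` per unordered pair (shared `u`/`v` induce the
#' cross-pair covariance structure). The backward measure is
#' `-forward + N(0, symmetry_noise_sd^2)`; a symmetric technique
#' (`symmetry_noise_sd = 0`) returns the exact negation.
#'
#' @inheritParams simulate_volume_dataset
#' @param params A [direct_params()] object or an `AD`/`control` list;
#'   `NULL` uses [atrophy_preset()].
#' @param change_kind Scale on which the `change` column is emitted:
#'   `"ln"` (the `100 * ln` change itself, default) or `"percent"`
#'   (`100 * (exp(c/100) - 1)`).
#' @return A data.frame of pair-change records with columns `subject`,
#'   `group`, `structure`, `start_visit`, `start_scan`, `end_visit`,
#'   `end_scan`, `delta_t_years`, `direction`, `change`, `change_kind`.
#'   Backward rows have start and end swapped relative to the forward row
#'   for the same unordered pair.
#' @export
simulate_direct_dataset <- function(design = study_design(), params = NULL,
                                    structure = "brain", attendance = NULL,
                                    seed = 1L, change_kind = c("ln", "percent")) {
  stopifnot(inherits(design, "study_design"))
  change_kind <- match.arg(change_kind)
  if (is.null(params))
    params <- list(AD = atrophy_preset(structure, "AD")$direct,
                   control = atrophy_preset(structure, "control")$direct)
  params <- .check_params_map(params, "direct_params")
  ids <- .subject_ids(design)
  groups <- .subject_groups(design)
  seeds <- .subject_seeds(design, seed)
  t_all <- visit_time_years(design, seq_len(design$n_visits))

  pair_cache <- list() # enumerated pairs keyed by attendance pattern
  n_sub <- length(ids)
  pr_l <- vector("list", n_sub); cf_l <- vector("list", n_sub)
  cb_l <- vector("list", n_sub); n_i <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(seeds[i])
    att <- if (is.null(attendance)) .draw_attendance(design)
           else as.logical(attendance[ids[i], ])
    p <- params[[groups[i]]]
    akey <- paste(which(att), collapse = ",")
    cached <- pair_cache[[akey]]
    if (is.null(cached)) {
      sc <- design_scans(design, which(att))
      pr <- enumerate_pairs(sc, include_same_day = TRUE)
      cached <- pair_cache[[akey]] <- list(sc = sc, pr = pr)
    }
    sc <- cached$sc; pr <- cached$pr
    if (nrow(pr) == 0L) next

    b <- rnorm(1L, 0, sqrt(p$sigma2_b))
    u <- setNames(rnorm(sum(att), 0, sqrt(p$sigma2_u)), which(att))
    scan_key <- paste(sc$visit, sc$scan, sep = ":")
    v <- setNames(rnorm(nrow(sc), 0, sqrt(p$sigma2_v)), scan_key)
    w <- rnorm(nrow(pr), 0, sqrt(p$sigma2_w))

    dt <- t_all[pr$end_visit] - t_all[pr$start_visit]
    cf <- (p$beta + b) * dt -
      u[as.character(pr$start_visit)] + u[as.character(pr$end_visit)] -
      v[paste(pr$start_visit, pr$start_scan, sep = ":")] +
      v[paste(pr$end_visit, pr$end_scan, sep = ":")] + w
    cb <- -cf + rnorm(nrow(pr), 0, p$symmetry_noise_sd)
    pr_l[[i]] <- pr; cf_l[[i]] <- unname(cf); cb_l[[i]] <- unname(cb)
    n_i[i] <- nrow(pr)
  }
  keep <- n_i > 0L
  pr_all <- do.call(rbind, pr_l[keep])
  sv <- pr_all$start_visit; sk <- pr_all$start_scan
  ev <- pr_all$end_visit; ek <- pr_all$end_scan
  dt_all <- t_all[ev] - t_all[sv]
  subj <- rep(ids[keep], n_i[keep]); grp <- rep(groups[keep], n_i[keep])
  res <- rbind(
    data.frame(subject = subj, group = grp, structure = structure,
               start_visit = sv, start_scan = sk, end_visit = ev,
               end_scan = ek, delta_t_years = dt_all, direction = "forward",
               change = unlist(cf_l[keep], use.names = FALSE)),
    data.frame(subject = subj, group = grp, structure = structure,
               start_visit = ev, start_scan = ek, end_visit = sv,
               end_scan = sk, delta_t_years = -dt_all,
               direction = "backward",
               change = unlist(cb_l[keep], use.names = FALSE)))
  # interleave so each subject's forward rows precede its backward rows
  res <- res[order(match(res$subject, ids)), ]
  rownames(res) <- NULL
  if (change_kind == "percent") res$change <- 100 * expm1(res$change / 100)
  res$change_kind <- change_kind
  res
}
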