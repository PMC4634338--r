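# Brute-force oracles, independent of the package's blockwise REML path:
# full dense covariance matrices assembled entrywise from the model
# definitions, with the restricted likelihood evaluated through the
# error-contrast formulation (orthonormal basis K of the null space of X',
# likelihood of K'y ~ N(0, K'VK)). The contrast criterion differs from the
# profiled criterion by the constant log|X'X|, which is added back for
# comparison.

oracle_volume_crit <- function(records, sb2, sd2, se2) {
  records <- records[order(records$subject, records$visit, records$scan), ]
  y <- 100 * log(records$volume)
  n <- nrow(records)
  subj <- records$subject
  vis <- records$visit
  tt <- records$time_years
  V <- matrix(0, n, n)
  for (r in seq_len(n)) {
    for (s in seq_len(n)) {
      if (subj[r] == subj[s]) {
        v <- sb2 * tt[r] * tt[s]
        if (vis[r] == vis[s]) v <- v + sd2
        if (r == s) v <- v + se2
        V[r, s] <- v
      }
    }
  }
  X <- cbind(stats::model.matrix(~ 0 + factor(subj)), tt)
  oracle_contrast_crit(y, V, X)
}

oracle_direct_crit <- function(records, sb2, su2, sv2, sw2) {
  records <- records[order(records$subject, records$start_visit,
                           records$start_scan, records$end_visit,
                           records$end_scan), ]
  n <- nrow(records)
  sgn_v <- function(p, j) # signed visit membership of pair p
    (records$end_visit[p] == j) - (records$start_visit[p] == j)
  sgn_s <- function(p, key)
    (paste(records$end_visit[p], records$end_scan[p]) == key) -
    (paste(records$start_visit[p], records$start_scan[p]) == key)
  V <- matrix(0, n, n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (records$subject[p] == records$subject[q]) {
        v <- sb2 * records$delta_t_years[p] * records$delta_t_years[q]
        for (j in unique(c(records$start_visit[p], records$end_visit[p],
                           records$start_visit[q], records$end_visit[q])))
          v <- v + su2 * sgn_v(p, j) * sgn_v(q, j)
        keys <- unique(c(paste(records$start_visit[p], records$start_scan[p]),
                         paste(records$end_visit[p], records$end_scan[p]),
                         paste(records$start_visit[q], records$start_scan[q]),
                         paste(records$end_visit[q], records$end_scan[q])))
        for (k in keys) v <- v + sv2 * sgn_s(p, k) * sgn_s(q, k)
        if (p == q) v <- v + sw2
        V[p, q] <- v
      }
    }
  }
  X <- cbind(records$delta_t_years)
  oracle_contrast_crit(records$change, V, X)
}

oracle_contrast_crit <- function(y, V, X) {
  n <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  KVK <- t(K) %*% V %*% K
  z <- drop(t(K) %*% y)
  crit_contrast <- (n - p) * log(2 * pi) +
    as.numeric(determinant(KVK)$modulus) +
    drop(t(z) %*% solve(KVK, z))
  # translate to the profiled-criterion convention:
  # log|K'VK| = log|V| + log|X'V^-1 X| - log|X'X| for orthonormal K
  crit_contrast + as.numeric(determinant(t(X) %*% X)$modulus)
}

# Entrywise oracle for a single subject's cross-pair covariance.
oracle_pair_cov <- function(pairs, sb2, su2, sv2, sw2) {
  n <- nrow(pairs)
  sgn_v <- function(p, j)
    (pairs$end_visit[p] == j) - (pairs$start_visit[p] == j)
  sgn_s <- function(p, key)
    (paste(pairs$end_visit[p], pairs$end_scan[p]) == key) -
    (paste(pairs$start_visit[p], pairs$start_scan[p]) == key)
  all_visits <- unique(c(pairs$start_visit, pairs$end_visit))
  all_scans <- unique(c(paste(pairs$start_visit, pairs$start_scan),
                        paste(pairs$end_visit, pairs$end_scan)))
  V <- matrix(0, n, n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      v <- sb2 * pairs$delta_t_years[p] * pairs$delta_t_years[q]
      for (j in all_visits) v <- v + su2 * sgn_v(p, j) * sgn_v(q, j)
      for (k in all_scans) v <- v + sv2 * sgn_s(p, k) * sgn_s(q, k)
      if (p == q) v <- v + sw2
      V[p, q] <- v
    }
  }
  V
}

# Small random fixtures -------------------------------------------------

random_volume_instance <- function(seed, n_subjects = 5L) {
  withr::local_seed(seed)
  design <- study_design(visit_weeks = c(0, 2, 6, 26, 52),
                         repeat_scan_visits = c(1L, 3L),
                         n_cases = n_subjects, n_controls = 1L)
  att <- matrix(TRUE, n_subjects + 1L, design$n_visits)
  rownames(att) <- c(sprintf("AD%02d", seq_len(n_subjects)), "HC01")
  # random incomplete attendance (keep >= 3 visits each)
  for (i in seq_len(n_subjects))
    att[i, sample(2:design$n_visits, sample(0:2, 1))] <- FALSE
  pars <- volume_params(beta = runif(1, -3, -1), sigma2_b = runif(1, 0.2, 1),
                        sigma2_d = runif(1, 0.02, 0.2),
                        sigma2_e = runif(1, 0.02, 0.2))
  vols <- simulate_volume_dataset(design, pars, attendance = att,
                                  seed = seed + 1000L)
  vols[vols$group == "AD", ]
}

random_direct_instance <- function(seed, n_subjects = 4L) {
  withr::local_seed(seed)
  design <- study_design(visit_weeks = c(0, 6, 26, 52),
                         repeat_scan_visits = 1L,
                         n_cases = n_subjects, n_controls = 1L)
  pars <- direct_params(beta = runif(1, -3, -1), sigma2_b = runif(1, 0.2, 1),
                        sigma2_u = runif(1, 0.02, 0.2),
                        sigma2_v = runif(1, 0.02, 0.2),
                        sigma2_w = runif(1, 0.02, 0.2))
  ch <- simulate_direct_dataset(design, pars, seed = seed + 2000L)
  ch[ch$group == "AD" & ch$direction == "forward", ]
}
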