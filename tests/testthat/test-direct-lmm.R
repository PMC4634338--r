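test_that("pair covariance matches hand-computed entries and the entrywise oracle", {
  pars <- direct_params(beta = -2, sigma2_b = 1, sigma2_u = 0.3,
                        sigma2_v = 0.1, sigma2_w = 0.05)
  one <- data.frame(start_visit = 1L, start_scan = 1L, end_visit = 2L,
                    end_scan = 1L, delta_t_years = 1)
  expect_equal(build_pair_covariance(one, pars)[1, 1], 1.85) # 1 + .6 + .2 + .05

  # chained pairs sharing visit 2 in opposite roles but through different
  # scans (visit 2 is a repeat-scan visit): slope overlap minus visit overlap
  chain <- data.frame(start_visit = 1:2, start_scan = c(1L, 2L),
                      end_visit = 2:3, end_scan = 1L,
                      delta_t_years = c(1, 1))
  V <- build_pair_covariance(chain, pars)
  expect_equal(V[1, 2], 1 - 0.3) # no shared scan, so no sigma2_v term
  expect_equal(V[1, 1], 1.85)
  # same chain through one shared physical scan also loses sigma2_v
  chain$start_scan[2] <- 1L
  expect_equal(build_pair_covariance(chain, pars)[1, 2], 1 - 0.3 - 0.1)

  same_day <- data.frame(start_visit = 1L, start_scan = 1L, end_visit = 1L,
                         end_scan = 2L, delta_t_years = 0)
  expect_equal(build_pair_covariance(same_day, pars)[1, 1],
               2 * 0.1 + 0.05) # visit effects cancel

  # random instances: equality with the entrywise oracle, symmetry, PSD
  for (seed in c(5, 17)) {
    ch <- random_direct_instance(seed)
    pr <- ch[ch$subject == ch$subject[1], ]
    V <- build_pair_covariance(pr, pars)
    expect_equal(V, oracle_pair_cov(pr, 1, 0.3, 0.1, 0.05))
    expect_equal(V, t(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("empirical cross-pair covariances match the covariance builder", {
  d <- study_design(visit_weeks = c(0, 26, 52), repeat_scan_visits = 1L,
                    n_cases = 20000L, n_controls = 1L)
  pars <- direct_params(beta = -2, sigma2_b = 1, sigma2_u = 0.3,
                        sigma2_v = 0.1, sigma2_w = 0.05)
  ch <- simulate_direct_dataset(d, pars, seed = 21)
  fwd <- ch[ch$group == "AD" & ch$direction == "forward", ]
  sub1 <- fwd[fwd$subject == sort(unique(fwd$subject))[1], ]
  V_model <- build_pair_covariance(sub1[, c("start_visit", "start_scan",
                                            "end_visit", "end_scan",
                                            "delta_t_years")], pars)
  # empirical covariance across subjects of the pair-measurement vector
  key <- paste(fwd$start_visit, fwd$start_scan, fwd$end_visit, fwd$end_scan)
  keys <- paste(sub1$start_visit, sub1$start_scan, sub1$end_visit,
                sub1$end_scan)
  M <- sapply(keys, function(k) fwd$change[key == k])
  V_emp <- cov(M)
  n <- nrow(M)
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      se <- sqrt((V_model[i, i] * V_model[j, j] + V_model[i, j]^2) / (n - 1))
      expect_lt(abs(V_emp[i, j] - V_model[i, j]), 3.5 * se)
    }
  }
})

test_that("direct REML criterion matches the brute-force oracle", {
  for (seed in c(12, 29)) {
    ch <- random_direct_instance(seed)
    withr::local_seed(seed + 1)
    for (rep in 1:2) {
      s2 <- c(runif(1, 0.2, 1), runif(1, 0.02, 0.2), runif(1, 0.02, 0.2),
              runif(1, 0.02, 0.2))
      impl <- atrophytrials:::direct_reml_cpp(
        atrophytrials:::.direct_subject_blocks(ch), s2[1], s2[2], s2[3], s2[4])
      expect_true(impl$ok)
      expect_equal(impl$crit,
                   oracle_direct_crit(ch, s2[1], s2[2], s2[3], s2[4]),
                   tolerance = 1e-6)
    }
  }
})

test_that("direct gradient matches Richardson differences of the oracle", {
  ch <- random_direct_instance(33)
  blocks <- atrophytrials:::.direct_subject_blocks(ch)
  s2 <- c(0.5, 0.05, 0.03, 0.04)
  r <- atrophytrials:::direct_reml_cpp(blocks, s2[1], s2[2], s2[3], s2[4])
  crit <- function(v) oracle_direct_crit(ch, v[1], v[2], v[3], v[4])
  fd <- vapply(1:4, function(k) {
    h <- 1e-3 * s2[k]
    pert <- function(dd) { v <- s2; v[k] <- v[k] + dd; crit(v) }
    d1 <- (pert(h) - pert(-h)) / (2 * h)
    d2 <- (pert(h / 2) - pert(-h / 2)) / h
    (4 * d2 - d1) / 3
  }, 0)
  expect_equal(as.numeric(r$grad), fd, tolerance = 1e-7)
})

test_that("noise-free direct data recover the exact rate", {
  d <- study_design(visit_weeks = c(0, 26, 52), repeat_scan_visits = 1L,
                    n_cases = 5L, n_controls = 1L)
  pars <- direct_params(beta = -2, sigma2_b = 0, sigma2_u = 0, sigma2_v = 0,
                        sigma2_w = 0)
  ch <- simulate_direct_dataset(d, pars, seed = 3)
  fit <- fit_direct_model(ch[ch$group == "AD", ])
  expect_equal(fit$beta_hat, -2, tolerance = 1e-6)
  expect_identical(c(fit$sigma2_u, fit$sigma2_v, fit$sigma2_w), c(0, 0, 0))
  expect_true(fit$boundary)
})

test_that("random visit effects are identifiable by likelihood ratio", {
  d <- study_design(n_cases = 40L, n_controls = 2L)
  pars <- atrophy_preset("ventricle", "AD")$direct
  expect_gt(pars$sigma2_u, 0)
  rejections <- 0L
  for (rep in 1:5) {
    ch <- simulate_direct_dataset(d, pars, seed = 100 + rep)
    fwd <- ch[ch$group == "AD" & ch$direction == "forward", ]
    full <- fit_direct_model(fwd)
    no_u <- fit_direct_model(fwd, fix_zero = "u")
    lr <- 2 * (full$restricted_loglik - no_u$restricted_loglik)
    expect_gte(lr, -1e-6)
    # 5% critical value for the 0.5*chisq(0) + 0.5*chisq(1) boundary mixture
    if (lr > qchisq(0.90, df = 1)) rejections <- rejections + 1L
  }
  expect_gte(rejections, 4L)
})

test_that("input validation catches rank deficiency and unscaled changes", {
  d <- study_design(visit_weeks = c(0, 52), repeat_scan_visits = c(1L, 2L),
                    n_cases = 4L, n_controls = 2L)
  ch <- simulate_direct_dataset(d, seed = 4)
  ad <- ch[ch$group == "AD" & ch$direction == "forward", ]
  only_sd <- ad[ad$start_visit == ad$end_visit, ] # two same-day pairs each
  expect_error(fit_direct_model(only_sd), "rank-deficient")
  pct <- ad; pct$change_kind <- "percent"
  expect_error(fit_direct_model(pct), "100\\*ln")
  expect_error(fit_direct_model(ad[ad$subject == "AD01", ]), "two subjects")
  expect_error(fit_direct_model(ad, fix_zero = c("b", "u", "v", "w")),
               "at least one")
})

test_that("direct rate variance follows its decomposition and beats a noisier indirect fit", {
  fake <- list(sigma2_b = 1, sigma2_u = 0.3, sigma2_v = 0.1, sigma2_w = 0.05)
  expect_equal(predict_rate_variance_direct(fake, 1), 1.85)
  expect_equal(predict_rate_variance_direct(fake, 1e6), 1, tolerance = 1e-9)
  # halving dt quadruples the within-subject contribution
  w1 <- predict_rate_variance_direct(fake, 1) - 1
  w05 <- predict_rate_variance_direct(fake, 0.5) - 1
  expect_equal(w05, 4 * w1)
  # dispatch through the generic entry point
  expect_equal(predict_rate_variance(fake, 1), 1.85)
  # smaller visit/scan noise than an indirect decomposition implies smaller
  # rate variance at every follow-up
  vol <- list(sigma2_b = 1, sigma2_d = 0.4, sigma2_e = 0.2)
  dts <- c(0.5, 1, 2)
  expect_true(all(predict_rate_variance_direct(fake, dts) <
                    predict_rate_variance(vol, dts)))
})
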