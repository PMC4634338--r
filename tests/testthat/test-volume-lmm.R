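test_that("REML criterion matches the brute-force error-contrast oracle", {
  for (seed in c(11, 23)) {
    rec <- random_volume_instance(seed)
    withr::local_seed(seed + 1)
    for (rep in 1:2) {
      s2 <- c(runif(1, 0.2, 1), runif(1, 0.02, 0.2), runif(1, 0.02, 0.2))
      impl <- atrophytrials:::volume_reml_cpp(
        atrophytrials:::.volume_subject_blocks(rec), s2[1], s2[2], s2[3])
      expect_true(impl$ok)
      expect_equal(impl$crit, oracle_volume_crit(rec, s2[1], s2[2], s2[3]),
                   tolerance = 1e-6)
    }
  }
})

test_that("analytic criterion gradient matches Richardson differences of the oracle", {
  rec <- random_volume_instance(31)
  blocks <- atrophytrials:::.volume_subject_blocks(rec)
  s2 <- c(0.4, 0.06, 0.04)
  r <- atrophytrials:::volume_reml_cpp(blocks, s2[1], s2[2], s2[3])
  crit <- function(v) oracle_volume_crit(rec, v[1], v[2], v[3])
  fd <- vapply(1:3, function(k) {
    h <- 1e-3 * s2[k]
    pert <- function(dd) { v <- s2; v[k] <- v[k] + dd; crit(v) }
    d1 <- (pert(h) - pert(-h)) / (2 * h)
    d2 <- (pert(h / 2) - pert(-h / 2)) / h
    (4 * d2 - d1) / 3
  }, 0)
  expect_equal(as.numeric(r$grad), fd, tolerance = 1e-7)
})

test_that("noise-free data give the exact slope with zero variance components", {
  d <- study_design(visit_weeks = c(0, 26, 52, 104), repeat_scan_visits = 1L,
                    n_cases = 5L, n_controls = 1L)
  pars <- volume_params(beta = -2, sigma2_b = 0, sigma2_d = 0, sigma2_e = 0,
                        alpha_mean = 100 * log(1000), alpha_sd = 3)
  vols <- simulate_volume_dataset(d, pars, seed = 2)
  fit <- fit_volume_model(vols[vols$group == "AD", ])
  expect_equal(fit$beta_hat, -2, tolerance = 1e-6)
  expect_identical(c(fit$sigma2_b, fit$sigma2_d, fit$sigma2_e), c(0, 0, 0))
  expect_true(fit$boundary)
  # subject intercepts are recovered too
  truth <- vols$volume[vols$group == "AD" & vols$visit == 1 & vols$scan == 1]
  expect_equal(unname(fit$alpha_hat), 100 * log(truth), tolerance = 1e-6)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- study_design(n_cases = 40L, n_controls = 2L)
  vols <- simulate_volume_dataset(d, structure = "brain", seed = 9)
  ad <- vols[vols$group == "AD", ]
  fit <- fit_volume_model(ad)

  ad$y <- 100 * log(ad$volume)
  ad$visit_id <- paste(ad$subject, ad$visit)
  lf <- lme4::lmer(
    y ~ 0 + subject + time_years + (0 + time_years | subject) + (1 | visit_id),
    data = ad, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$beta_hat, unname(lme4::fixef(lf)["time_years"]),
               tolerance = 1e-4)
  expect_equal(fit$sigma2_b, vc$vcov[vc$grp == "subject"], tolerance = 1e-3)
  expect_equal(fit$sigma2_d, vc$vcov[vc$grp == "visit_id"], tolerance = 1e-3)
  expect_equal(fit$sigma2_e, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(-2 * fit$restricted_loglik, lme4::REMLcrit(lf),
               tolerance = 1e-6)
})

test_that("constrained fallback holds between-subject and visit components at zero", {
  d <- study_design(n_cases = 15L, n_controls = 2L)
  vols <- simulate_volume_dataset(d, structure = "brain", seed = 13)
  fit <- fit_volume_model(vols[vols$group == "AD", ], constrain_between = TRUE)
  expect_identical(fit$sigma2_b, 0)
  expect_identical(fit$sigma2_d, 0)
  expect_gt(fit$sigma2_e, 0)
  expect_true(fit$constrained)
  full <- fit_volume_model(vols[vols$group == "AD", ])
  expect_gte(full$restricted_loglik, fit$restricted_loglik)
})

test_that("input validation rejects unusable record sets", {
  d <- study_design(n_cases = 4L, n_controls = 2L)
  vols <- simulate_volume_dataset(d, seed = 1)
  one <- vols[vols$subject == "AD01", ]
  expect_error(fit_volume_model(one), "two subjects")
  flat <- vols[vols$visit == 1, ]
  expect_error(fit_volume_model(flat), "degenerate")
  expect_error(fit_volume_model(vols), "one group")
  bad <- vols[vols$group == "AD", ]; bad$volume[1] <- -5
  expect_error(fit_volume_model(bad), "positive")
})

test_that("predicted change and rate variances follow the fitted decomposition", {
  fake <- list(sigma2_b = 1, sigma2_d = 0.5, sigma2_e = 0.25)
  expect_equal(predict_change_variance(fake, 2), 5.5)
  expect_equal(predict_change_variance(fake, 0), 1.5) # same-visit limit
  expect_equal(predict_rate_variance(fake, 2), 1.375)
  dts <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(predict_change_variance(fake, dts)) >= 0))
  expect_true(all(diff(predict_rate_variance(fake, dts)) < 0))
  # asymptote: between-subject variance only
  expect_equal(predict_rate_variance(fake, 1e6), 1, tolerance = 1e-9)
  expect_error(predict_rate_variance(fake, 0), "dt")
  expect_error(predict_change_variance(fake, -1), "dt")
})
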