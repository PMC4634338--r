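test_that("noise-free volume model reproduces the deterministic trajectory", {
  # a visit at exactly one year: 365.25/7 weeks
  d <- study_design(visit_weeks = c(0, 365.25 / 7), repeat_scan_visits = 1L,
                    n_cases = 2L, n_controls = 1L)
  pars <- volume_params(beta = -2, sigma2_b = 0, sigma2_d = 0, sigma2_e = 0,
                        alpha_mean = 100 * log(1000), alpha_sd = 0)
  vols <- simulate_volume_dataset(d, pars, seed = 1)
  expect_equal(vols$volume[vols$visit == 1], rep(1000, 6)) # 3 subjects x 2 scans
  expect_equal(vols$volume[vols$visit == 2], rep(1000 * exp(-0.02), 3))
})

test_that("simulation is reproducible and uses per-subject substreams", {
  d <- study_design(n_cases = 6L, n_controls = 3L)
  expect_identical(simulate_volume_dataset(d, seed = 42),
                   simulate_volume_dataset(d, seed = 42))
  ch1 <- simulate_direct_dataset(d, seed = 42)
  expect_identical(ch1, simulate_direct_dataset(d, seed = 42))

  # changing one subject's attendance leaves every other subject untouched
  att <- matrix(TRUE, 9, d$n_visits,
                dimnames = list(c(sprintf("AD%02d", 1:6),
                                  sprintf("HC%02d", 1:3)), NULL))
  base <- simulate_volume_dataset(d, attendance = att, seed = 7)
  att2 <- att; att2["AD03", 8:9] <- FALSE
  mod <- simulate_volume_dataset(d, attendance = att2, seed = 7)
  others <- function(x) {
    x <- x[x$subject != "AD03", ]
    rownames(x) <- NULL
    x
  }
  expect_identical(others(base), others(mod))
  expect_lt(sum(mod$subject == "AD03"), sum(base$subject == "AD03"))
})

test_that("volume and direct datasets share each subject's slope draw", {
  d <- study_design(visit_weeks = c(0, 26, 52), repeat_scan_visits = integer(),
                    n_cases = 30L, n_controls = 2L)
  vp <- volume_params(beta = -2, sigma2_b = 1, sigma2_d = 0, sigma2_e = 0,
                      alpha_sd = 0)
  dp <- direct_params(beta = -2, sigma2_b = 1, sigma2_u = 0, sigma2_v = 0,
                      sigma2_w = 0)
  vols <- simulate_volume_dataset(d, vp, seed = 3)
  ch <- simulate_direct_dataset(d, dp, seed = 3)
  # per-subject rate from volumes vs from a direct pair must coincide
  v1 <- vols[vols$visit == 1, ]; v3 <- vols[vols$visit == 3, ]
  rate_vol <- c_indirect(v1$volume, v3$volume) / visit_time_years(d, 3)
  fwd <- ch[ch$direction == "forward" & ch$start_visit == 1 &
              ch$end_visit == 3, ]
  rate_dir <- fwd$change / fwd$delta_t_years
  expect_equal(rate_vol[order(v1$subject)], rate_dir[order(fwd$subject)],
               tolerance = 1e-10)
})

test_that("direct generator honors the signed visit/scan effect structure", {
  d <- study_design(visit_weeks = c(0, 26, 52), repeat_scan_visits = 1L,
                    n_cases = 50L, n_controls = 1L)
  # only visit effects: same-day changes must vanish exactly
  dp <- direct_params(beta = 0, sigma2_b = 0, sigma2_u = 5, sigma2_v = 0,
                      sigma2_w = 0)
  ch <- simulate_direct_dataset(d, dp, seed = 5)
  same_day <- ch$direction == "forward" & ch$start_visit == ch$end_visit
  expect_true(any(same_day))
  expect_equal(ch$change[same_day], rep(0, sum(same_day)))
  expect_gt(var(ch$change[!same_day & ch$direction == "forward"]), 0)

  # symmetric technique: backward is the exact negation, pair by pair
  key <- function(x) paste(x$subject, pmin(x$start_visit, x$end_visit),
                           pmax(x$start_visit, x$end_visit),
                           ifelse(x$direction == "forward", x$start_scan,
                                  x$end_scan),
                           ifelse(x$direction == "forward", x$end_scan,
                                  x$start_scan))
  dp2 <- direct_params(beta = -3, sigma2_b = 0.5, sigma2_u = 0.1,
                       sigma2_v = 0.1, sigma2_w = 0.1,
                       symmetry_noise_sd = 0)
  ch2 <- simulate_direct_dataset(d, dp2, seed = 6)
  fwd <- ch2[ch2$direction == "forward", ]
  bwd <- ch2[ch2$direction == "backward", ]
  m <- match(key(fwd), key(bwd))
  expect_false(anyNA(m))
  expect_equal(bwd$change[m], -fwd$change)
})

test_that("additivity defect of chained direct changes has variance 3*sigma2_w", {
  d <- study_design(visit_weeks = c(0, 26, 52), repeat_scan_visits = integer(),
                    n_cases = 4000L, n_controls = 1L)
  sw2 <- 0.12
  dp <- direct_params(beta = -2, sigma2_b = 0.5, sigma2_u = 0.1,
                      sigma2_v = 0.08, sigma2_w = sw2)
  ch <- simulate_direct_dataset(d, dp, seed = 8)
  fwd <- ch[ch$group == "AD" & ch$direction == "forward", ]
  g <- function(sv, ev) {
    r <- fwd[fwd$start_visit == sv & fwd$end_visit == ev, ]
    r$change[order(r$subject)]
  }
  defect <- g(1, 3) - (g(1, 2) + g(2, 3)) # b, u, v all cancel; 3 w terms left
  expect_equal(mean(defect), 0, tolerance = 5 * sqrt(3 * sw2 / 4000))
  se_var <- 3 * sw2 * sqrt(2 / (length(defect) - 1))
  expect_lt(abs(var(defect) - 3 * sw2), 3 * se_var)
})

test_that("presets give controls smaller rate magnitudes than AD throughout", {
  for (s in c("brain", "ventricle", "hippo_L", "hippo_R")) {
    ad <- atrophy_preset(s, "AD"); hc <- atrophy_preset(s, "control")
    expect_lt(abs(hc$volume$beta), abs(ad$volume$beta))
    expect_lt(abs(hc$direct$beta), abs(ad$direct$beta))
    # ventricles expand, the others shrink
    expect_identical(sign(ad$volume$beta), if (s == "ventricle") 1 else -1)
    # within-subject aggregates consistent with the declared partitions
    expect_equal(2 * ad$volume$sigma2_d + 2 * ad$volume$sigma2_e,
                 2 * hc$volume$sigma2_d + 2 * hc$volume$sigma2_e)
    expect_equal(2 * ad$direct$sigma2_u / (2 * ad$direct$sigma2_u +
                   2 * ad$direct$sigma2_v + ad$direct$sigma2_w), 0.5)
  }
  expect_error(atrophy_preset("cerebellum"), "arg")
  expect_error(volume_params(-2, -1, 0, 0), "variances")
  expect_error(direct_params(-2, 1, 0.1, 0.1, -0.2), "variances")
})
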