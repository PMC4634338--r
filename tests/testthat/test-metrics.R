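test_that("standardized change formulas agree across their variants", {
  expect_identical(c_indirect(1000, 1000), 0)
  expect_equal(c_indirect(1000, 990), 100 * log(0.99))
  expect_equal(c_direct(1000, -10), 100 * log(0.99))
  expect_equal(c_direct_percent(-1), 100 * log(0.99))
  expect_identical(c_direct(500, 0), 0)

  # antisymmetry and the direct/indirect identity, over random volumes
  withr::local_seed(1)
  a <- runif(50, 1, 2000); b <- runif(50, 1, 2000)
  expect_equal(c_indirect(a, b), -c_indirect(b, a))
  expect_equal(c_direct(a, b - a), c_indirect(a, b))

  expect_error(c_indirect(0, 10), "positive")
  expect_error(c_direct(100, -100), "implausible")
  expect_error(c_direct_percent(-100), "-100")
})

test_that("short-interval t-test handles degenerate and symmetric inputs", {
  z <- short_interval_test(rep(0, 10))
  expect_identical(z$mean_change, 0)
  expect_identical(z$ci95, c(0, 0))
  expect_identical(z$p_value, 1)

  s <- short_interval_test(c(-1, 1))
  expect_identical(s$mean_change, 0)
  expect_equal(s$p_value, 1)
  expect_identical(s$n, 2L)

  expect_error(short_interval_test(5), "at least two")

  biased <- short_interval_test(rnorm(200, mean = 3, sd = 0.1))
  expect_lt(biased$p_value, 1e-10)
  expect_true(biased$ci95[1] <= biased$mean_change &&
                biased$mean_change <= biased$ci95[2])
})

test_that("symmetry and transitivity differences match hand-computed values", {
  expect_identical(symmetry_difference(-10, -10)[1], 0)
  expect_equal(symmetry_difference(-10, -8)[1], 100 * (-2) / (-9))
  expect_identical(transitivity_difference(-9, -5, -4)[1], 0)
  expect_equal(transitivity_difference(-10, -5, -4)[1], 100 * (-1) / (-9.5))

  # scale invariance under positive rescaling
  withr::local_seed(2)
  f <- rnorm(40, -5); g <- rnorm(40, -5); h <- rnorm(40, -2); k <- runif(1, 0.1, 50)
  expect_equal(symmetry_difference(f, g), symmetry_difference(k * f, k * g))
  expect_equal(transitivity_difference(f, g, h),
               transitivity_difference(k * f, k * g, k * h))

  # near-zero denominators are flagged undefined, not returned as huge ratios
  suppressMessages(d <- symmetry_difference(c(1, -1 + 1e-15), c(-1, 1)))
  expect_true(is.na(d[1]) && is.na(d[2]))
  expect_identical(attr(d, "n_undefined"), 2L)
  suppressMessages(d2 <- transitivity_difference(2, -1, -1))
  expect_true(is.na(d2[1]))
  suppressMessages(expect_identical(symmetry_difference(0, 0)[1], NA_real_))
})

test_that("median order-statistic interval is exact, covering, and safe at n = 1", {
  expect_warning(m <- median_with_ci(c(1, 2, 3)), "too few values")
  expect_identical(m$median, 2)
  expect_identical(m$ci95, c(1, 3))

  expect_warning(m1 <- median_with_ci(7), "single value")
  expect_identical(m1$median, 7)
  expect_identical(m1$ci95, c(7, 7))

  suppressWarnings(mna <- median_with_ci(c(1, NA, 3, 5)))
  expect_identical(mna$n, 3L)
  expect_identical(mna$n_missing, 1L)

  # coverage of the true median 0 for symmetric data
  withr::local_seed(3)
  hits <- vapply(1:200, function(i) {
    ci <- median_with_ci(rnorm(1000))$ci95
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.93)
})

test_that("reliability scorecard summarizes groups, metrics and symmetric techniques", {
  d <- study_design(n_cases = 25L, n_controls = 12L)
  vols <- simulate_volume_dataset(d, structure = "brain", seed = 11)
  ch <- simulate_direct_dataset(d, structure = "brain", seed = 11)
  sc <- reliability_scorecard(vols, ch, d)
  expect_setequal(unique(sc$metric),
                  c("short_same_day", "short_two_week", "symmetry",
                    "transitivity"))
  expect_setequal(unique(sc$group), c("AD", "control"))
  # the default preset is a symmetric technique: symmetry medians exactly 0
  sym <- sc[sc$metric == "symmetry", ]
  expect_equal(sym$estimate, rep(0, nrow(sym)))
  # short-interval rows carry a p-value, median rows do not
  expect_true(all(is.finite(sc$p_value[grepl("short", sc$metric)])))
  expect_true(all(is.na(sc$p_value[!grepl("short", sc$metric)])))
  # changes-only scorecard still yields short-interval rows (direct route)
  sc2 <- reliability_scorecard(changes = ch, design = d)
  expect_true(any(sc2$metric == "short_same_day"))
})
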