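test_that("funnel data centers on the fixed-effect mean with 1.96 se walls", {
  d <- data.frame(value = c(0.5), sampling_variance = c(0.04))
  fd <- funnel_data(d)
  expect_equal(fd$center, 0.5)
  expect_equal(fd$bounds$lower, 0.5 - qnorm(0.975) * fd$bounds$se)

  # doubling every n halves every variance, shrinking each se by sqrt(2)
  r <- one_record()
  e1 <- compute_effect_sizes(r, "MD")
  r2 <- one_record(male_n = 2 * r$male_n, female_n = 2 * r$female_n)
  e2 <- compute_effect_sizes(r2, "MD")
  expect_equal(sqrt(e1$sampling_variance) / sqrt(e2$sampling_variance),
               sqrt(2), tolerance = 1e-12)
})

test_that("funnel boundaries hold ~95% of homogeneous effects", {
  set.seed(61)
  v <- runif(1000, 0.02, 0.3)
  d <- data.frame(value = rnorm(1000, 0.3, sqrt(v)), sampling_variance = v)
  fd <- funnel_data(d)
  inside <- abs(d$value - fd$center) <= qnorm(0.975) * sqrt(v)
  expect_gt(mean(inside), 0.93)
  expect_lt(mean(inside), 0.97)
  # symmetric effects split roughly evenly around the center
  expect_gt(mean(d$value > fd$center), 0.45)
  expect_lt(mean(d$value > fd$center), 0.55)
})

test_that("year regression centers year and finds an injected decline", {
  # no trend: intercept equals the pooled estimate at the mean year
  d <- sim_effects(n = 40, n_groups = 10, sigma2 = 0.1, seed = 71)
  d$pub_year <- rep(1995:2014, 2)
  f <- year_bias_regression(d, random = "study")
  f0 <- fit_meta(d, ~ 1, random = "study")
  expect_equal(mean(d$pub_year - f$data$year_c), mean(d$pub_year))
  expect_lt(abs(unname(f$beta[1]) - unname(f0$beta[1])), 0.05)

  # strong decline, low noise: slope detected
  set.seed(72)
  yrs <- rep(seq(1990, 2019), 2)
  dd <- data.frame(value = 1 - 0.02 * (yrs - 1990) + rnorm(60, 0, 0.05),
                   sampling_variance = 0.01,
                   study_id = paste0("S", seq_len(60)),
                   pub_year = yrs)
  fb <- year_bias_regression(dd, random = "study")
  expect_lt(unname(fb$ci.ub["year_c"]), 0)
  expect_equal(unname(fb$beta["year_c"]), -0.02, tolerance = 0.25)

  dd$pub_year <- 2000
  expect_error(year_bias_regression(dd, random = "study"), "distinct")
})

test_that("slope CIs cover a zero year trend at the nominal rate", {
  set.seed(73)
  cover <- replicate(60, {
    d <- sim_effects(n = 30, n_groups = 10, sigma2 = 0.1,
                     seed = sample.int(1e6, 1))
    d$pub_year <- rep(1991:2020, length.out = 30)
    f <- suppressWarnings(year_bias_regression(d, random = "study"))
    f$ci.lb["year_c"] <= 0 && 0 <= f$ci.ub["year_c"]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("leave-one-out Cook's distances flag a gross outlier", {
  set.seed(81)
  n <- 50
  d <- data.frame(value = rnorm(n, 0.2, 0.15), sampling_variance = 0.04,
                  study_id = paste0("S", seq_len(n)))
  d$value[17] <- 6   # gross outlier
  inf <- loo_cooks(d, ~ 1, random = "study")
  expect_equal(inf$n_refits, n)
  expect_equal(which.max(inf$cooks_d), 17)
  expect_true(inf$flagged[17])
  expect_true(all(inf$cooks_d >= 0, na.rm = TRUE))
  expect_equal(inf$threshold, 4 / n)
  # exactly one refit per observation is recorded
  expect_equal(nrow(inf$beta_loo), n)
})

test_that("a duplicated observation has near-zero influence", {
  set.seed(82)
  d <- data.frame(value = c(rnorm(14, 0.3, 0.2), 0.3, 0.3),
                  sampling_variance = 0.05,
                  study_id = paste0("S", c(1:14, 15, 16)))
  inf <- loo_cooks(d, ~ 1, random = "study")
  expect_lt(inf$cooks_d[15], max(inf$cooks_d, na.rm = TRUE))
  expect_lt(inf$cooks_d[15], inf$threshold)
})

test_that("weight sensitivity: within-only weights equal OLS at equal v", {
  d <- sim_effects(n = 25, n_groups = 6, sigma2 = 0.3, seed = 91,
                   slope = 0.4)
  d$sampling_variance <- 0.1
  ws <- weight_sensitivity(d, ~ x, random = "study")
  ols <- coef(lm(value ~ x, data = d))
  expect_equal(ws$within_only$estimate, unname(ols), tolerance = 1e-10)

  # zero-heterogeneity process: the two weighting schemes agree
  set.seed(92)
  v <- runif(40, 0.05, 0.3)
  d0 <- data.frame(value = 0.25 + rnorm(40, 0, sqrt(v)),
                   sampling_variance = v,
                   study_id = paste0("S", 1:40))
  ws0 <- suppressWarnings(weight_sensitivity(d0, ~ 1, random = "study"))
  expect_lt(max(abs(ws0$delta_beta)), 0.05)

  # large heterogeneity: deltas are reported and typically nonzero
  dh <- sim_effects(n = 30, n_groups = 30, sigma2 = 2, seed = 93,
                    slope = 0.5, v_range = c(0.01, 0.5))
  wsh <- weight_sensitivity(dh, ~ x, random = "study")
  expect_length(wsh$delta_beta, 2)
  expect_true(all(is.finite(wsh$delta_beta)))
})

test_that("complete-case filter partitions with per-row reasons", {
  sim <- simulate_dataset(sim_truth(n_studies = 30, n_species = 30,
                                    seed = 14))
  rec <- sim$records
  cc <- complete_case_filter(rec)
  expect_equal(cc$n_dropped, 0)
  expect_equal(cc$n_kept, nrow(rec))

  rec$female_sd[3] <- NA
  rec$male_mass[5] <- NA
  cc2 <- complete_case_filter(rec)
  expect_equal(cc2$n_dropped, 2)
  expect_match(cc2$dropped$reason[1], "female_sd")
  expect_match(cc2$dropped$reason[2], "male_mass")

  # sds not required for an MD-only analysis without variance moderators
  cc3 <- complete_case_filter(rec, required = c("male_mean", "female_mean"))
  expect_equal(cc3$n_dropped, 0)
})

test_that("missing masses shrink the usable dataset as logged", {
  truth <- sim_truth(seed = 15, mass_missing_frac = 5 / 163)
  sim <- simulate_dataset(truth)
  full <- prepare_effects(sim$records, "MD", "N15", require_mass = FALSE)
  red <- prepare_effects(sim$records, "MD", "N15")
  log <- attr(red, "filter_log")
  expect_equal(length(unique(sim$records$species)) -
                 length(unique(red$species)), 5)
  expect_gt(log$n_dropped_incomplete, 0)
  expect_lt(nrow(red), nrow(full))
})
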