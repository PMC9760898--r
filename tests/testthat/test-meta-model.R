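test_that("with no random levels the fit is the inverse-variance mean", {
  d <- data.frame(value = c(0.1, 0.4, -0.2, 0.5),
                  sampling_variance = c(0.1, 0.2, 0.05, 0.4))
  f <- fit_meta(d, ~ 1, random = character(0))
  w <- 1 / d$sampling_variance
  expect_equal(unname(f$beta), sum(w * d$value) / sum(w), tolerance = 1e-12)
  expect_equal(unname(f$se), sqrt(1 / sum(w)), tolerance = 1e-12)

  # equal weights reduce to the arithmetic mean
  d$sampling_variance <- 0.25
  f2 <- fit_meta(d, ~ 1, random = character(0))
  expect_equal(unname(f2$beta), mean(d$value), tolerance = 1e-12)
})

test_that("two-point REML equals the method-of-moments/grid solution", {
  y <- c(0, 2); v <- c(1, 1)
  d <- data.frame(value = y, sampling_variance = v)
  f <- fit_meta(d, ~ 1, random = "observation")
  X <- matrix(1, 2, 1)
  M <- list(diag(2))
  grid <- seq(0, 10, by = 1e-4)
  ll <- vapply(grid, function(s2) oracle_loglik(s2, y, X, v, M), 0)
  expect_equal(unname(f$sigma2), grid[which.max(ll)], tolerance = 2e-4)
  # balanced equal-v closed form: sigma2 = max(0, S^2 - v)
  expect_equal(unname(f$sigma2), max(0, var(y) - 1), tolerance = 1e-4)
})

test_that("equal-v one-level REML matches max(0, S^2 - v) across datasets", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:15, 1)
    v0 <- runif(1, 0.05, 0.5)
    y <- rnorm(n, 0, sqrt(v0 + 0.3))
    d <- data.frame(value = y, sampling_variance = v0)
    f <- fit_meta(d, ~ 1, random = "observation")
    expect_equal(unname(f$sigma2), max(0, var(y) - v0), tolerance = 1e-5)
  }
})

test_that("REML/ML optima match a brute-force 2-D grid oracle", {
  set.seed(21)
  d <- sim_effects(n = 12, n_groups = 4, sigma2 = 0.3, seed = 21,
                   slope = 0.4)
  X <- cbind(1, d$x)
  M <- list(oracle_group_M(d$study_id), diag(nrow(d)))
  for (meth in c("REML", "ML")) {
    f <- fit_meta(d, ~ x, random = c("study", "observation"),
                  method = meth)
    g <- as.matrix(expand.grid(s1 = seq(0, 1.5, by = 0.01),
                               s2 = seq(0, 1.5, by = 0.01)))
    ll <- apply(g, 1, function(s) oracle_loglik(s, d$value, X,
                                                d$sampling_variance, M, meth))
    best <- g[which.max(ll), ]
    # the fitted optimum must not be worse than the best grid point
    ll_fit <- oracle_loglik(f$sigma2, d$value, X, d$sampling_variance, M,
                            meth)
    expect_gte(ll_fit, max(ll) - 1e-9)
    expect_lt(max(abs(f$sigma2 - best)), 0.011)
    expect_equal(unname(f$beta),
                 oracle_beta(f$sigma2, d$value, X, d$sampling_variance, M),
                 tolerance = 1e-8)
  }
})

test_that("the optimum beats 100 random variance probes", {
  d <- sim_effects(n = 25, n_groups = 6, sigma2 = 0.4, seed = 5, slope = 0.2)
  f <- fit_meta(d, ~ x, random = c("study", "species"))
  X <- f$X
  M <- list(oracle_group_M(d$study_id), oracle_group_M(d$species))
  ll_fit <- oracle_loglik(f$sigma2, d$value, X, d$sampling_variance, M)
  set.seed(77)
  probes <- matrix(runif(200, 0, 2), ncol = 2)
  ll_probe <- apply(probes, 1, function(s)
    oracle_loglik(s, d$value, X, d$sampling_variance, M))
  expect_true(all(ll_fit >= ll_probe - 1e-8))
})

test_that("fit_meta agrees with metafor::rma.mv on a phylogenetic model", {
  sim <- simulate_dataset(sim_truth(n_studies = 40, n_species = 40,
                                    seed = 12))
  d <- prepare_effects(sim$records, "MD", "N15")
  A <- phylo_correlation(sim$tree, unique(d$species))
  f <- fit_meta(d, ~ dimorphism, A = A)
  d$phylo <- d$species
  m <- metafor::rma.mv(value, sampling_variance, mods = ~ dimorphism,
                       data = d,
                       random = list(~ 1 | study_id, ~ 1 | species,
                                     ~ 1 | phylo),
                       R = list(phylo = unclass(A)), method = "REML")
  expect_equal(unname(f$beta), unname(coef(m)), tolerance = 1e-4)
  expect_equal(unname(f$sigma2), m$sigma2, tolerance = 1e-3)
  expect_equal(unname(f$se), unname(m$se), tolerance = 1e-4)

  fml <- fit_meta(d, ~ dimorphism, A = A, method = "ML")
  mml <- metafor::rma.mv(value, sampling_variance, mods = ~ dimorphism,
                         data = d,
                         random = list(~ 1 | study_id, ~ 1 | species,
                                       ~ 1 | phylo),
                         R = list(phylo = unclass(A)), method = "ML")
  expect_equal(fml$loglik, as.numeric(logLik(mml)), tolerance = 1e-5)
})

test_that("identity phylo correlation is exchangeable with the species level", {
  d <- sim_effects(n = 40, n_groups = 10, sigma2 = 0.5, seed = 9)
  d$species <- paste0("sp", rep(1:8, length.out = 40))
  Aid <- diag(8)
  dimnames(Aid) <- list(unique(d$species), unique(d$species))
  f2 <- fit_meta(d, ~ 1, random = c("species", "phylo"), A = Aid)
  f1 <- fit_meta(d, ~ 1, random = "species")
  # the species/phylo split is unidentified but their sum is recovered
  expect_equal(sum(f2$sigma2), sum(f1$sigma2), tolerance = 1e-4)
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 1e-5)
})

test_that("rank-deficient designs fail naming the aliased columns", {
  d <- sim_effects(n = 10, seed = 2)
  d$x2 <- 2 * d$x
  expect_error(fit_meta(d, ~ x + x2, random = "study"), "x2")
})

test_that("multilevel I2 follows the typical-v decomposition", {
  v <- c(0.1, 0.2, 0.15, 0.05, 0.3)
  k <- length(v); w <- 1 / v
  vbar <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))

  fake <- structure(list(beta = c("(Intercept)" = 0.1),
                         sigma2 = c(study = vbar / 2, species = vbar / 2),
                         vi = v), class = "meta_fit")
  h <- i_squared(fake)
  expect_equal(h$typical_v, vbar)
  expect_equal(h$i2_total, 50)
  expect_equal(sum(h$i2_per_level), h$i2_total)
  expect_equal(unname(h$i2_per_level), c(25, 25))

  # zero components -> 0%
  fake0 <- structure(list(beta = c("(Intercept)" = 0.1),
                          sigma2 = c(study = 0), vi = v),
                     class = "meta_fit")
  expect_equal(i_squared(fake0)$i2_total, 0)

  # moderated models are refused
  d <- sim_effects(n = 10, seed = 3)
  f <- fit_meta(d, ~ x, random = "study")
  expect_error(i_squared(f), "intercept-only")
})

test_that("AICc follows the small-sample formula and penalizes parameters", {
  expect_equal(aicc(0, n_param = 1, n_obs = 10), 2 + 0.5)
  expect_equal(aicc(-252, n_param = 4, n_obs = 282), 512.1444, tolerance = 1e-4)
  expect_lt(aicc(-100, n_param = 3, n_obs = 50),
            aicc(-100, n_param = 4, n_obs = 50))
  expect_error(aicc(-10, n_param = 9, n_obs = 10), "n - p - 1")
})

test_that("model selection orders by AICc and flags ties at equal rank", {
  d <- sim_effects(n = 30, n_groups = 8, sigma2 = 0.2, seed = 31,
                   slope = 0.8)
  tab <- model_selection_table(list(~ 1, ~ x), d, random = "study")
  expect_equal(attr(tab, "method"), "ML")
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$aicc) >= 0))
  expect_equal(tab$formula[1], "~x")
  expect_equal(tab$delta[1], 0)

  one <- model_selection_table(list(~ x), d, random = "study")
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1L)
})

test_that("predictions with bands match a direct quadratic form", {
  d <- sim_effects(n = 30, n_groups = 8, sigma2 = 0.3, seed = 41,
                   slope = 0.5)
  f <- fit_meta(d, ~ x, random = "study")
  grid <- data.frame(x = c(-2, -1, 0, 1, 2))
  pr <- predict_with_band(f, grid)
  Xg <- cbind(1, grid$x)
  est <- drop(Xg %*% f$beta)
  se <- sqrt(diag(Xg %*% f$vcov_beta %*% t(Xg)))
  expect_equal(pr$estimate, est, tolerance = 1e-12)
  expect_equal(pr$ci.lb, est - qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(pr$ci.ub, est + qnorm(0.975) * se, tolerance = 1e-12)

  # at all-zero moderators the prediction is the intercept +/- 1.96 se
  p0 <- predict_with_band(f, data.frame(x = 0))
  expect_equal(p0$estimate, unname(f$beta[1]))
  expect_equal(p0$ci.ub - p0$estimate, qnorm(0.975) * unname(f$se[1]),
               tolerance = 1e-12)

  # band narrowest near the moderator mean
  xs <- seq(min(d$x), max(d$x), length.out = 41)
  wid <- with(predict_with_band(f, data.frame(x = xs)), ci.ub - ci.lb)
  expect_lt(abs(xs[which.min(wid)] - mean(d$x)), diff(range(d$x)) / 8)
})

test_that("Wald inference converts estimates to z, p and 95% CIs", {
  d <- sim_effects(n = 20, n_groups = 5, sigma2 = 0.2, seed = 51)
  f <- fit_meta(d, ~ x, random = "study")
  wi <- wald_inference(f)
  expect_equal(wi$zval, wi$estimate / wi$se)
  expect_equal(wi$pval, 2 * pnorm(-abs(wi$zval)))
  expect_equal(wi$ci.lb, wi$estimate - qnorm(0.975) * wi$se)
  # the printed-style triple: estimate 0.126, se 0.0332 -> CI (0.061, 0.191)
  est <- 0.126; se <- 0.0332
  expect_equal(est + c(-1, 1) * qnorm(0.975) * se, c(0.0609, 0.1911),
               tolerance = 1e-3)
})
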