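# Independent oracle for the multilevel (restricted) likelihood.
# Deliberately coded from the density formulas with solve()/determinant()
# (no Cholesky shortcuts, no code shared with the package's optimizer), so
# grid searches over it are an external check on fit_meta().
oracle_loglik <- function(sigma2, y, X, v, Mlist, method = "REML") {
  n <- length(y)
  p <- ncol(X)
  V <- diag(v, n)
  for (l in seq_along(Mlist)) V <- V + sigma2[l] * Mlist[[l]]
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (method == "REML") {
    ldB <- as.numeric(determinant(B, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) + ldV + ldB + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  }
}

oracle_beta <- function(sigma2, y, X, v, Mlist) {
  n <- length(y)
  V <- diag(v, n)
  for (l in seq_along(Mlist)) V <- V + sigma2[l] * Mlist[[l]]
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Grouping-structure matrices built independently of the package internals.
oracle_group_M <- function(g) {
  g <- as.character(g)
  outer(g, g, "==") * 1
}

# A minimal complete study record for unit examples.
one_record <- function(male_mean = 12, male_sd = 1.5, male_n = 11,
                       female_mean = 10.5, female_sd = 1.0, female_n = 21,
                       male_mass = 2, female_mass = 1, ...) {
  data.frame(study_id = "S1", species = "Species_001", tissue = "muscle",
             isotope = "N15", male_mean = male_mean, male_sd = male_sd,
             male_n = male_n, female_mean = female_mean,
             female_sd = female_sd, female_n = female_n,
             male_mass = male_mass, female_mass = female_mass,
             diet_class = "carnivore", gape_limited = FALSE,
             pub_year = 2010, taxon_class = "mammal",
             stringsAsFactors = FALSE, ...)
}

swap_sexes <- function(rec) {
  out <- rec
  out$male_mean <- rec$female_mean; out$female_mean <- rec$male_mean
  out$male_sd <- rec$female_sd;     out$female_sd <- rec$male_sd
  out$male_n <- rec$female_n;       out$female_n <- rec$male_n
  out
}

# Small clustered effect-size datasets for model tests.
sim_effects <- function(n = 12, n_groups = 4, sigma2 = 0.3, seed = 1,
                        slope = 0, v_range = c(0.05, 0.2)) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), length.out = n)
  x <- rnorm(n)
  u <- rnorm(n_groups, 0, sqrt(sigma2))
  v <- runif(n, v_range[1], v_range[2])
  data.frame(value = 0.2 + slope * x + u[g] + rnorm(n, 0, sqrt(v)),
             sampling_variance = v,
             study_id = paste0("S", g),
             species = paste0("sp", seq_len(n)),
             x = x)
}
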