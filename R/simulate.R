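#' Truth ledger for a synthetic literature dataset
#'
#' Collects every generating parameter of [simulate_dataset()] so a dataset
#' is fully reproducible from its seed and recovery experiments can compare
#' estimates against truth. Defaults emulate the compiled vertebrate
#' literature the pipeline targets: 158 studies covering 163 species with a
#' mammal-dominated taxon mix, three dietary classes, a gape-limited
#' carnivore subset (fish and snake-like reptiles), mass dimorphism spanning
#' roughly 10-fold female-biased to 7-fold male-biased (log2 index about
#' -3.35 to 2.85), multiple tissue rows per study, and strong multilevel
#' heterogeneity (variance components summing to about 0.95 against a median
#' sampling variance near 0.1, i.e. I-squared around 90 percent).
#'
#' @param n_studies,n_species dataset dimensions.
#' @param taxon_probs named proportions of species per taxon class.
#' @param beta_n15,beta_c13 named lists of true fixed effects per isotope:
#'   `intercept` (permil), `slope_carnivore`, `slope_omnivore`,
#'   `slope_herbivore` (permil per log2 dimorphism unit), `mean_size`
#'   (permil per kg).
#' @param sigma2_study,sigma2_species,sigma2_phylo true variance components
#'   (permil squared).
#' @param dimorphism_mean,dimorphism_sd,dimorphism_range distribution of the
#'   log2 male:female mass index across species (normal, clipped).
#' @param extra_study_prob probability that a species is measured by a
#'   second, independent study. This crossing of species over studies (plus
#'   studies covering several species) is what separates the study-level
#'   from the species-level variance component; without it the two
#'   groupings coincide and only their sum is identified.
#' @param tissue_probs probabilities of 1, 2 or 3 tissues per study-species
#'   pair (each tissue yields one row per isotope).
#' @param sd_meanlog,sd_sdlog log-normal law of the per-sex true SDs (permil);
#'   `lnvr_sd` spread of the true log male:female SD ratio.
#' @param n_meanlog,n_sdlog,n_min law of per-sex sample sizes.
#' @param mass_missing_frac fraction of species whose masses are set missing
#'   (exercises the complete-case path).
#' @param seed integer master seed; stage sub-seeds are derived as
#'   `seed + 1` (tree), `+ 2` (species), `+ 3` (studies), `+ 4` (effects),
#'   `+ 5` (summaries), modulo 2^31 - 1.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(n_studies = 158, n_species = 163,
                      taxon_probs = c(mammal = 68, bird = 60, fish = 18,
                                      reptile = 17, amphibian = 1) / 164,
                      beta_n15 = list(intercept = 0.2,
                                      slope_carnivore = 0.126,
                                      slope_omnivore = 0.126,
                                      slope_herbivore = 0.126,
                                      mean_size = 3.6e-6),
                      beta_c13 = list(intercept = 0,
                                      slope_carnivore = 0,
                                      slope_omnivore = 0,
                                      slope_herbivore = 0.847,
                                      mean_size = 0),
                      sigma2_study = 0.35, sigma2_species = 0.35,
                      sigma2_phylo = 0.25,
                      dimorphism_mean = 0.15, dimorphism_sd = 1.0,
                      dimorphism_range = c(-3.35, 2.85),
                      extra_study_prob = 0.15,
                      tissue_probs = c(0.60, 0.30, 0.10),
                      sd_meanlog = log(0.9), sd_sdlog = 0.35,
                      lnvr_sd = 0.35,
                      n_meanlog = log(15), n_sdlog = 0.5, n_min = 3,
                      mass_missing_frac = 0,
                      seed = 1) {
  stopifnot(n_studies >= 1, n_species >= 2,
            sigma2_study >= 0, sigma2_species >= 0, sigma2_phylo >= 0,
            abs(sum(taxon_probs) - 1) < 1e-8,
            abs(sum(tissue_probs) - 1) < 1e-8,
            mass_missing_frac >= 0, mass_missing_frac < 1)
  structure(as.list(environment()), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic-data truth:", x$n_studies, "studies,", x$n_species,
      "species; sigma^2 =",
      paste(signif(c(x$sigma2_study, x$sigma2_species, x$sigma2_phylo), 3),
            collapse = "/"),
      "(study/species/phylo); seed", x$seed, "\n")
  invisible(x)
}

sub_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with unit depth and deterministic tip labels
#' (`Species_001`, ...), reproducible from the seed.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo` object.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 2) stop("need at least 2 species", call. = FALSE)
  set.seed(sub_seed(seed, 0))
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- sprintf("Species_%03d", seq_len(n_species))
  tr
}

#' Simulate a literature-style study table with known truth
#'
#' Draws a dataset with the statistical structure the pipeline assumes. Per
#' species: a taxon class, a dietary class (taxon-dependent), a gape
#' limitation flag (fish, and half of carnivorous reptiles), a female mass
#' (log-normal, taxon-dependent scale) and a log2 mass-dimorphism index
#' (normal, clipped to the configured range). Per study-species pair: one to
#' three tissues, each contributing one row per isotope. The true per-row
#' sex difference is
#' \eqn{\theta = \beta_0 + \beta_{diet} d + \beta_{size} \bar M +
#'      u_{study} + u_{species} + u_{phylo}}
#' with \eqn{u_{phylo} \sim MVN(0, \sigma^2_{phylo} A)} on the tree, and the
#' emitted per-sex summaries are sample means/SDs/sizes consistent with that
#' truth (observed SDs follow the chi-square law of a sample SD, observed
#' means carry sampling noise \eqn{s/\sqrt{n}}).
#'
#' @param truth a [sim_truth()] ledger.
#' @param tree optional `phylo` with at least `n_species` tips; simulated
#'   via [simulate_tree()] when absent.
#' @return list of class `sim_dataset`: `records` (study table data.frame),
#'   `tree`, `truth`.
#' @export
simulate_dataset <- function(truth = sim_truth(), tree = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(tree)) {
    tree <- simulate_tree(truth$n_species, sub_seed(truth$seed, 1))
  }
  if (length(tree$tip.label) < truth$n_species) {
    stop("tree has fewer tips than n_species", call. = FALSE)
  }
  if (length(tree$tip.label) > truth$n_species) {
    tree <- ape::keep.tip(tree, tree$tip.label[seq_len(truth$n_species)])
  }
  sp_names <- tree$tip.label
  ns <- truth$n_species

  ## --- species-level draws -------------------------------------------------
  set.seed(sub_seed(truth$seed, 2))
  # largest-remainder allocation of taxon classes
  raw <- truth$taxon_probs * ns
  cnt <- floor(raw)
  rem <- ns - sum(cnt)
  if (rem > 0) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1
  }
  taxon <- sample(rep(names(truth$taxon_probs), cnt))

  mass_meanlog <- c(mammal = log(10), bird = log(0.3), fish = log(1),
                    reptile = log(2), amphibian = log(0.05))[taxon]
  mass_sdlog <- c(mammal = 1.5, bird = 1.0, fish = 1.0,
                  reptile = 1.2, amphibian = 0.3)[taxon]
  female_mass <- stats::rlnorm(ns, mass_meanlog, mass_sdlog)
  dim_idx <- pmin(pmax(stats::rnorm(ns, truth$dimorphism_mean,
                                    truth$dimorphism_sd),
                       truth$dimorphism_range[1]), truth$dimorphism_range[2])
  male_mass <- female_mass * 2^dim_idx

  diet_probs <- list(mammal    = c(0.35, 0.35, 0.30),
                     bird      = c(0.50, 0.35, 0.15),
                     fish      = c(1.00, 0.00, 0.00),
                     reptile   = c(0.70, 0.20, 0.10),
                     amphibian = c(1.00, 0.00, 0.00))
  diets <- c("carnivore", "omnivore", "herbivore")
  diet <- vapply(taxon, function(tx)
    sample(diets, 1, prob = diet_probs[[tx]]), "")
  gape <- diet == "carnivore" &
    (taxon == "fish" | (taxon == "reptile" & stats::runif(ns) < 0.5))

  if (truth$mass_missing_frac > 0) {
    nmiss <- round(truth$mass_missing_frac * ns)
    if (nmiss > 0) {
      miss <- sample(ns, nmiss)
      female_mass[miss] <- NA
      male_mass[miss] <- NA
    }
  }

  species <- data.frame(species = sp_names, taxon_class = taxon,
                        diet_class = diet, gape_limited = gape,
                        male_mass = male_mass, female_mass = female_mass,
                        dim_idx = dim_idx,
                        mean_size = (male_mass + female_mass) / 2)

  ## --- study layout --------------------------------------------------------
  # every species has a primary study (studies wrap, so some studies cover
  # several species); a fraction of species is measured by a second study,
  # which is what makes the study and species groupings genuinely crossed
  set.seed(sub_seed(truth$seed, 3))
  primary <- ((seq_len(ns) - 1) %% truth$n_studies) + 1
  extra <- which(stats::runif(ns) < truth$extra_study_prob)
  second <- vapply(extra, function(i) {
    s <- sample.int(truth$n_studies, 1)
    as.integer(if (s == primary[i]) (s %% truth$n_studies) + 1 else s)
  }, 1L)
  pairs <- rbind(data.frame(species_i = seq_len(ns), study = primary),
                 data.frame(species_i = extra, study = second))
  study_ids <- sprintf("S%03d", seq_len(truth$n_studies))
  pub_year <- sample(1990:2020, truth$n_studies, replace = TRUE)

  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    nt <- sample(1:3, 1, prob = truth$tissue_probs)
    tis <- sample(c("muscle", "blood", "liver", "feather"), nt)
    expand.grid(species_i = pairs$species_i[k], study = pairs$study[k],
                tissue = tis, isotope = c("N15", "C13"),
                stringsAsFactors = FALSE)
  }))
  nr <- nrow(rows)

  ## --- true effects --------------------------------------------------------
  set.seed(sub_seed(truth$seed, 4))
  A <- phylo_correlation(tree, sp_names)
  Ru <- chol(unclass(A)[sp_names, sp_names] + 1e-10 * diag(ns))
  u <- list()
  for (iso in c("N15", "C13")) {
    u[[iso]] <- list(
      study   = stats::rnorm(truth$n_studies, 0, sqrt(truth$sigma2_study)),
      species = stats::rnorm(ns, 0, sqrt(truth$sigma2_species)),
      phylo   = sqrt(truth$sigma2_phylo) * drop(t(Ru) %*% stats::rnorm(ns))
    )
  }
  slope_of <- function(beta, d) {
    c(carnivore = beta$slope_carnivore, omnivore = beta$slope_omnivore,
      herbivore = beta$slope_herbivore)[d]
  }
  theta <- numeric(nr)
  for (iso in c("N15", "C13")) {
    b <- if (iso == "N15") truth$beta_n15 else truth$beta_c13
    sel <- rows$isotope == iso
    i <- rows$species_i[sel]
    ms <- species$mean_size[i]
    ms[is.na(ms)] <- 0        # missing-mass rows are filtered downstream
    theta[sel] <- b$intercept +
      slope_of(b, species$diet_class[i]) * species$dim_idx[i] +
      b$mean_size * ms +
      u[[iso]]$study[rows$study[sel]] +
      u[[iso]]$species[i] + u[[iso]]$phylo[i]
  }

  ## --- per-sex summaries ---------------------------------------------------
  set.seed(sub_seed(truth$seed, 5))
  sd_f <- stats::rlnorm(nr, truth$sd_meanlog, truth$sd_sdlog)
  sd_m <- sd_f * exp(stats::rnorm(nr, 0, truth$lnvr_sd))
  n_f <- pmax(truth$n_min, round(stats::rlnorm(nr, truth$n_meanlog,
                                               truth$n_sdlog)))
  n_m <- pmax(truth$n_min, round(stats::rlnorm(nr, truth$n_meanlog,
                                               truth$n_sdlog)))
  base <- ifelse(rows$isotope == "N15",
                 stats::rnorm(nr, 10, 2), stats::rnorm(nr, -20, 3))
  female_mean <- base + stats::rnorm(nr, 0, sd_f / sqrt(n_f))
  male_mean <- base + theta + stats::rnorm(nr, 0, sd_m / sqrt(n_m))
  obs_sd <- function(s, n) s * sqrt(stats::rchisq(nr, n - 1) / (n - 1))

  i <- rows$species_i
  records <- data.frame(
    study_id = study_ids[rows$study],
    species = species$species[i],
    tissue = rows$tissue,
    isotope = rows$isotope,
    male_mean = male_mean, male_sd = obs_sd(sd_m, n_m), male_n = n_m,
    female_mean = female_mean, female_sd = obs_sd(sd_f, n_f), female_n = n_f,
    male_mass = species$male_mass[i], female_mass = species$female_mass[i],
    diet_class = species$diet_class[i],
    gape_limited = species$gape_limited[i],
    pub_year = pub_year[rows$study],
    taxon_class = species$taxon_class[i],
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  structure(list(records = records, tree = tree, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic study table:", nrow(x$records), "rows,",
      length(unique(x$records$study_id)), "studies,",
      length(unique(x$records$species)), "species\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a dataset from `truth`, runs the effect-size and
#' model-fitting pipeline, and tabulates bias, RMSE, confidence-interval
#' coverage and the Wald rejection rate for a chosen slope. With a zero true
#' slope, the rejection rate is the empirical type-I error of the Wald test;
#' with a nonzero slope, its power.
#'
#' @param truth a [sim_truth()] ledger; the true slope compared against is
#'   taken from `beta_n15` (or `beta_c13`) and must be common to the three
#'   dietary classes when `moderators` has a single `dimorphism` slope.
#' @param n_reps number of replicates (>= 2; >= 50 for stable coverage).
#' @param seed master seed; replicate r uses `seed + 1000003 * r`
#'   (mod 2^31 - 1) as its dataset seed.
#' @param moderators fixed-effect formula (default `~ dimorphism`).
#' @param slope_term coefficient whose recovery is tabulated.
#' @param isotope,metric response definition.
#' @inheritParams fit_meta
#' @return list of class `recovery`: `reps` (per-replicate estimates),
#'   `summary` (true value, mean estimate, bias, rmse, coverage,
#'   reject_rate, n_nonconverged), and the settings used.
#' @export
recovery_experiment <- function(truth = sim_truth(), n_reps = 50, seed = 1,
                                moderators = ~ dimorphism,
                                slope_term = "dimorphism",
                                isotope = "N15", metric = "MD",
                                random = c("study", "species", "phylo"),
                                method = "REML", control = list()) {
  if (n_reps < 2) stop("need at least 2 replicates", call. = FALSE)
  b <- if (isotope == "N15") truth$beta_n15 else truth$beta_c13
  slopes <- unlist(b[c("slope_carnivore", "slope_omnivore",
                       "slope_herbivore")])
  true_slope <- if (length(unique(slopes)) == 1) slopes[[1]] else NA_real_

  one <- function(r) {
    tr_truth <- truth
    tr_truth$seed <- sub_seed(seed, 1000003 * r)
    sim <- simulate_dataset(tr_truth)
    d <- prepare_effects(sim$records, metric = metric, isotope = isotope)
    A <- if ("phylo" %in% random) {
      phylo_correlation(sim$tree, unique(d$species))
    } else NULL
    fit <- tryCatch(
      withCallingHandlers(
        fit_meta(d, moderators = moderators, random = random, A = A,
                 method = method, control = control),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || !(slope_term %in% names(fit$beta))) {
      return(data.frame(rep = r, estimate = NA, se = NA, ci.lb = NA,
                        ci.ub = NA, pval = NA, converged = FALSE))
    }
    data.frame(rep = r, estimate = unname(fit$beta[slope_term]),
               se = unname(fit$se[slope_term]),
               ci.lb = unname(fit$ci.lb[slope_term]),
               ci.ub = unname(fit$ci.ub[slope_term]),
               pval = unname(fit$pval[slope_term]),
               converged = fit$converged)
  }
  reps <- do.call(rbind, lapply(seq_len(n_reps), one))
  ok <- reps$converged & is.finite(reps$estimate)
  est <- reps$estimate[ok]
  summary <- data.frame(
    term = slope_term,
    true = true_slope,
    mean_estimate = mean(est),
    bias = mean(est) - true_slope,
    rmse = sqrt(mean((est - true_slope)^2)),
    coverage = mean(reps$ci.lb[ok] <= true_slope &
                    true_slope <= reps$ci.ub[ok]),
    reject_rate = mean(reps$pval[ok] < 0.05),
    n_reps = n_reps,
    n_used = sum(ok),
    n_nonconverged = sum(!reps$converged)
  )
  structure(list(reps = reps, summary = summary, truth = truth,
                 seed = seed, moderators = moderators, method = method),
            class = "recovery")
}

#' @export
print.recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Recovery of '%s' over %d reps: true %.4g, mean %.4g ",
                     "(bias %.4g), rmse %.4g, coverage %.3f, ",
                     "reject rate %.3f, %d nonconverged\n"),
              s$term, s$n_reps, s$true, s$mean_estimate, s$bias, s$rmse,
              s$coverage, s$reject_rate, s$n_nonconverged))
  invisible(x)
}
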