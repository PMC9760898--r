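#' Read / write a study table
#'
#' The study table is delimited text with a header, one row per
#' study x species x tissue x isotope, columns named exactly as the record
#' fields: `study_id`, `species`, `tissue`, `isotope` (`N15`/`C13`),
#' `male_mean`, `male_sd`, `male_n`, `female_mean`, `female_sd`, `female_n`,
#' `male_mass`, `female_mass`, `diet_class`
#' (`carnivore`/`omnivore`/`herbivore`), `gape_limited`, `pub_year`,
#' `taxon_class`. Missing values are empty cells.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return data.frame of study records.
#' @export
read_study_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = TRUE)
}

#' @rdname read_study_table
#' @param records data.frame to write.
#' @export
write_study_table <- function(records, path, sep = "\t") {
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

study_table_columns <- c(
  "study_id", "species", "tissue", "isotope",
  "male_mean", "male_sd", "male_n",
  "female_mean", "female_sd", "female_n",
  "male_mass", "female_mass",
  "diet_class", "gape_limited", "pub_year", "taxon_class")

#' Validate a study table
#'
#' Parses and type-checks a study table, reporting per-row issues (negative
#' SD, sample size below one, nonpositive mass, unknown isotope or dietary
#' class) without aborting; only a missing header or unknown columns are a
#' hard error. Missing values are legitimate (they are handled by the
#' complete-case filter) and are not reported as issues.
#'
#' @param x a file path or a data.frame.
#' @param sep delimiter when `x` is a path.
#' @return list of class `validation`: `records` (parsed data.frame),
#'   `issues` (data.frame with `row`, `column`, `problem`), `n_issues`.
#' @export
validate_study_table <- function(x, sep = "\t") {
  records <- if (is.character(x)) read_study_table(x, sep) else
    as.data.frame(x)
  unknown <- setdiff(names(records), study_table_columns)
  missing <- setdiff(study_table_columns, names(records))
  if (length(missing) || length(unknown)) {
    stop("study table header mismatch; missing: ",
         paste(missing, collapse = ", "), "; unknown: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  issues <- list()
  note <- function(rows, column, problem) {
    if (any(rows)) {
      issues[[length(issues) + 1]] <<- data.frame(
        row = which(rows), column = column, problem = problem)
    }
  }
  isnum <- function(col) suppressWarnings(as.numeric(records[[col]]))
  for (col in c("male_sd", "female_sd")) {
    note(!is.na(isnum(col)) & isnum(col) < 0, col, "negative sd")
  }
  for (col in c("male_n", "female_n")) {
    note(!is.na(isnum(col)) & isnum(col) < 1, col, "sample size below 1")
  }
  for (col in c("male_mass", "female_mass")) {
    note(!is.na(isnum(col)) & isnum(col) <= 0, col, "nonpositive mass")
  }
  note(!is.na(records$isotope) & !records$isotope %in% c("N15", "C13"),
       "isotope", "unknown isotope")
  note(!is.na(records$diet_class) &
         !records$diet_class %in% c("carnivore", "omnivore", "herbivore"),
       "diet_class", "unknown dietary class")
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(), problem = character())
  issues <- issues[order(issues$row), , drop = FALSE]
  rownames(issues) <- NULL
  structure(list(records = records, issues = issues,
                 n_issues = nrow(issues)), class = "validation")
}

#' @export
print.validation <- function(x, ...) {
  cat("Study table:", nrow(x$records), "rows,", x$n_issues, "issue(s)\n")
  if (x$n_issues) print(utils::head(x$issues, 20))
  invisible(x)
}

#' Build an analysis-ready effect-size table
#'
#' The standard preprocessing chain: restrict to one isotope, apply the
#' complete-case filter for the requested metric (per-sex summaries always;
#' masses when moderators are required), compute effect sizes and append the
#' dimorphism and mean-size moderators.
#'
#' @param records study table (data.frame).
#' @param metric `"MD"`, `"lnVR"` or `"lnCVR"`.
#' @param isotope `"N15"` or `"C13"`.
#' @param convention dimorphism convention, see [dimorphism_index()].
#' @param require_mass drop rows with missing masses (needed whenever
#'   dimorphism or mean size enter a model); default TRUE.
#' @return data.frame of complete effect-size rows with `value`,
#'   `sampling_variance`, `dimorphism`, `mean_size` columns; attribute
#'   `filter_log` records the drop counts and reasons.
#' @export
prepare_effects <- function(records, metric = "MD", isotope = "N15",
                            convention = "log2", require_mass = TRUE) {
  records <- records[records$isotope == isotope, , drop = FALSE]
  req <- c("male_mean", "male_sd", "male_n",
           "female_mean", "female_sd", "female_n")
  if (require_mass) req <- c(req, "male_mass", "female_mass")
  cc <- complete_case_filter(records, required = req)
  es <- compute_effect_sizes(cc$kept, metric = metric)
  out <- if (require_mass) add_moderators(es, convention) else es
  attr(out, "filter_log") <- list(
    isotope = isotope, metric = metric,
    n_input = nrow(records), n_complete = cc$n_kept,
    n_dropped_incomplete = cc$n_dropped,
    incomplete_reasons = if (cc$n_dropped)
      as.list(table(cc$dropped$reason)) else list(),
    n_dropped_undefined = nrow(attr(es, "dropped")),
    n_effects = nrow(out)
  )
  out
}

#' Pipeline configuration
#'
#' Bundles every setting of a [run_pipeline()] run so results are traceable
#' to their inputs. Paths are checked at validation time.
#'
#' @param data study table: path or data.frame.
#' @param tree phylogeny: path, Newick string or `phylo`; optional unless
#'   `"phylo"` is in `random`.
#' @param metric,isotope response definition.
#' @param moderators fixed-effect formula.
#' @param random random levels, see [fit_meta()].
#' @param method `"REML"` or `"ML"`.
#' @param convention dimorphism convention.
#' @param subset optional predicate on the study table, as a one-sided
#'   formula, e.g. `~ gape_limited & diet_class == "carnivore"`.
#' @param run_loo run leave-one-out influence (n refits); default FALSE.
#' @param seed integer seed for any stochastic diagnostic.
#' @param out_dir optional output directory for the JSON/TSV result bundle.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(data, tree = NULL, metric = "MD",
                            isotope = "N15", moderators = ~ 1,
                            random = c("study", "species", "phylo"),
                            method = "REML", convention = "log2",
                            subset = NULL, run_loo = FALSE, seed = 1,
                            out_dir = NULL) {
  if (is.character(data) && !file.exists(data)) {
    stop("data file not found: ", data, call. = FALSE)
  }
  if (is.character(tree) && !file.exists(tree) && !grepl("\\(", tree)) {
    stop("tree file not found: ", tree, call. = FALSE)
  }
  if ("phylo" %in% random && is.null(tree)) {
    stop("random level 'phylo' requires a tree", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes: validation, subsetting, complete-case filtering, effect-size
#' construction, tree matching, multilevel model fit, heterogeneity
#' decomposition (on the intercept-only companion model), and the
#' publication-bias / sensitivity battery. Every exclusion and setting is
#' recorded in the returned bundle; with `out_dir` set, the bundle is
#' serialized to `results.json` plus delimited effect-size, funnel and
#' influence tables. Reruns with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_bundle`: `settings`, `filter_log`, `fit`,
#'   `coefficients`, `heterogeneity`, `diagnostics`, `n_effects`,
#'   `converged`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  val <- validate_study_table(config$data)
  records <- val$records
  if (!is.null(config$subset)) {
    keep <- eval(config$subset[[2]], records, environment(config$subset))
    keep[is.na(keep)] <- FALSE
    records <- records[keep, , drop = FALSE]
  }
  d <- prepare_effects(records, metric = config$metric,
                       isotope = config$isotope,
                       convention = config$convention)
  if (nrow(d) < 2) stop("pipeline: fewer than 2 usable effects",
                        call. = FALSE)
  A <- if ("phylo" %in% config$random) {
    phylo_correlation(config$tree, unique(d$species))
  } else NULL

  fit <- fit_meta(d, moderators = config$moderators, random = config$random,
                  A = A, method = config$method)
  fit0 <- if (length(fit$beta) == 1) fit else
    fit_meta(d, moderators = ~ 1, random = config$random, A = A,
             method = config$method)
  het <- i_squared(fit0)

  diag_list <- list(funnel = funnel_data(d))
  if (length(unique(d$pub_year)) >= 3) {
    diag_list$year_bias <- wald_inference(
      year_bias_regression(d, random = config$random, A = A,
                           method = config$method))
  }
  ws <- weight_sensitivity(d, moderators = config$moderators,
                           random = config$random, A = A,
                           method = config$method)
  diag_list$weight_sensitivity <- list(
    within_only = ws$within_only, delta_beta = ws$delta_beta)
  if (isTRUE(config$run_loo)) {
    diag_list$influence <- loo_cooks(d, moderators = config$moderators,
                                     random = config$random, A = A,
                                     method = config$method)
  }

  bundle <- structure(list(
    settings = list(
      metric = config$metric, isotope = config$isotope,
      moderators = paste(deparse(config$moderators), collapse = " "),
      random = config$random, method = config$method,
      convention = config$convention,
      subset = if (is.null(config$subset)) NA else
        paste(deparse(config$subset), collapse = " "),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("sidmeta"))
    ),
    filter_log = attr(d, "filter_log"),
    validation_issues = val$n_issues,
    n_effects = nrow(d),
    effects = d,
    fit = fit,
    coefficients = wald_inference(fit),
    sigma2 = as.list(fit$sigma2),
    loglik = fit$loglik, aicc = fit$aicc,
    heterogeneity = het,
    diagnostics = diag_list,
    converged = fit$converged
  ), class = "run_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("Pipeline run:", x$settings$metric, x$settings$isotope, "~",
      x$settings$moderators, "\n")
  cat("  effects:", x$n_effects, " I^2 total:",
      sprintf("%.2f%%", x$heterogeneity$i2_total), "\n")
  print(x$fit)
  invisible(x)
}

#' Serialize a result bundle
#'
#' Writes `results.json` (settings, coefficients, variance components,
#' criterion, heterogeneity, diagnostics) and delimited tables
#' (`effects.tsv`, `funnel_points.tsv`, `funnel_bounds.tsv`, and
#' `influence.tsv` when present) to a directory, so plots and downstream
#' checks can run headlessly from plain files.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir directory (created if needed).
#' @return invisibly, the path to `results.json`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(
    settings = bundle$settings,
    filter_log = bundle$filter_log,
    n_effects = bundle$n_effects,
    coefficients = bundle$coefficients,
    sigma2 = bundle$sigma2,
    loglik = bundle$loglik,
    aicc = bundle$aicc,
    heterogeneity = list(
      i2_total = bundle$heterogeneity$i2_total,
      i2_per_level = as.list(bundle$heterogeneity$i2_per_level),
      typical_v = bundle$heterogeneity$typical_v),
    converged = bundle$converged
  )
  if (!is.null(bundle$diagnostics$year_bias)) {
    res$year_bias <- bundle$diagnostics$year_bias
  }
  res$weight_sensitivity <- bundle$diagnostics$weight_sensitivity
  if (!is.null(bundle$diagnostics$influence)) {
    inf <- bundle$diagnostics$influence
    res$influence <- list(threshold = inf$threshold,
                          n_flagged = sum(inf$flagged, na.rm = TRUE),
                          n_refits = inf$n_refits)
    utils::write.table(
      data.frame(cooks_d = inf$cooks_d, flagged = inf$flagged,
                 indeterminate = inf$indeterminate),
      file.path(out_dir, "influence.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path <- file.path(out_dir, "results.json")
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write_study_table(bundle$effects, file.path(out_dir, "effects.tsv"))
  utils::write.table(bundle$diagnostics$funnel$points,
                     file.path(out_dir, "funnel_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$diagnostics$funnel$bounds,
                     file.path(out_dir, "funnel_bounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The nine candidate moderator structures for the dimorphism analysis
#'
#' All additive and interactive combinations of size dimorphism, dietary
#' class and species mean size that are compared by AICc when asking whether
#' ecological context modifies the dimorphism association.
#'
#' @return named list of one-sided formulas.
#' @export
candidate_formulas <- function() {
  list(
    dim_x_diet_plus_size = ~ dimorphism * diet_class + mean_size,
    dim_x_size_plus_diet = ~ dimorphism * mean_size + diet_class,
    dim_x_size           = ~ dimorphism * mean_size,
    dim_x_diet_x_size    = ~ dimorphism * diet_class * mean_size,
    dim_x_diet           = ~ dimorphism * diet_class,
    dim_plus_diet_x_size = ~ dimorphism + diet_class * mean_size,
    dim_plus_diet_plus_size = ~ dimorphism + diet_class + mean_size,
    dim_plus_size        = ~ dimorphism + mean_size,
    dim_plus_diet        = ~ dimorphism + diet_class
  )
}

#' Reproduce the full inferential battery on a deposited dataset
#'
#' Runs, from a study table and a tree, the complete analysis a reproduction
#' of the published meta-analysis requires: intercept-only multilevel models
#' and their I-squared for the four responses (mean difference and lnVR, for
#' each isotope); dimorphism-only meta-regressions for the four responses;
#' the per-diet dimorphism slopes (with mean size) for both isotopes; the
#' AICc comparison of the nine candidate moderator structures for the
#' nitrogen mean difference; the gape-limited versus non-gape-limited
#' carnivore fits; the fraction of cases with one sex more than twice as
#' variable; and the local phylogenetic signal of nitrogen sex differences
#' in gape-limited carnivores.
#'
#' @param data study table path or data.frame.
#' @param tree tree path, Newick string or `phylo`.
#' @param convention dimorphism convention (see [dimorphism_index()]); the
#'   printed-slope scale corresponds to `"log2"` (one unit = 100 percent
#'   dimorphism).
#' @param seed seed for the local-signal permutations.
#' @param out_dir optional directory for a JSON report.
#' @param selection_method criterion method for the AICc table (`"ML"`
#'   default; `"REML"` mirrors toolchains that compare REML fits).
#' @return nested list of class `reproduction` with elements `overall`
#'   (per response: `n`, `i2`, `dimorphism_slope`), `diet_interaction`
#'   (per isotope: per-diet slope triples, mean-size row), `selection`
#'   (AICc table and best formula), `gape` (per subset: slope triple, n),
#'   `twice_variable` (per isotope), `local_signal`.
#' @export
reproduce_study <- function(data, tree, convention = "log2", seed = 1,
                            out_dir = NULL, selection_method = "ML") {
  records <- validate_study_table(data)$records
  responses <- list(
    md_n15 = c("MD", "N15"), md_c13 = c("MD", "C13"),
    lnvr_n15 = c("lnVR", "N15"), lnvr_c13 = c("lnVR", "C13"))

  overall <- lapply(responses, function(rs) {
    d <- prepare_effects(records, metric = rs[1], isotope = rs[2],
                         convention = convention)
    A <- phylo_correlation(tree, unique(d$species))
    f0 <- fit_meta(d, ~ 1, A = A)
    f1 <- fit_meta(d, ~ dimorphism, A = A)
    list(n = nrow(d),
         value_range = range(d$value),
         i2 = i_squared(f0),
         pooled = wald_inference(f0),
         dimorphism_slope = wald_inference(f1)[2, ])
  })

  diet_interaction <- lapply(c(N15 = "N15", C13 = "C13"), function(iso) {
    d <- prepare_effects(records, metric = "MD", isotope = iso,
                         convention = convention)
    A <- phylo_correlation(tree, unique(d$species))
    # nested parametrization: one dimorphism slope per dietary class
    f <- fit_meta(d, ~ diet_class + diet_class:dimorphism + mean_size,
                  A = A)
    wi <- wald_inference(f)
    list(n = nrow(d),
         slopes = wi[grepl(":dimorphism", wi$term), ],
         mean_size = wi[wi$term == "mean_size", ])
  })

  d_n <- prepare_effects(records, metric = "MD", isotope = "N15",
                         convention = convention)
  A_n <- phylo_correlation(tree, unique(d_n$species))
  sel <- model_selection_table(candidate_formulas(), d_n, A = A_n,
                               method = selection_method)

  gape <- lapply(c(gape_limited = TRUE, non_gape_limited = FALSE),
                 function(flag) {
    sub <- d_n[d_n$diet_class == "carnivore" & d_n$gape_limited == flag, ,
               drop = FALSE]
    if (nrow(sub) < 3) return(list(n = nrow(sub), skipped = TRUE))
    A_s <- phylo_correlation(tree, unique(sub$species))
    f <- fit_meta(sub, ~ dimorphism, A = A_s)
    list(n = nrow(sub), dimorphism_slope = wald_inference(f)[2, ])
  })

  twice_variable <- vapply(c(N15 = "N15", C13 = "C13"), function(iso) {
    d <- prepare_effects(records, metric = "lnVR", isotope = iso,
                         convention = convention, require_mass = FALSE)
    100 * mean(abs(d$value) > log(2))
  }, 0)

  gl <- d_n[d_n$diet_class == "carnivore" & d_n$gape_limited, , drop = FALSE]
  local_signal <- if (length(unique(gl$species)) >= 3) {
    sp_val <- tapply(gl$value, gl$species, mean)
    A_g <- phylo_correlation(tree, names(sp_val))
    local_phylo_signal(sp_val, A_g, seed = seed)
  } else NULL

  out <- structure(list(
    overall = overall,
    diet_interaction = diet_interaction,
    selection = list(table = sel,
                     method = attr(sel, "method"),
                     best_formula = sel$formula[1]),
    gape = gape,
    twice_variable = twice_variable,
    local_signal = local_signal,
    convention = convention
  ), class = "reproduction")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ser <- out
    ser$overall <- lapply(out$overall, function(o)
      list(n = o$n, value_range = o$value_range,
           i2_total = o$i2$i2_total,
           i2_per_level = as.list(o$i2$i2_per_level),
           pooled = o$pooled, dimorphism_slope = o$dimorphism_slope))
    ser$local_signal <- if (is.null(out$local_signal)) NULL else
      as.data.frame(out$local_signal)
    ser$selection$table <- as.data.frame(sel)
    class(ser) <- NULL
    jsonlite::write_json(ser, file.path(out_dir, "reproduction.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  out
}

#' @export
print.reproduction <- function(x, ...) {
  cat("Reproduction battery (dimorphism convention:", x$convention, ")\n")
  for (nm in names(x$overall)) {
    o <- x$overall[[nm]]
    cat(sprintf("  %-9s n = %3d  I^2 = %6.2f%%  slope = %7.4g [%.4g, %.4g]\n",
                nm, o$n, o$i2$i2_total, o$dimorphism_slope$estimate,
                o$dimorphism_slope$ci.lb, o$dimorphism_slope$ci.ub))
  }
  cat("  best model:", x$selection$best_formula,
      "(", x$selection$method, "AICc )\n")
  invisible(x)
}
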