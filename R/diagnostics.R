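#' Funnel-plot data
#'
#' Returns each effect with its standard error plus pseudo-confidence funnel
#' boundaries: at each standard error level, the fixed-effect (inverse
#' variance weighted) mean \eqn{\pm 1.96\, se}. Emitted as plain tables so
#' the plot can be drawn — or the asymmetry inspected — headlessly.
#'
#' @param effects data.frame with `value` and `sampling_variance` columns
#'   (an output of [compute_effect_sizes()]), or a [fit_meta()] object.
#' @param n_se number of standard-error levels for the boundary table.
#' @return list of class `funnel_data`: `points` (value, se), `center`
#'   (fixed-effect mean), `bounds` (se, lower, upper).
#' @export
funnel_data <- function(effects, n_se = 50) {
  if (inherits(effects, "meta_fit")) {
    y <- effects$yi; v <- effects$vi
  } else {
    y <- effects$value; v <- effects$sampling_variance
  }
  if (any(v <= 0)) stop("sampling variances must be positive", call. = FALSE)
  se <- sqrt(v)
  w <- 1 / v
  center <- sum(w * y) / sum(w)
  zc <- stats::qnorm(0.975)
  se_grid <- seq(0, max(se) * 1.05, length.out = n_se)
  structure(list(
    points = data.frame(value = y, se = se),
    center = center,
    bounds = data.frame(se = se_grid,
                        lower = center - zc * se_grid,
                        upper = center + zc * se_grid)
  ), class = "funnel_data")
}

#' @export
print.funnel_data <- function(x, ...) {
  cat("Funnel data:", nrow(x$points), "effects, fixed-effect center",
      signif(x$center, 4), "\n")
  invisible(x)
}

#' Time-lag (publication-year) bias meta-regression
#'
#' Regresses the effect sizes on mean-centered publication year with the
#' standard multilevel random structure. A slope whose confidence interval
#' excludes zero indicates effect sizes drifting with publication year, the
#' decline-effect signature of publication bias. Centering keeps the
#' intercept interpretable as the pooled estimate at the mean year.
#'
#' @param data data.frame of effects (needs `value`, `sampling_variance`,
#'   grouping columns for `random`, and the year column).
#' @param year name of the publication-year column (default `"pub_year"`).
#' @inheritParams fit_meta
#' @return a [fit_meta()] object; the centered year column is `year_c`.
#' @export
year_bias_regression <- function(data, year = "pub_year",
                                 random = c("study", "species", "phylo"),
                                 A = NULL, method = "REML",
                                 control = list()) {
  yr <- data[[year]]
  if (is.null(yr)) stop("column `", year, "` not found", call. = FALSE)
  if (length(unique(yr[is.finite(yr)])) < 3) {
    stop("need at least 3 distinct publication years", call. = FALSE)
  }
  data$year_c <- yr - mean(yr, na.rm = TRUE)
  fit_meta(data, moderators = ~ year_c, random = random, A = A,
           method = method, control = control)
}

#' Leave-one-out Cook's distances
#'
#' Refits the model without each observation in turn and measures the
#' influence of observation i on the coefficient vector as
#' \deqn{D_i = (\hat\beta - \hat\beta_{-i})^\top
#'       \widehat{\mathrm{Cov}}(\hat\beta)^{-1}
#'       (\hat\beta - \hat\beta_{-i}).}
#' Observations with \eqn{D_i} above the threshold (default \eqn{4/n}) are
#' flagged; refits that fail to converge are flagged indeterminate.
#'
#' @param data data.frame of effects and moderators.
#' @param moderators fixed-effect formula, as in [fit_meta()].
#' @inheritParams fit_meta
#' @param threshold flag rule on \eqn{D_i}; default `4 / n`.
#' @return list of class `influence_report`: `cooks_d`, `flagged`,
#'   `indeterminate`, `beta_loo` (one refit per row), `threshold`,
#'   `n_refits`, and the full `fit`.
#' @export
loo_cooks <- function(data, moderators = ~ 1,
                      random = c("study", "species", "phylo"),
                      A = NULL, method = "REML", threshold = NULL,
                      control = list()) {
  fit <- fit_meta(data, moderators = moderators, random = random, A = A,
                  method = method, control = control)
  n <- fit$n_obs
  if (is.null(threshold)) threshold <- 4 / n
  Sinv <- solve(fit$vcov_beta)
  cooks <- rep(NA_real_, n)
  beta_loo <- matrix(NA_real_, n, length(fit$beta),
                     dimnames = list(NULL, names(fit$beta)))
  indet <- logical(n)
  for (i in seq_len(n)) {
    f_i <- tryCatch(
      withCallingHandlers(
        fit_meta(data[-i, , drop = FALSE], moderators = moderators,
                 random = random, A = A, method = method, control = control),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(f_i) || !f_i$converged ||
        length(f_i$beta) != length(fit$beta)) {
      indet[i] <- TRUE
      next
    }
    d <- fit$beta - f_i$beta
    cooks[i] <- drop(t(d) %*% Sinv %*% d)
    beta_loo[i, ] <- f_i$beta
  }
  structure(list(
    cooks_d = cooks,
    flagged = !is.na(cooks) & cooks > threshold,
    indeterminate = indet,
    beta_loo = beta_loo,
    threshold = threshold,
    n_refits = n,
    fit = fit
  ), class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat("Leave-one-out influence:", x$n_refits, "refits;",
      sum(x$flagged, na.rm = TRUE), "flagged (D >",
      signif(x$threshold, 3), ");", sum(x$indeterminate),
      "indeterminate\n")
  invisible(x)
}

#' Sensitivity to the weighting scheme
#'
#' Compares the standard multilevel fit (weights from the full marginal
#' variance, sampling plus estimated heterogeneity) against a fit whose
#' weights are only the inverse within-study sampling variances
#' \eqn{w_i = 1/v_i}: \eqn{\hat\beta_w = (X^\top W X)^{-1} X^\top W y}, with
#' a sandwich covariance under the estimated marginal variance. When
#' between-study heterogeneity dominates, the standard weights flatten
#' toward equality and can mask the within-study precision ranking; the
#' delta between the two coefficient vectors measures how much that choice
#' matters.
#'
#' @inheritParams loo_cooks
#' @return list of class `weight_sensitivity`: `standard` ([fit_meta()]
#'   object), `within_only` (data.frame of estimate/se/ci per term),
#'   `delta_beta`.
#' @export
weight_sensitivity <- function(data, moderators = ~ 1,
                               random = c("study", "species", "phylo"),
                               A = NULL, method = "REML", control = list()) {
  fit <- fit_meta(data, moderators = moderators, random = random, A = A,
                  method = method, control = control)
  X <- fit$X
  y <- fit$yi
  W <- 1 / fit$vi
  XtW <- t(X * W)
  Bw <- XtW %*% X
  beta_w <- drop(solve(Bw, XtW %*% y))
  # sandwich: Cov = (X'WX)^-1 X'W Vhat W X (X'WX)^-1 with Vhat at the
  # REML/ML variance components of the standard fit
  M <- make_level_matrices(fit$data, fit$random, attr_A(fit, A), fit$n_obs)
  V <- diag(fit$vi, fit$n_obs)
  for (l in seq_along(M)) V <- V + fit$sigma2[l] * M[[l]]
  meat <- XtW %*% V %*% t(XtW)
  cv <- solve(Bw, t(solve(Bw, meat)))
  se_w <- sqrt(diag(cv))
  zc <- stats::qnorm(0.975)
  within_only <- data.frame(term = names(fit$beta), estimate = beta_w,
                            se = se_w,
                            ci.lb = beta_w - zc * se_w,
                            ci.ub = beta_w + zc * se_w, row.names = NULL)
  structure(list(
    standard = fit,
    within_only = within_only,
    delta_beta = beta_w - unname(fit$beta)
  ), class = "weight_sensitivity")
}

attr_A <- function(fit, A) if ("phylo" %in% fit$random) A else NULL

#' @export
print.weight_sensitivity <- function(x, ...) {
  cat("Weighting sensitivity; max |delta beta| =",
      signif(max(abs(x$delta_beta)), 4), "\n")
  invisible(x)
}

#' Complete-case filter with logged reasons
#'
#' Partitions study records into those complete for the requested fields and
#' those dropped, each drop carrying the name(s) of the missing fields.
#' Mirrors a complete-case analysis in which rows missing any predictor or
#' effect-size ingredient are removed before modelling.
#'
#' @param records data.frame of study records.
#' @param required character vector of column names that must be non-missing.
#' @return list of class `case_filter`: `kept` (data.frame), `dropped`
#'   (data.frame with a `reason` column), `n_kept`, `n_dropped`.
#' @export
complete_case_filter <- function(records,
                                 required = c("male_mean", "male_sd",
                                              "male_n", "female_mean",
                                              "female_sd", "female_n",
                                              "male_mass", "female_mass")) {
  records <- as.data.frame(records)
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("required columns absent from the table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- sapply(records[required], function(x) is.na(x))
  if (is.null(dim(bad))) bad <- matrix(bad, nrow = nrow(records))
  drop_row <- rowSums(bad) > 0
  reason <- apply(bad, 1, function(b)
    paste("missing:", paste(required[b], collapse = ", ")))
  dropped <- records[drop_row, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[drop_row]
  else dropped$reason <- character(0)
  structure(list(
    kept = records[!drop_row, , drop = FALSE],
    dropped = dropped,
    n_kept = sum(!drop_row),
    n_dropped = sum(drop_row)
  ), class = "case_filter")
}

#' @export
print.case_filter <- function(x, ...) {
  cat("Complete-case filter:", x$n_kept, "kept,", x$n_dropped, "dropped\n")
  if (x$n_dropped) {
    tab <- table(x$dropped$reason)
    for (nm in names(tab)) cat("  ", nm, ":", tab[[nm]], "\n")
  }
  invisible(x)
}
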