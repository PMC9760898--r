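#' Fit a multilevel random-effects meta-analysis / meta-regression
#'
#' Fits the marginal model \eqn{y \sim N(X\beta,\; V)} with
#' \eqn{V = \sum_L \sigma^2_L Z_L G_L Z_L^\top + \mathrm{diag}(v_i)}, where
#' \eqn{y} are effect sizes, \eqn{v_i} their known sampling variances, and the
#' random levels are any subset of:
#' \describe{
#'   \item{study}{grouping by `study_id`, \eqn{G = I} — between-study
#'     heterogeneity shared by rows (tissues, isotopes) of one study.}
#'   \item{species}{grouping by `species`, \eqn{G = I} — species-specific
#'     deviations independent of relatedness.}
#'   \item{phylo}{grouping by `species`, \eqn{G = A} the phylogenetic
#'     correlation matrix from [phylo_correlation()] — Brownian-motion
#'     covariance among related species.}
#'   \item{observation}{one effect per row, \eqn{G = I} — residual
#'     heterogeneity beyond sampling error (off unless requested).}
#' }
#' Variance components are estimated by restricted maximum likelihood (REML,
#' default) or ML, by quasi-Newton optimization on log variance components
#' with an analytic gradient and three deterministic starting points;
#' \eqn{\hat\beta} is the GLS solution at the optimum with Wald z inference.
#'
#' @param data data.frame holding the response, sampling variances, grouping
#'   columns (`study_id`, `species` as needed by `random`) and any moderators.
#' @param moderators model formula for the fixed effects, e.g.
#'   `~ dimorphism * diet_class + mean_size`; the intercept is always
#'   retained. A two-sided formula's left side is ignored.
#' @param value,vi names of the effect-size and sampling-variance columns.
#' @param random character subset of
#'   `c("study", "species", "phylo", "observation")`.
#' @param A phylogenetic correlation matrix, required iff `"phylo"` is in
#'   `random`; its dimnames must cover `data$species`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control list: `reltol` convergence tolerance on the criterion
#'   (default 1e-8), `sigma2_floor` values below which a component is reported
#'   as zero (default 1e-8), `starts` number of deterministic starting points
#'   (default 3; later starts are skipped once two agree within `reltol`).
#' @return an object of class `meta_fit`; see [wald_inference()],
#'   [i_squared()], [aicc()], [predict_with_band()].
#' @examples
#' d <- data.frame(value = c(0.2, 0.5, -0.1, 0.4), sampling_variance = 0.04,
#'                 study_id = c("s1", "s1", "s2", "s3"),
#'                 species = c("a", "a", "b", "c"))
#' fit <- fit_meta(d, random = c("study", "species"))
#' @export
fit_meta <- function(data, moderators = ~ 1, value = "value",
                     vi = "sampling_variance",
                     random = c("study", "species", "phylo"),
                     A = NULL, method = c("REML", "ML"),
                     control = list()) {
  method <- match.arg(method)
  ctl <- utils::modifyList(list(reltol = 1e-8, sigma2_floor = 1e-8,
                                starts = 3L), control)
  data <- as.data.frame(data)
  random <- if (length(random)) {
    match.arg(random, c("study", "species", "phylo", "observation"),
              several.ok = TRUE)
  } else character(0)

  y <- data[[value]]
  v <- data[[vi]]
  if (is.null(y) || is.null(v)) {
    stop("columns `", value, "` and `", vi, "` are required", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("effect sizes must be finite and sampling variances positive; ",
         "run complete_case_filter()/compute_effect_sizes() first",
         call. = FALSE)
  }
  n <- length(y)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)

  # fixed-effect design
  mf <- if (inherits(moderators, "formula")) moderators else
    stats::as.formula(moderators)
  tt <- stats::delete.response(stats::terms(mf, data = data))
  frame <- stats::model.frame(tt, data, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, frame)
  xlev <- stats::.getXlevels(tt, frame)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    stop("rank-deficient fixed-effect design; aliased columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "),
         call. = FALSE)
  }
  if (n <= p) stop("more fixed-effect columns than observations",
                   call. = FALSE)

  # random-level 'M' matrices: V = sum sigma2_l * M_l + diag(v)
  M <- make_level_matrices(data, random, A, n)
  L <- length(M)

  neg_crit <- function(theta) crit_eval(theta, y, X, v, M, method,
                                        want_grad = FALSE)$nll
  neg_grad <- function(theta) crit_eval(theta, y, X, v, M, method,
                                        want_grad = TRUE)$ngr

  if (L > 0) {
    t0 <- max(stats::var(y) - mean(v), 0.01 * stats::var(y), 1e-4)
    starts <- list(rep(log(t0 / L), L),
                   rep(log(t0 / L) + log(0.1), L),
                   rep(log(t0 / L) + log(10), L))
    starts <- starts[seq_len(max(1L, min(ctl$starts, 3L)))]
    best <- NULL
    n_hit <- 0L
    for (s in starts) {
      op <- stats::nlminb(s, neg_crit, gradient = neg_grad,
                          lower = rep(log(1e-10), L),
                          upper = rep(log(1e6), L),
                          control = list(rel.tol = ctl$reltol,
                                         iter.max = 500L))
      if (is.null(best) || op$objective < best$objective - ctl$reltol) {
        best <- op; n_hit <- 1L
      } else if (op$objective < best$objective + ctl$reltol) {
        n_hit <- n_hit + 1L
        if (op$objective < best$objective) best <- op
      }
      if (n_hit >= 2L) break
    }
    sigma2 <- exp(best$par)
    sigma2[sigma2 < ctl$sigma2_floor] <- 0
    converged <- best$convergence == 0 ||
      grepl("relative convergence|X-convergence|both X.*relative",
            best$message, ignore.case = TRUE)
  } else {
    sigma2 <- numeric(0)
    converged <- TRUE
  }

  fin <- crit_eval(log(pmax(sigma2, 1e-12)), y, X, v, M, method,
                   want_beta = TRUE)

  beta <- drop(fin$beta)
  names(beta) <- colnames(X)
  vb <- fin$vcov_beta
  dimnames(vb) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vb))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  zc <- stats::qnorm(0.975)

  names(sigma2) <- names(M)
  n_param <- p + L

  out <- structure(list(
    beta = beta, se = se, zval = zval, pval = pval,
    ci.lb = beta - zc * se, ci.ub = beta + zc * se,
    vcov_beta = vb,
    sigma2 = sigma2,
    loglik = -fin$nll,
    method = method,
    n_obs = n, n_param = n_param,
    converged = converged,
    yi = y, vi = v, X = X,
    random = names(M),
    moderators = mf, terms = tt, xlev = xlev,
    data = data,
    call = match.call()
  ), class = "meta_fit")
  out$aicc <- tryCatch(aicc(out), error = function(e) NA_real_)
  if (!converged) warning("fit_meta: optimizer did not report convergence")
  out
}

# Z_L G_L Z_L^T for each requested random level.
make_level_matrices <- function(data, random, A, n) {
  M <- list()
  for (lev in random) {
    if (lev == "observation") {
      M[[lev]] <- diag(n)
      next
    }
    col <- if (lev == "study") "study_id" else "species"
    g <- data[[col]]
    if (is.null(g)) {
      stop("random level '", lev, "' needs column `", col, "`", call. = FALSE)
    }
    g <- factor(g)
    Z <- stats::model.matrix(~ 0 + g)
    if (lev == "phylo") {
      if (is.null(A)) {
        stop("random level 'phylo' requires a correlation matrix `A`",
             call. = FALSE)
      }
      sp <- levels(g)
      if (!all(sp %in% colnames(A))) {
        stop("correlation matrix lacks species: ",
             paste(setdiff(sp, colnames(A)), collapse = ", "), call. = FALSE)
      }
      M[[lev]] <- Z %*% A[sp, sp, drop = FALSE] %*% t(Z)
    } else {
      M[[lev]] <- tcrossprod(Z)
    }
  }
  M
}

# (Restricted) log-likelihood of the marginal model at log variance
# components `theta`, with optional analytic gradient and GLS beta.
# Returns the NEGATIVE criterion (for minimizers).
crit_eval <- function(theta, y, X, v, M, method,
                      want_grad = FALSE, want_beta = FALSE) {
  n <- length(y); p <- ncol(X); L <- length(M)
  sigma2 <- exp(theta)
  V <- diag(v, n)
  for (l in seq_len(L)) V <- V + sigma2[l] * M[[l]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    return(list(nll = 1e10, ngr = rep(0, L)))
  }
  Vi <- chol2inv(R)
  logdetV <- 2 * sum(log(diag(R)))
  XtVi <- crossprod(X, Vi)                   # p x n
  B <- XtVi %*% X                            # X' Vi X
  Bc <- chol(B)
  logdetB <- 2 * sum(log(diag(Bc)))
  beta <- backsolve(Bc, backsolve(Bc, XtVi %*% y, transpose = TRUE))
  r <- y - X %*% beta
  Vir <- Vi %*% r                            # equals P y
  quad <- sum(r * Vir)

  ll <- if (method == "REML") {
    -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetB + quad)
  } else {
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  }

  out <- list(nll = -ll)
  if (want_grad) {
    if (method == "REML") {
      # P = Vi - Vi X (X'ViX)^-1 X'Vi ;  P y = Vi r
      H <- Vi - crossprod(XtVi, backsolve(Bc, backsolve(Bc, XtVi,
                                                        transpose = TRUE)))
    } else {
      H <- Vi
    }
    gr <- numeric(L)
    for (l in seq_len(L)) {
      tr_l <- sum(H * M[[l]])
      qf_l <- drop(crossprod(Vir, M[[l]] %*% Vir))
      gr[l] <- -0.5 * (tr_l - qf_l) * sigma2[l]   # d ll / d log sigma2_l
    }
    out$ngr <- -gr
  }
  if (want_beta) {
    out$beta <- beta
    out$vcov_beta <- chol2inv(Bc)
  }
  out
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (", x$method, ")\n", sep = "")
  cat("  k =", x$n_obs, "effect sizes;",
      length(x$beta), "fixed effect(s);",
      length(x$sigma2), "variance component(s)\n")
  if (length(x$sigma2)) {
    cat("  sigma^2:",
        paste(sprintf("%s = %.*g", names(x$sigma2), digits, x$sigma2),
              collapse = ", "), "\n")
  }
  cat("  logLik =", format(x$loglik, digits = digits),
      "  AICc =", format(x$aicc, digits = digits),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n\n")
  print(wald_inference(x), digits = digits)
  invisible(x)
}

#' Wald z inference for the fixed effects of a fitted model
#'
#' Per-coefficient z statistic (`estimate/se`), two-sided normal p-value, and
#' 95 percent confidence bounds `estimate +/- 1.96 se`.
#'
#' @param model a [fit_meta()] object.
#' @return data.frame with columns `term`, `estimate`, `se`, `zval`, `pval`,
#'   `ci.lb`, `ci.ub`.
#' @export
wald_inference <- function(model) {
  stopifnot(inherits(model, "meta_fit"))
  data.frame(term = names(model$beta), estimate = unname(model$beta),
             se = unname(model$se), zval = unname(model$zval),
             pval = unname(model$pval), ci.lb = unname(model$ci.lb),
             ci.ub = unname(model$ci.ub), row.names = NULL)
}

#' Multilevel heterogeneity (I-squared)
#'
#' Decomposes total heterogeneity for an intercept-only multilevel model.
#' The typical within-study sampling variance is
#' \deqn{\bar v = \frac{(k-1) \sum_i w_i}{(\sum_i w_i)^2 - \sum_i w_i^2},
#'       \qquad w_i = 1/v_i,}
#' and \eqn{I^2_{total} = 100\,\sum_L \sigma^2_L / (\sum_L \sigma^2_L + \bar v)}
#' with each level's share proportional to its \eqn{\sigma^2_L}.
#'
#' @param model an intercept-only [fit_meta()] object.
#' @param variances optional override of the sampling variances (defaults to
#'   those stored in the fit).
#' @return list of class `heterogeneity`: `i2_total` and `i2_per_level`
#'   (percent), `typical_v` (squared response units).
#' @export
i_squared <- function(model, variances = NULL) {
  stopifnot(inherits(model, "meta_fit"))
  if (length(model$beta) != 1 || names(model$beta)[1] != "(Intercept)") {
    stop("I^2 is defined for the intercept-only model", call. = FALSE)
  }
  v <- if (is.null(variances)) model$vi else variances
  k <- length(v)
  if (k < 2) stop("need at least 2 observations", call. = FALSE)
  w <- 1 / v
  typical_v <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  s2 <- model$sigma2
  tot <- sum(s2)
  i2_total <- 100 * tot / (tot + typical_v)
  per <- if (length(s2)) 100 * s2 / (tot + typical_v) else numeric(0)
  structure(list(i2_total = i2_total, i2_per_level = per,
                 typical_v = typical_v),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("I^2 total: %.2f%%  (typical sampling variance %.4g)\n",
              x$i2_total, x$typical_v))
  for (nm in names(x$i2_per_level)) {
    cat(sprintf("  %-12s %6.2f%%\n", nm, x$i2_per_level[[nm]]))
  }
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\,\ell + 2p + 2p(p+1)/(n-p-1)} with \eqn{p} the number of
#' estimated parameters (fixed-effect columns plus variance components) and
#' \eqn{n} the number of effect sizes. Model comparisons across different
#' fixed-effect structures should use ML fits (see
#' [model_selection_table()]); REML criteria are only comparable at a fixed
#' design.
#'
#' @param object a [fit_meta()] object, or a numeric log-likelihood.
#' @param n_param,n_obs required when `object` is a bare log-likelihood.
#' @return numeric AICc.
#' @export
aicc <- function(object, n_param = NULL, n_obs = NULL) {
  if (inherits(object, "meta_fit")) {
    ll <- object$loglik; p <- object$n_param; n <- object$n_obs
  } else {
    ll <- object; p <- n_param; n <- n_obs
    if (is.null(p) || is.null(n)) {
      stop("supply n_param and n_obs with a bare log-likelihood",
           call. = FALSE)
    }
  }
  if (!is.finite(ll)) stop("log-likelihood is not finite", call. = FALSE)
  if (n - p - 1 <= 0) {
    stop("AICc undefined: n - p - 1 must be positive", call. = FALSE)
  }
  -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Compare moderator structures by AICc
#'
#' Fits every candidate fixed-effect structure on the same data and random
#' levels and returns them sorted by AICc (ascending; lower is better). Fits
#' use ML by default, since likelihoods under REML are not comparable across
#' fixed-effect structures; the criterion method is recorded in the
#' `method` attribute. Candidates whose AICc differ by less than 0.01 share a
#' rank.
#'
#' @param formulas list of moderator formulas (or character strings).
#' @param data,value,vi,random,A,control as in [fit_meta()].
#' @param method criterion method, `"ML"` (default) or `"REML"`.
#' @return data.frame with columns `formula`, `n_param`, `loglik`, `aicc`,
#'   `delta`, `rank`, `converged`, sorted by AICc; attributes `method` and
#'   `fits` (the fitted models, in input order).
#' @export
model_selection_table <- function(formulas, data, value = "value",
                                  vi = "sampling_variance",
                                  random = c("study", "species", "phylo"),
                                  A = NULL, method = c("ML", "REML"),
                                  control = list()) {
  method <- match.arg(method)
  if (inherits(formulas, "formula")) formulas <- list(formulas)
  fits <- lapply(formulas, function(f) {
    withCallingHandlers(
      fit_meta(data, moderators = f, value = value, vi = vi,
               random = random, A = A, method = method, control = control),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  tab <- data.frame(
    formula = vapply(formulas, function(f)
      paste(deparse(stats::as.formula(f)), collapse = " "), ""),
    n_param = vapply(fits, function(f) f$n_param, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aicc = vapply(fits, function(f) f$aicc, 0),
    converged = vapply(fits, function(f) f$converged, TRUE)
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1]
  # equal rank for ties closer than 0.01 AICc units
  rk <- integer(nrow(tab))
  if (nrow(tab)) {
    rk[1] <- 1L
    for (i in seq_len(nrow(tab))[-1]) {
      rk[i] <- if (tab$aicc[i] - tab$aicc[i - 1] < 0.01) rk[i - 1] else
        rk[i - 1] + 1L
    }
  }
  tab$rank <- rk
  rownames(tab) <- NULL
  attr(tab, "method") <- method
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Meta-regression predictions with a 95 percent Wald band
#'
#' Evaluates \eqn{x^\top \hat\beta} on a moderator grid with the band
#' \eqn{\pm 1.96 \sqrt{x^\top \widehat{\mathrm{Cov}}(\hat\beta)\, x}} from the
#' fixed-effect covariance, the quantity plotted as a meta-regression line
#' with its confidence ribbon.
#'
#' @param model a [fit_meta()] object.
#' @param grid data.frame of moderator values; columns (and factor levels)
#'   must match the fitted design.
#' @return data.frame: the grid with `estimate`, `ci.lb`, `ci.ub` appended.
#' @export
predict_with_band <- function(model, grid) {
  stopifnot(inherits(model, "meta_fit"))
  grid <- as.data.frame(grid)
  Xg <- tryCatch(
    stats::model.matrix(model$terms,
                        stats::model.frame(model$terms, grid,
                                           na.action = stats::na.fail,
                                           xlev = model$xlev),
                        xlev = model$xlev),
    error = function(e) stop("grid incompatible with the fitted design: ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(colnames(Xg), names(model$beta))) {
    stop("grid columns do not span the fitted design", call. = FALSE)
  }
  est <- drop(Xg %*% model$beta)
  se <- sqrt(rowSums((Xg %*% model$vcov_beta) * Xg))
  zc <- stats::qnorm(0.975)
  cbind(grid, data.frame(estimate = est,
                         ci.lb = est - zc * se, ci.ub = est + zc * se))
}
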