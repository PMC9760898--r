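#' Delta notation for stable isotope ratios
#'
#' Expresses a sample's heavy:light isotope ratio relative to an international
#' standard (air for nitrogen, VPDB for carbon) in permil (‰):
#' \eqn{\delta = 1000 \, (R_{sample} - R_{standard}) / R_{standard}}.
#' Positive values indicate heavy-isotope enrichment of the sample relative to
#' the standard.
#'
#' Literature isotope data are almost always already reported in ‰; this
#' helper exists for utilities and simulation, not as a processing step.
#'
#' @param r_sample numeric, isotope ratio(s) of the sample (heavy/light).
#' @param r_standard numeric, isotope ratio of the standard; must be > 0.
#' @return numeric, delta value(s) in permil.
#' @examples
#' delta_value(0.0036, 0.0036765) # approx -20.8 permil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("`r_standard` must be a positive finite isotope ratio", call. = FALSE)
  }
  1000 * (r_sample - r_standard) / r_standard
}

#' Sex-difference effect sizes from per-sex isotope summaries
#'
#' Computes, for each row of a study table, one of three effect-size metrics
#' for the male-female contrast in an isotope value, with its sampling
#' variance:
#' \describe{
#'   \item{MD}{raw mean difference \eqn{\bar{x}_m - \bar{x}_f} (‰);
#'     sampling variance \eqn{s_m^2/n_m + s_f^2/n_f} (unpooled two-sample
#'     form). Positive = males heavy-isotope enriched.}
#'   \item{lnVR}{bias-corrected log variability ratio
#'     \eqn{\ln(s_m/s_f) + \frac{1}{2(n_m-1)} - \frac{1}{2(n_f-1)}};
#'     sampling variance \eqn{\frac{1}{2(n_m-1)} + \frac{1}{2(n_f-1)}}.
#'     Positive = males more variable; \eqn{|lnVR| > \ln 2} means one sex is
#'     more than twice as variable as the other.}
#'   \item{lnCVR}{bias-corrected log coefficient-of-variation ratio
#'     \eqn{\ln\frac{s_m/|\bar{x}_m|}{s_f/|\bar{x}_f|}} plus the same
#'     small-sample correction as lnVR; sampling variance
#'     \eqn{\frac{s_m^2}{n_m \bar{x}_m^2} + \frac{1}{2(n_m-1)} +
#'          \frac{s_f^2}{n_f \bar{x}_f^2} + \frac{1}{2(n_f-1)}}.}
#' }
#'
#' Rows whose required summaries are missing or invalid for the requested
#' metric (e.g. zero SD for lnVR, zero mean for lnCVR, n < 2) are dropped and
#' reported in the `dropped` attribute with a per-row reason, mirroring a
#' complete-case analysis.
#'
#' @param records data.frame of study records (see [read_study_table()] for
#'   the column contract: `male_mean`, `male_sd`, `male_n`, `female_mean`,
#'   `female_sd`, `female_n` and metadata columns).
#' @param metric one of `"MD"`, `"lnVR"`, `"lnCVR"`.
#' @return data.frame: the input rows that survived filtering, with columns
#'   `metric`, `value`, `sampling_variance` appended; attribute `dropped` is a
#'   data.frame of row indices and reasons.
#' @seealso [dimorphism_index()], [mean_species_size()], [fit_meta()]
#' @export
compute_effect_sizes <- function(records, metric = c("MD", "lnVR", "lnCVR")) {
  metric <- match.arg(metric)
  records <- as.data.frame(records)
  need <- c("male_mean", "female_mean", "male_sd", "female_sd",
            "male_n", "female_n")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("study table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  mm <- records$male_mean;  fm <- records$female_mean
  ms <- records$male_sd;    fs <- records$female_sd
  mn <- records$male_n;     fn <- records$female_n

  reason <- character(nrow(records))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- why
  }
  bad(!is.finite(mm) | !is.finite(fm), "missing mean")
  if (metric != "MD" || TRUE) bad(!is.finite(ms) | !is.finite(fs), "missing sd")
  bad(!is.finite(mn) | !is.finite(fn), "missing n")
  bad(ms < 0 | fs < 0, "negative sd")
  bad(mn < 1 | fn < 1, "n below 1")
  if (metric %in% c("lnVR", "lnCVR")) {
    bad(ms == 0 | fs == 0, "zero sd undefined for variability ratio")
    bad(mn < 2 | fn < 2, "n below 2 for variability ratio")
  }
  if (metric == "lnCVR") bad(mm == 0 | fm == 0, "zero mean undefined for lnCVR")

  keep <- reason == ""
  mm <- mm[keep]; fm <- fm[keep]; ms <- ms[keep]; fs <- fs[keep]
  mn <- mn[keep]; fn <- fn[keep]

  es <- switch(metric,
    MD = list(value = mm - fm,
              vi    = ms^2 / mn + fs^2 / fn),
    lnVR = {
      corr <- 1 / (2 * (mn - 1)) - 1 / (2 * (fn - 1))
      list(value = log(ms / fs) + corr,
           vi    = 1 / (2 * (mn - 1)) + 1 / (2 * (fn - 1)))
    },
    lnCVR = {
      corr <- 1 / (2 * (mn - 1)) - 1 / (2 * (fn - 1))
      list(value = log((ms / abs(mm)) / (fs / abs(fm))) + corr,
           vi    = ms^2 / (mn * mm^2) + 1 / (2 * (mn - 1)) +
                   fs^2 / (fn * fm^2) + 1 / (2 * (fn - 1)))
    })

  out <- records[keep, , drop = FALSE]
  out$metric <- rep(metric, nrow(out))
  out$value <- es$value
  out$sampling_variance <- es$vi
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    row = which(!keep),
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}

#' Sexual size dimorphism index
#'
#' Signed index of mass dimorphism. The default convention is
#' \eqn{\log_2(M_{male}/M_{female})}, so that one unit corresponds to a
#' two-fold (100 percent) male-biased dimorphism and the sign is positive iff
#' males are heavier. The alternative `"relative"` convention is the
#' untransformed proportional difference \eqn{(M_m - M_f)/\bar{M}} with
#' \eqn{\bar{M}} the male-female mean mass.
#'
#' @param male_mass,female_mass numeric, body masses in kg; must be > 0.
#' @param convention `"log2"` (default) or `"relative"`.
#' @return numeric dimorphism index (dimensionless).
#' @examples
#' dimorphism_index(2, 1)            # 1: males twice as heavy
#' dimorphism_index(0.1, 1)          # approx -3.32: 10x female-biased
#' @export
dimorphism_index <- function(male_mass, female_mass,
                             convention = c("log2", "relative")) {
  convention <- match.arg(convention)
  ok <- is.na(male_mass) | is.na(female_mass) |
    (male_mass > 0 & female_mass > 0)
  if (!all(ok)) stop("body masses must be positive", call. = FALSE)
  switch(convention,
    log2     = log2(male_mass / female_mass),
    relative = (male_mass - female_mass) /
               ((male_mass + female_mass) / 2))
}

#' Mean species size
#'
#' Arithmetic mean of male and female body mass, the "species mean size"
#' moderator used alongside dimorphism in meta-regressions.
#'
#' @inheritParams dimorphism_index
#' @return numeric, kg.
#' @export
mean_species_size <- function(male_mass, female_mass) {
  ok <- is.na(male_mass) | is.na(female_mass) |
    (male_mass > 0 & female_mass > 0)
  if (!all(ok)) stop("body masses must be positive", call. = FALSE)
  (male_mass + female_mass) / 2
}

#' Append moderator columns to a study or effect-size table
#'
#' Adds `dimorphism` (see [dimorphism_index()]) and `mean_size`
#' (see [mean_species_size()]) computed from the `male_mass` / `female_mass`
#' columns.
#'
#' @param records data.frame with `male_mass` and `female_mass` columns (kg).
#' @param convention passed to [dimorphism_index()].
#' @return the input with `dimorphism` and `mean_size` columns appended.
#' @export
add_moderators <- function(records, convention = c("log2", "relative")) {
  convention <- match.arg(convention)
  records$dimorphism <- dimorphism_index(records$male_mass,
                                         records$female_mass, convention)
  records$mean_size <- mean_species_size(records$male_mass,
                                         records$female_mass)
  records
}
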