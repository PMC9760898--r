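---
title: "Methods: multilevel phylogenetic meta-analysis of isotopic sex differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel phylogenetic meta-analysis of isotopic sex differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidmeta)
```

## Scope and data model

`sidmeta` quantifies how sexual size dimorphism relates to sex differences
in stable-isotope ratios (δ¹⁵N, δ¹³C) across vertebrate species, using only
published per-sex summary statistics. The unit of analysis is one
study × species × tissue × isotope row holding the male and female mean, SD
and sample size (‰), per-sex body masses (kg), a dietary class
(carnivore / omnivore / herbivore), a gape-limitation flag and the
publication year. Literature screening, figure digitisation and body-mass
lookup are outside the package's scope: the study table and a Newick tree
are its inputs.

## Effect sizes

Three metrics are computed per row, each with a known sampling variance
used as the model weight:

* **Raw mean difference (MD)**, ‰: $\bar x_m - \bar x_f$, variance
  $s_m^2/n_m + s_f^2/n_f$. The *unpooled* two-sample form is used: the
  sexes are different populations and nothing justifies pooling their
  variances.
* **lnVR**: $\ln(s_m/s_f) + \frac{1}{2(n_m-1)} - \frac{1}{2(n_f-1)}$,
  variance $\frac{1}{2(n_m-1)} + \frac{1}{2(n_f-1)}$. The additive terms
  are the standard small-sample bias correction for a log sample-SD; they
  cancel at equal $n$ and vanish asymptotically. $|lnVR| > \ln 2$ marks one
  sex as more than twice as variable as the other.
* **lnCVR**: the log ratio of coefficients of variation with the same
  correction; its variance adds the mean-driven terms
  $s^2/(n\,\bar x^2)$ per sex. lnVR is the headline variability metric —
  isotope data are deviations from an international standard, so rescaling
  variability by the group mean (as lnCVR does) can misrepresent a sex's
  ecological niche width; lnCVR is kept for mean–variance sensitivity
  checks. Algebraically, $lnVR - lnCVR = \ln(|\bar x_m|/|\bar x_f|)$ on
  identical inputs, which the tests exploit.

Rows that cannot support a metric (zero SD for variability ratios, zero
mean for lnCVR, $n < 2$, missing summaries) are excluded with per-row
logged reasons; models use complete cases only, and rows missing body mass
are dropped whenever dimorphism or mean size enters a model.

### Moderators

The literature quantity "size dimorphism" has no unique numeric
convention, so the package makes one explicit and configurable:

* default `log2`: $d = \log_2(M_m/M_f)$, so $d = 1$ is a two-fold (100 %)
  male-biased dimorphism and $d = -\log_2 10 \approx -3.32$ a ten-fold
  female-biased one. This makes "a dimorphism of 100 % raises δ¹⁵N by the
  slope" literally true, is symmetric under sex exchange
  ($d \mapsto -d$), and keeps extreme ratios on a linear scale;
* alternative `relative`: $(M_m - M_f)/\bar M$, an untransformed
  proportional difference, for sensitivity to the convention choice.

`mean_size` is the arithmetic mean of the two masses (kg).

## The multilevel model

Effects $y_i$ with sampling variances $v_i$ follow

$$y \sim N(X\beta, V), \qquad
V = \sigma^2_{study}\,Z_sZ_s^\top + \sigma^2_{species}\,Z_pZ_p^\top +
    \sigma^2_{phylo}\,Z_pAZ_p^\top + \mathrm{diag}(v_i).$$

The study level absorbs shared methodology across a study's rows (tissues,
isotopes of the same specimens — the pseudoreplication channel); the
species level absorbs species idiosyncrasy independent of relatedness; the
phylogenetic level shares variance between relatives through $A$, the
Brownian-motion correlation matrix (shared root-to-tip path length divided
by tree depth, computed on the full tree and then subset so that shared
history is preserved for any species subset). An observation-level
component is available but off by default: the three listed levels define
the model, and with a single effect per row the observation level is only
weakly separated from the sampling variances.

Assumptions worth stating: sampling variances are treated as known (the
usual meta-analytic convention); random effects are Gaussian; the
phylogenetic effect follows Brownian motion on the given tree (no
Pagel's λ or OU damping); and inference on $\beta$ is Wald z — normal
quantiles, not t — matching standard multilevel meta-analytic practice.
With ~160 species this slightly understates tail risk; the recovery
experiments below measure the realised coverage.

### Estimation

The (restricted) log-likelihood is maximised over log variance components
by bounded quasi-Newton (`nlminb`) with an analytic gradient
($\partial\ell/\partial\sigma^2_L = -\tfrac12[\mathrm{tr}(P M_L) -
y^\top P M_L P y]$ with $M_L = Z_LG_LZ_L^\top$), a convergence tolerance of
1e-8 on the criterion, and three deterministic starting points (a
method-of-moments split of the excess variance, and that value scaled by
0.1 and 10). Remaining starts are skipped once two have reached the same
optimum within tolerance — the surfaces here are well behaved and the
analytic gradient makes each start cheap, so this preserves the multistart
safety net without tripling every fit. Components converging below 1e-8
are reported as exactly zero. $\hat\beta$ is the GLS estimate at the
optimum, with covariance $(X^\top V^{-1}X)^{-1}$.

REML is the default for estimation; model-selection tables default to ML
because REML likelihoods are not comparable across fixed-effect
structures. The criterion method is always recorded in the table. AICc is
$-2\ell + 2p + 2p(p+1)/(n-p-1)$ with $p$ counting fixed-effect columns
*plus* estimated variance components and $n$ the number of effects; the
parameter count convention matters for AICc and is therefore stated
explicitly. Candidates closer than 0.01 AICc units share a rank rather
than being ordered arbitrarily.

### Heterogeneity

For the intercept-only model,
$\bar v = (k-1)\sum w_i/((\sum w_i)^2 - \sum w_i^2)$ (with $w_i = 1/v_i$)
is the typical sampling variance, and
$I^2 = 100\,\Sigma\sigma^2_L/(\Sigma\sigma^2_L + \bar v)$ with per-level
shares proportional to $\sigma^2_L$ — the multilevel decomposition of the
proportion of between-study variance that is not sampling noise.

## Phylogeny

Trees are read with `ape`; tip labels are matched after underscore/space
normalisation, and synonyms are resolved only through an explicit
user-supplied alias map (silent taxonomic guessing is worse than an
error). Trees without branch lengths get Grafen heights — node height
proportional to descendant-tip count minus one, normalised to unit depth —
the convention `ape::compute.brlen` implements. Local phylogenetic signal
uses the local Moran statistic
$I_i = n(x_i-\bar x)\sum_j w_{ij}(x_j-\bar x)/\sum_k(x_k-\bar x)^2$ with
row-standardised off-diagonal correlations as weights and permutation
p-values (default two-sided, 999 permutations, fixed seed). A species
sharing no path with any other has all-zero weights and a structurally
zero statistic with p = 1; constant traits return zeros with a warning.

## Diagnostics

* **Funnel data**: effect vs standard error, with pseudo-confidence walls
  at the fixed-effect (inverse-variance) mean ± 1.96 se — the fixed-effect
  center is used because the walls describe pure sampling scatter.
* **Time-lag regression**: effect on mean-centred publication year with
  the full random structure; centring keeps the intercept interpretable as
  the pooled estimate at the mean year.
* **Weight sensitivity**: the standard fit against
  $\hat\beta_w = (X^\top WX)^{-1}X^\top Wy$ with $W = \mathrm{diag}(1/v_i)$
  and a sandwich covariance under the fitted $V$ — when heterogeneity
  dominates, marginal weights flatten toward equality, and this contrast
  quantifies how much that choice moves each coefficient.
* **Leave-one-out Cook's distances**:
  $D_i = (\hat\beta-\hat\beta_{-i})^\top \widehat{\mathrm{Cov}}
  (\hat\beta)^{-1}(\hat\beta-\hat\beta_{-i})$ by exactly $n$ refits; the
  flag threshold defaults to $4/n$ (a conventional choice — none is
  prescribed by the analysis this mirrors) and is configurable.

## The synthetic-data generator

`simulate_dataset()` draws datasets with the structure the model assumes,
and `sim_truth()` records every generating parameter. Defaults emulate the
compiled literature the pipeline targets: 158 studies, 163 species with a
mammal-dominated taxon mix (68/60/18/17/1), taxon-dependent log-normal
masses, a log2 dimorphism index $N(0.15, 1)$ clipped to $[-3.35, 2.85]$
(ten-fold female-biased to seven-fold male-biased), diet classes with
taxon-dependent probabilities, gape limitation for fish and half of
carnivorous reptiles, one to three tissues per study-species pair with
both isotopes each (≈282 usable δ¹⁵N mean-difference rows in expectation),
per-sex sample sizes log-normal around 15, and per-sex SDs log-normal
around 0.9 ‰ so the median sampling variance is ≈0.1 ‰². Variance
components default to 0.35/0.35/0.25 ‰² (study/species/phylogeny), which
against $\bar v \approx 0.1$ puts total $I^2$ near 90 % — the
high-heterogeneity regime typical of cross-species isotope compilations. A species is measured by a second independent
study with probability 0.15; this crossing (plus studies covering several
species) is what separates the study from the species component — a 1:1
species-study layout would alias the two levels and reduce the model to
two levels. True per-sex summaries are internally consistent: observed
SDs follow the sampling law of a sample SD
($s\sqrt{\chi^2_{n-1}/(n-1)}$) and observed means carry $s/\sqrt n$ noise,
so computed effect sizes have exactly the advertised sampling variances in
expectation.

What the generator does **not** emulate: correlated N/C responses within a
row (random effects are drawn independently per isotope), tissue-specific
discrimination offsets, non-Gaussian heterogeneity, selective reporting
(no publication-bias mechanism — year trends must be injected explicitly),
and measurement error in body masses. Passing recovery tests therefore
show the estimator is correct *under the stated model*, not that the model
is correct for any real literature.

Determinism: one master seed; stages derive sub-seeds as documented in
`?sim_truth`, so identical seeds give byte-identical datasets, fits and
reports.

## Experiment sizes and expectations

The test suite runs recovery experiments at the analysis' own scale —
about 300 effects over 160 species with all three variance components —
with 200 replicates for coverage/bias and for the null rejection rate, and
100 replicates for AICc interaction recovery; the brute-force grid-search
oracle checks use ≤15-observation instances where a dense scan of the
criterion is exact. These sizes give Monte-Carlo standard errors around
0.015 on a coverage proportion.

One expectation deserves honesty: with the diet-specific dimorphism slopes
the interaction experiment generates (0.17 carnivore, 0.36 omnivore, 0
herbivore — the scale of diet-specific associations in this literature)
and heterogeneity at $I^2 \approx 90\%$, the
2-df interaction signal is weak — the noncentrality works out to roughly 5
where ≈13 would be needed for AICc to prefer the interaction in ≥90 % of
replicates — so the interaction-recovery experiment selects the generating
model only about half the time. The corresponding acceptance test asserts
the stronger bound and fails; the package reports the measured rate rather
than inflating the generating signal to force a pass.

## Known limitations

Wald z (not t) inference; no robust/cluster variance estimation; no
bivariate N+C models; no trim-and-fill, Egger regression or selection
models (the sensitivity battery mirrors the funnel / time-lag /
reweighting / leave-one-out set); no global signal statistics (Pagel's λ,
Blomberg's K); Brownian motion is the only phylogenetic model. Reproducing
the published numbers requires the archived study table and tree as
inputs to `reproduce_study()` — the package ships no copy of them, and its
synthetic stand-ins are labelled as such.
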