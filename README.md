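# sidmeta

Multilevel phylogenetic meta-analysis of sex differences in stable-isotope
ratios.

## The problem

Across vertebrates, males and females of the same species often feed
differently: at different trophic levels (tracked by δ¹⁵N) or on different
basal carbon resources (tracked by δ¹³C). A long-standing comparative
question is whether such ecological sex differences go hand in hand with
sexual size dimorphism — larger-bodied sexes taking larger or
higher-trophic-level prey — and whether the association depends on dietary
class or on gape limitation (predators that swallow prey whole, in which
trophic level tracks body size closely).

`sidmeta` implements the full inferential pipeline for that question from
published per-sex summary statistics: effect-size construction, multilevel
phylogenetic meta-analysis and meta-regression, heterogeneity decomposition,
AICc model selection, and a publication-bias / sensitivity battery. A
synthetic-data generator with a truth ledger makes every stage testable
without any data download.

## The model

Each study × species × tissue × isotope row carries per-sex mean, SD and
sample size. From these the package builds

- **MD** — raw mean difference \(\bar{x}_m - \bar{x}_f\) (‰), with unpooled
  sampling variance \(s_m^2/n_m + s_f^2/n_f\);
- **lnVR** — bias-corrected log variability ratio
  \(\ln(s_m/s_f) + \tfrac{1}{2(n_m-1)} - \tfrac{1}{2(n_f-1)}\), sampling
  variance \(\tfrac{1}{2(n_m-1)} + \tfrac{1}{2(n_f-1)}\); \(|lnVR| > \ln 2\)
  means one sex is more than twice as variable;
- **lnCVR** — the analogous log ratio of coefficients of variation.

Effect sizes \(y_i\) with sampling variances \(v_i\) are modelled as

\[
y \sim N(X\beta,\; V), \qquad
V = \sigma^2_{study} Z_s Z_s^\top + \sigma^2_{species} Z_p Z_p^\top
  + \sigma^2_{phylo} Z_p A Z_p^\top + \mathrm{diag}(v_i),
\]

where \(A\) is the Brownian-motion correlation matrix from a Newick tree
(shared root-to-tip path length over tree depth; Grafen heights when branch
lengths are absent). Variance components are estimated by REML (or ML) with
an analytic gradient; \(\hat\beta\) is the GLS solution with Wald z
inference. Moderators are R formulas, e.g.
`~ dimorphism * diet_class + mean_size`, where `dimorphism` is
\(\log_2(M_m/M_f)\) — one unit = a two-fold (100 %) male-biased mass
dimorphism. Heterogeneity is decomposed as
\(I^2 = 100\sum_L \sigma^2_L / (\sum_L \sigma^2_L + \bar v)\) with the
typical sampling variance
\(\bar v = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)\), and moderator
structures are compared by small-sample AICc (ML likelihoods). Diagnostics
cover funnel data, publication-year meta-regression, within-study-only
weighting, leave-one-out Cook's distances and a local Moran-type per-species
phylogenetic signal with permutation p-values.

## Worked example

```r
library(sidmeta)

sim <- simulate_dataset(sim_truth(seed = 42))     # literature-scale dataset
d   <- prepare_effects(sim$records, metric = "MD", isotope = "N15")
A   <- phylo_correlation(sim$tree, unique(d$species))

fit <- fit_meta(d, ~ dimorphism, A = A)
fit
#> Multilevel meta-analytic model (REML)
#>   k = 259 effect sizes; 2 fixed effect(s); 3 variance component(s)
#>   sigma^2: study = 0.3836, species = 0.3353, phylo = 0.6676
#>   logLik = -324.4   AICc = 659.1
#>
#>          term estimate      se    zval    pval    ci.lb  ci.ub
#> 1 (Intercept)  -0.0740 0.31677 -0.2336 0.81529 -0.69486 0.5469
#> 2  dimorphism   0.1352 0.07784  1.7374 0.08231 -0.01732 0.2878

i_squared(fit_meta(d, ~ 1, A = A))
#> I^2 total: 94.56%  (typical sampling variance 0.07845)
#>   study         28.48%
#>   species       23.16%
#>   phylo         42.92%
```

The slope says a 100 % (two-fold) male-biased mass dimorphism is associated
with a 0.135 ‰ higher male δ¹⁵N on average in this synthetic dataset (the
generating value is 0.126 ‰); the heterogeneity report says essentially all
between-study variation is non-sampling variance, split across the study,
species and phylogenetic levels. `model_selection_table()`,
`reproduce_study()` and `run_pipeline()` wrap the moderator comparison, the
full published-style battery, and the end-to-end file-to-JSON run.

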