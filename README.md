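# circatrend

Unbiased discovery of circadian genes in short free-running expression time
courses, for chronobiologists and plant genomicists who would rather let the
data define its rhythms than fit a preconceived waveform.

## What it does

Given a genes × timepoints matrix (typically 12 samples at 4 h intervals under
constant conditions), circatrend:

1. **Extracts eigentrends** — dominant latent time profiles — by averaging many
   FastICA restarts of the model *X = AS* (genes × timepoints = loadings ×
   profiles), ranking components by the kurtosis of their gene-loading
   distributions.
2. **Decides how many components are real** with an empirical randomization
   test: the reconstruction error of a *d*-component model is compared with the
   errors of within-gene-shuffled matrices; the p-value is the frequency with
   which randomized errors are smaller.
3. **Calls circadian genes by projection**: every unit-normalized gene profile
   is projected onto the two circadian eigentrends (*q₁ = n·v₁*, *q₂ = n·v₂*);
   genes with radius √(q₁² + q₂²) ≥ 0.8 are circadian, their projection angle
   is their phase, and the signed axis with the largest dot product assigns one
   of four phase modules (dawn, dusk, mid-day, midnight).
4. **Scores cross-study conservation** with the integrative correlation
   coefficient (correlation of a gene's correlation profiles across two
   studies, over a shared ortholog set) and Jaccard module-preservation
   z-scores against randomized module nulls.
5. **Links promoter elements to phase**: 5–8-mer over-representation screening
   (hypergeometric, top 21 features), one-vs-rest random forests (2000 trees,
   mtry 4), held-out permutation variable importance, ROC/AUC, progressive
   presence/absence element tables, and mean-phase vectors of element
   combinations.

Synthetic-data generators with full ground truth (`simulate_expression()`,
`simulate_promoters()`, `simulate_study_pair()`) accompany every stage, so the
whole pipeline is exercisable and testable end to end without any downloads.

## Worked example

```r
library(circatrend)

sim <- simulate_expression(simulation_spec(seed = 1))   # 2000 genes, 200 cyclers
x   <- preprocess(sim$expr)

dec  <- run_ica(x, n_components = 2, n_runs = 100, seed = 102)
pick <- select_circadian_components(dec)
ax   <- orient_axes(dec, pick)

proj <- project_genes(x, ax$v1, ax$v2) |>
  classify_circadian(cutoff = 0.8) |>
  assign_modules()
#> 217 of 2000 genes called circadian at radius >= 0.8

dplyr::count(tibble::as_tibble(proj), module_label)
#> # A tibble: 5 × 2
#>   module_label     n
#>   <fct>        <int>
#> 1 dawn            65
#> 2 dusk            89
#> 3 noon            29
#> 4 midnight        34
#> 5 <NA>          1783

autoplot(proj)   # projection scatter with the 0.8 cutoff circle
```

The 217 called genes recover the planted cyclers completely (recall 1.00 for
cyclers with signal-to-noise ≥ 2 at these settings, false-positive rate
0.0094), and the module labels match the planted phase classes for 96.5% of
them. Significance of the component count on a three-trend study (two
circadian trends plus a damped one, 400 genes):

```r
x3 <- preprocess(simulate_expression(
  simulation_spec(n_genes = 400, n_circadian = 80, damping_fraction = 0.3,
                  class_weights = c(1, 1, 1, 1) / 4, phase_jitter_sd = 0,
                  amp_range = c(1, 2), seed = 8))$expr)
empirical_component_test(x3, d = 3, n_randomizations = 200, seed = 12)$p_value
#> [1] 0        # three components: significant
empirical_component_test(x3, d = 5, n_randomizations = 200, seed = 13)$p_value
#> [1] 1        # no support for five
```

Tabular views come from the usual verbs: `tidy(dec)` (long component
profiles), `glance(model)` (per-class AUC of a `phase_forest`),
`autoplot(ct)`, `autoplot(model)`. A configurable stage runner
(`pipeline_config()`, `run_stage()`, `run_pipeline()`) writes every stage's
artifacts plus a JSON run manifest to an output directory.

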