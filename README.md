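# sgemix

Variance-component analysis of **social (indirect) genetic effects** in
group-housed populations.

When animals are housed in groups, a phenotype can depend on the genotypes
of the focal animal's cage mates — social genetic effects (SGE) — in
addition to its own genotype (direct genetic effects, DGE). SGE act through
unmeasured mediating phenotypes of the partners, and when cage mates are
relatives the two effect classes are correlated: ignoring SGE then biases
heritability estimates up (cooperative-like covariance) or down
(competition-like covariance).

`sgemix` provides, in one tidyverse-style package:

* **Relationship matrices**: Wright's pedigree numerator matrix `A`
  (tabular method), the genomic matrix `G = MM'/2Σpq` from allele-frequency
  centred dosages, the blended `G* = 0.95(a + bG) + 0.05 A_gg`, and the
  single-step `H` combining pedigree and genomic information
  (`H⁻¹ = A⁻¹ + blockdiag(0, G*⁻¹ − A_gg⁻¹)`).
* **The SGE mixed model** for outbred designs: REML with correlated direct
  and social genetic components,

  cov(y) = σ²_AD·H₁ + σ_ADS·(H₂Zᵀ + ZH₂ᵀ) + σ²_AS·ZH₃Zᵀ
         + σ²_ED·I₁ + σ_EDS·(I₂Zᵀ + ZI₂ᵀ) + σ²_ES·ZI₃Zᵀ + σ²_C·WI₄Wᵀ,

  where every design matrix is scaled to unit sample variance
  (`sampleVar(M) = Tr(PMP)/(n−1)`) so each parameter is directly a share of
  phenotypic variance. Fisher (expected-information) standard errors,
  variance partitioning, a conservative 2-df restricted likelihood-ratio
  test for SGE, and Storey q-values across traits.
* **The paired two-inbred-strain design** (B6/D2): covariate-aware Box-Cox
  normalization, fixed-effect DGE/SGE/interaction models with
  compound-symmetry residuals (via `nlme::gls`), AIC model selection,
  per-strain SGE tests, and fixed-effect variance partitioning.
* **Simulation machinery**: pedigree gene dropping, relatedness-biased cage
  assignment, phenotype generation from the full model, and a
  heritability-bias study comparing DGE-only, DGE+cage and full-model fits.

## Worked example

Simulate a reference colony (full-sib families bred for three generations,
cages of three with sibling co-housing, 80% genotyped, single-step H), draw
one phenotype under the strong-SGE scenario, and fit the full model:

```r
library(sgemix)

study  <- simulate_sge_study(n_families = 80, seed = 7)
design <- study$design
y <- simulate_phenotype(sge_scenario("high-sge"), design, n_reps = 1, seed = 8)[, 1]

fit <- fit_sge(y, design = design, model = "full")
#> constant cage size: environmental terms collapsed to an exchangeable
#> residual (s2_E, cov_E)
tidy(fit)
#> # A tibble: 5 × 5
#>   term  estimate std.error proportion_pct se_pct
#>   <chr>    <dbl>     <dbl>          <dbl>  <dbl>
#> 1 s2_AD  0.00919    0.0830          0.888  8.02
#> 2 s_ADS  0.0205     0.117           0.858  4.90
#> 3 s2_AS  0.188      0.195          18.2   18.8
#> 4 s2_E   0.835      0.323          80.7   31.2
#> 5 cov_E  0.809      0.323          -0.655  0.261
glance(fit)
#> # A tibble: 1 × 6
#>   model     n logLik rho_ads converged collapsed_env
#>   <chr> <int>  <dbl>   <dbl> <lgl>     <lgl>
#> 1 full    240  -171.   0.492 TRUE      TRUE

lrt_sge(y, design = design)
#> # A tibble: 1 × 3
#>   statistic    df p_value
#>       <dbl> <dbl>   <dbl>
#> 1      5.66     2  0.0591
```

Reading the output: the fitted social genetic component explains ~18% of
phenotypic variance on this draw (generating value 27%, n = 240 — single
replicates scatter widely), the estimated direct-social genetic correlation
is 0.49, and the restricted LRT gives p = 0.059 against the null with both
the SGE variance and the DGE-SGE covariance removed. Because every cage
here has three mice, the fitter has collapsed the four environmental
parameters — which are not separately identifiable at constant group size —
to an exchangeable residual, and says so.

Multi-trait scans (`sge_scan()`, or `run_scan()` from TSV/YAML files),
the misspecification study (`run_bias_study()`, plotted with `autoplot()`),
and the inbred-design analysis (`inbred_scan()`, `fit_paired_model()`,
`aic_select()`, `sge_test_per_strain()`, `fixed_effect_variance()`) follow
the same data-frame-in, tibble-out pattern. The methods vignette
(`vignettes/social-genetic-effects.Rmd`) documents the model, the
sample-variance scaling, the identifiability guard and all numerical
choices.

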