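Package: sgemix
Title: Social Genetic Effects in Group-Housed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of social (indirect) genetic effects
    (SGE) in group-housed laboratory populations. Builds pedigree (Wright
    numerator), genomic (VanRaden), blended and single-step (H) relationship
    matrices; fits a linear mixed model with correlated direct and social
    genetic effects, direct and social environmental effects and cage effects
    by restricted maximum likelihood; partitions phenotypic variance on the
    sample-variance scale; tests SGE with a conservative 2-df restricted
    likelihood-ratio test and Storey q-values.  Also implements the paired
    two-inbred-strain design (fixed-effect DGE/SGE/interaction models with
    compound-symmetry residuals, AIC model selection, covariate-aware Box-Cox
    normalisation) and simulation machinery: pedigree gene dropping,
    relatedness-biased cage assignment and phenotype generation from the full
    model, including the heritability-bias study under misspecified models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
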