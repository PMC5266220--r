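---
title: "Modelling social genetic effects in group-housed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social genetic effects in group-housed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In group-housed animals, an individual's phenotype can depend not only on its
own genotype (direct genetic effects, DGE) but also on the genotypes of its
social partners — its cage mates (social or indirect genetic effects, SGE).
SGE act through unmeasured mediating phenotypes of the partners; no
measurement of those mediators is needed, because their genetic and
environmental components are captured jointly by the model.  Ignoring SGE is
not harmless: when cage mates are relatives, an animal's own genotype is
correlated with its social environment, and heritability estimates absorb
part of the social signal.

`sgemix` implements this model class end to end for two designs:

* an **outbred design**: genetically unique, pedigreed individuals housed in
  groups, analysed with a variance-component mixed model in which direct and
  social genetic effects are random, correlated effects;
* a **paired two-inbred-strain design** (B6/D2): the strain of the cage mate
  is a fixed covariate, and DGE, SGE and their interaction are tested by
  model comparison with a compound-symmetry residual.

# The outbred mixed model

For focal individual $f$ with covariate row $x_f$,

$$y_f = x_f b + a_{D,f} + e_{D,f} + Z_f a_S + Z_f e_S + W_f c,$$

where $Z$ indicates cage mates ($Z_{ii} = 0$), $W$ indicates cage
assignment, $a_D, a_S$ are direct and social additive genetic effects,
$e_D, e_S$ direct and social environmental effects, and $c$ cage effects.
The random effects are jointly Gaussian with

$$\begin{pmatrix} a_D \\ a_S \end{pmatrix} \sim N\!\left(0,
\begin{pmatrix} \sigma^2_{AD} H_1 & \sigma_{ADS} H_2 \\
\sigma_{ADS} H_2^{T} & \sigma^2_{AS} H_3 \end{pmatrix}\right),$$

the environmental pair analogous with identity kernels, and
$c \sim N(0, \sigma^2_C I_4)$.  The phenotypic covariance is

$$\mathrm{cov}(y_i, y_j) = \sigma^2_{AD} H_{1,ij}
 + \sigma_{ADS}\{(H_2 Z^T)_{ij} + (Z H_2^T)_{ij}\}
 + \sigma^2_{AS} (Z H_3 Z^T)_{ij}
 + \sigma^2_{ED} I_{1,ij} + \sigma_{EDS}\{(I_2 Z^T)_{ij} + (Z I_2^T)_{ij}\}
 + \sigma^2_{ES} (Z I_3 Z^T)_{ij} + \sigma^2_C (W I_4 W^T)_{ij}.$$

## The sample-variance scaling

Every design matrix is divided by its *sample variance*
$\mathrm{sampleVar}(M) = \mathrm{Tr}(PMP)/(n-1)$, $P = I - 11'/n$:
$H_1 = H/\mathrm{sampleVar}(H)$, $H_3 = H/\mathrm{sampleVar}(ZHZ^T)$, and the
identity analogues likewise ($I_4$ uses $WIW^T$).  After this scaling each
variance parameter equals that component's contribution to the sample
variance of the phenotypic covariance, so the parameters are directly
comparable "shares of variance".

For the cross matrix $H_2$ we use the **geometric mean** of the two
scalings, $H_2 = H/\sqrt{\mathrm{sampleVar}(H)\,\mathrm{sampleVar}(ZHZ^T)}$.
Two reasons.  First, only with this convention is the joint genetic
covariance a Kronecker product $K \otimes H$ with
$K$ the $2\times 2$ matrix of scaled variances, which guarantees positive
semidefiniteness whenever $|\rho_{ADS}| \le 1$ and makes
$\rho_{ADS} = \sigma_{ADS}/(\sigma_{AD}\sigma_{AS})$ a true correlation
bounded by $\pm 1$.  Second, without the square root the implied
"correlation" could exceed 1 and the joint distribution of
$(a_D, a_S)$ would not exist for legitimate parameter values.

## Relationship matrices

* `pedigree_A()` builds Wright's numerator relationship matrix by the
  tabular method (founders unrelated and non-inbred; unknown parents
  allowed).
* `genomic_G()` builds $G = MM^T / 2\sum_i p_i q_i$ from dosages centred by
  observed allele frequencies; monomorphic loci are dropped and missing
  dosages mean-imputed (zero after centring, unbiased in expectation).
* `blend_G()` forms $G^{*} = 0.95(a + b\,G) + 0.05 A_{gg}$.  The default
  constants are $a = 0.015$, $b = 0.982$; the `"match"` mode instead solves
  the $2 \times 2$ linear system equating the mean diagonal and mean
  off-diagonal of $a + bG$ with those of $A_{gg}$, which is the right choice
  for synthetic populations whose drift statistics differ from any fixed
  constants.
* `build_H()` combines both sources single-step style:
  $H^{-1} = A^{-1} + \mathrm{blockdiag}(0,\, G^{*-1} - A_{gg}^{-1})$ on the
  (non-genotyped, genotyped) partition.  The **minus** sign on
  $A_{gg}^{-1}$ is essential: it is the only form for which $H = A$ when
  nobody is genotyped and $H = G^{*}$ when everybody is — both identities
  are asserted in the test suite.  Inversions are Cholesky-based with an
  escalating diagonal jitter ($10^{-10} \to 10^{-6}$), each jitter signalled
  as a logged condition.

## REML estimation

`fit_sge()` maximizes the restricted likelihood with analytic gradients
under an L-BFGS-B quasi-Newton scheme.  The two $2\times 2$ covariance
blocks are parameterized by their Cholesky factors (positive
semidefiniteness and $|\rho| \le 1$ by construction); strictly positive
scalar variances by their logarithms.  Three starting points are used —
null-like (residual-dominated), DGE-heavy, and an equal split — and the best
optimum is kept; convergence requires a relative likelihood change below
$10^{-8}$ and gradient norm below $10^{-6}$.  Standard errors come from the
*expected* (Fisher) information of the restricted likelihood,
$\mathcal{I}_{k\ell} = \tfrac12 \mathrm{Tr}(P C_k P C_\ell)$ with
$C_k = \partial V / \partial \sigma_k$, evaluated at the optimum.

**Identifiability guard.**  When every cage has the same size, the four
environmental parameters $(\sigma^2_{ED}, \sigma_{EDS}, \sigma^2_{ES},
\sigma^2_C)$ enter the covariance only through two functionals (its diagonal
and its within-cage off-diagonal), so they are not separately identifiable.
The fitter detects constant cage size and collapses them to an exchangeable
residual — variance $\sigma^2_E$ and within-cage covariance
$\mathrm{cov}_E = \rho_E \sigma^2_E$ with $-1/(k_{max}-1) < \rho_E < 1$ —
with a logged notice.  Genetic parameters are unaffected.

**Variance partitioning.**  A component's contribution is its estimate times
the sample variance of its design matrix (unity for the scaled genetic
matrices); the denominator is the sample variance of the full fitted
covariance.  Proportions are reported as percentages; their standard errors
propagate the component SE through the ratio with the denominator treated
as fixed (first order).

**Significance.**  SGE is tested with a restricted likelihood-ratio test
removing both $\sigma^2_{AS}$ and $\sigma_{ADS}$ (environmental terms are
retained in the null: $\sigma_{EDS}$ is an environmental, not genetic,
parameter).  The statistic is referred to $\chi^2_2$, which is conservative
because $\sigma^2_{AS}$ sits on its boundary under the null — the test suite
verifies the conservativeness empirically.  The full fit is seeded from the
null optimum, which makes the statistic non-negative up to optimizer
tolerance.  Across traits, p-values are adjusted with Storey q-values
(`qvalues()`): $\hat\pi_0$ from the $\lambda$-grid with a df-3 smoothing
spline, falling back to the conservative $\pi_0 = 1$ for short vectors,
where the procedure reduces exactly to Benjamini-Hochberg.

## Missing phenotypes

Rows with missing phenotypes are dropped from the analysis, but their
animals keep acting socially: all component matrices are assembled on the
full housed population and then subset to the phenotyped rows, so a cage
mate without a phenotype still contributes through $Z$.

# The paired inbred design

With exactly two mice per cage and strains coded 0 (B6) / 1 (D2), the model
is $y_f = \beta_D X_f + \beta_S X_{cm} + \beta_{D:S} X_f X_{cm} + e_f$ with
$\mathrm{cov}(e_i, e_j) = \sigma^2_E$ if $i = j$ and $\rho\sigma^2_E$ for
cage mates.  With group size 2 the direct/social/cage environmental pieces
are not identifiable ($\sigma^2_E = \sigma^2_{ED} + \sigma^2_{ES} +
\sigma^2_C$, $\rho = (2\sigma_{EDS} + \sigma^2_C)/\sigma^2_E$), and $\rho$
may legitimately be negative, so the residual cannot be rewritten as cage
effects plus iid noise.  Fits go through `nlme::gls()` with a
`corCompSymm` structure (the iid mode reduces exactly to OLS); the test
suite checks the ML likelihood against a direct multivariate-normal density
evaluation, and the equivalence with a cage random intercept when
$\hat\rho > 0$.

Conventions, mirroring the analysis split this design calls for:

* **AIC model selection** uses ML fits (REML likelihoods are not comparable
  across fixed-effect structures) over all marginality-respecting term
  combinations crossed with iid/compound-symmetry residuals.
* **Per-strain SGE tests** are ML likelihood-ratio tests of
  $\beta_S = 0$ on one focal strain at a time ($\chi^2_1$), with q-values
  across traits and strains; REML is exposed as an option.
* **Variance partitioning** uses REML: the SGE share is
  $\mathrm{var}(\hat\beta_S X_{cm})$ over the average sample variance of
  10,000 Monte-Carlo draws from the fitted model, with first-order
  (Gaussian) propagation of the coefficient uncertainty.
* **Box-Cox normalization** (`boxcox_transform()`) maximizes the profile
  likelihood of $y^{(\lambda)} \sim X$ over a $[-2, 2]$ grid refined by
  golden-section search, with strain, cage-mate strain and their interaction
  informing $\lambda$ — the covariates are *not* regressed out of the
  returned values, so genetic signal is preserved.  Covariate adjustment,
  when requested, regresses out covariates individually associated at
  $p < 0.05$ (a screening threshold we fixed ourselves, logged at run time);
  an include-as-fixed-effects mode is available.

# The synthetic study

Because the organismal data sets this model class targets are external,
every analysis stage is exercised on synthetic data whose structure mirrors
a real group-housed colony:

* **Population** (`simulate_population()`): 200 families per generation,
  three offspring per family, three generations by random re-mating, 2,000
  biallelic loci gene-dropped from Hardy-Weinberg founders with frequencies
  uniform on (0.1, 0.9).  The last generation (600 mice in 200 full-sib
  families) is the study cohort.  Three generations matter: they produce
  relatedness at many levels (full sibs, half relatives, cousins, remoter
  kin), as in a closed breeding colony, rather than the binary
  full-sib/unrelated structure of a single generation — and graded
  relatedness is what lets the model separate social genetic effects from
  shared-cage effects.
* **Housing** (`assign_cages()`): cages of three, filled with a
  sibling-cohousing weight of 0.5 (each slot is a random sibling of the
  cage's seed animal with probability one half, otherwise a random
  unassigned mouse).  This yields mean within-cage relatedness an order of
  magnitude above the population average while keeping mixed cages, which
  preserves the contrast needed to identify SGE separately from cage
  effects.
* **Relatedness**: 80% of study mice are "genotyped" (matching the roughly
  four-fifths genotyped fraction typical of such colonies); the analysis
  walks the full single-step path A → G → G* (mean-matching blend) → H.
* **Phenotypes** (`simulate_phenotype()`): drawn from the full model above;
  thanks to the Kronecker structure a replicate costs one $n \times 2$
  Gaussian draw per effect pair.  Scenario presets (`sge_scenario()`) put,
  on the percent scale, `average` = (DGE 15, SGE 4, $\rho_{ADS}$ 0.5,
  DEE 52, SEE 0, $\rho_{EDS}$ 0, cage 22) and `high-sge` = (5, 27, 0.92, 5,
  0, 0, 51).

What the generator does **not** emulate: linkage disequilibrium and
recombination maps (loci are independent), founder haplotype mosaics,
selection, and non-random mating beyond family structure.  Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions, not robustness to real-genome LD structure.

## Problem sizes and what to expect at them

The package's reference reproduction runs 100 replicates per scenario on the
600-mouse cohort (the tests and `scripts/acceptance.R` both do).  At this
size the direct genetic variance and the strong social component of the
`high-sge` scenario are recovered without systematic bias, and the
misspecification study shows the expected pattern under a positive DGE-SGE
covariance: DGE-only fits are strongly inflated, adding a cage effect
removes most of that inflation (at constant cage size it overcorrects
slightly, because the free cage term also absorbs within-cage genetic
covariance), and the full model is unbiased — the bias magnitudes are
strictly ordered DGE-only > DGE+cage > full.  With a negative covariance
the DGE-only bias reverses sign (competition masks heritability).

One caveat we document rather than hide: in the `average` scenario the
social variance is small (4%) and constrained non-negative, so at $n = 600$
its sampling distribution piles up at zero and the *mean* estimate across
replicates sits above the generating value (the median sits near it).  This
boundary effect shrinks with sample size — it is a property of
variance-component estimation near a boundary, not of this implementation;
the corresponding recovery assertion is intentionally strict and records the
effect.  The null-calibration study (500 replicates) runs at $n = 150$, and
the restricted LRT is conservative there as the boundary argument predicts.

# Numerical choices

* Diagonal nugget $10^{-8}$ on every assembled covariance before
  factorization; jitter for inversions escalates $10^{-10} \to 10^{-6}$,
  always logged.
* Cage-mate indicator entries are unweighted 0/1 — no $1/(k-1)$ dilution —
  so a mouse with more cage mates receives more social input; group-size
  heterogeneity is absorbed by the sample-variance scaling.
* The $(a, b)$ blend constants for synthetic populations use the
  mean-matching mode; the fixed printed constants remain the defaults of
  `blend_G()` for data whose drift statistics they were derived from.
* Proportion-to-parameter mapping in the generator is the identity: because
  of the sample-variance scaling, requesting a 22% cage share means
  $\sigma^2_C = 0.22$.
* Near-zero social components (below $10^{-3}$ on the sample-variance
  scale) are excluded when averaging the estimated genetic correlation,
  which is undefined at $\sigma^2_{AS} = 0$; exclusions are logged.

# Known limitations

* Dense linear algebra throughout: fine to a few thousand individuals, not
  at livestock scale (no sparse inverse-H machinery).
* Single-trait REML only; no per-locus association mapping of social
  effects.
* The expected-information SEs are asymptotic; near boundaries the Fisher
  information can be singular, in which case SEs are reported as missing
  with a warning rather than fabricated.
* The covariate screening threshold (0.05) and the Monte-Carlo draw count
  (10,000) in the inbred partitioning are package choices where the
  procedure itself fixes none.
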