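test_that("Box-Cox profile likelihood recovers the generative transform", {
  set.seed(3)
  n <- 2000
  X <- cbind(1, rbinom(n, 1, 0.5))
  ## y already Gaussian given X: lambda near 1 (spread wide enough for the
  ## power family to be identified)
  y1 <- 10 + as.numeric(X %*% c(0, 2)) + 3 * rnorm(n)
  y1 <- pmax(y1, 0.5)
  t1 <- boxcox_transform(y1, X)
  expect_lt(abs(attr(t1, "lambda") - 1), 0.25)
  ## y log-normal given X: lambda near 0
  y2 <- exp(1 + 0.5 * as.numeric(X %*% c(0, 1)) + 0.6 * rnorm(n))
  t2 <- boxcox_transform(y2, X)
  expect_lt(abs(attr(t2, "lambda")), 0.1)
  ## optimum equals an exhaustive fine-grid maximum within grid resolution
  fine <- seq(-2, 2, by = 0.001)
  pll <- vapply(fine, function(l) {
    z <- if (abs(l) < 1e-8) log(y2) else (y2^l - 1) / l
    -n / 2 * log(sum(lm.fit(X, z)$residuals^2) / n) + (l - 1) * sum(log(y2))
  }, 0)
  expect_lt(abs(attr(t2, "lambda") - fine[which.max(pll)]), 2e-3)
  ## agrees with the MASS implementation in the covariate-free case
  bc <- MASS::boxcox(y2 ~ 1, lambda = fine, plotit = FALSE)
  expect_lt(abs(attr(boxcox_transform(y2), "lambda") - bc$x[which.max(bc$y)]), 5e-3)
  ## non-positive values are shifted with a logged offset
  expect_message(boxcox_transform(c(-1, y1)), class = "sgemix_boxcox_shift")
})

test_that("GLS with rho fixed at zero equals ordinary least squares exactly", {
  obs <- simulate_inbred_experiment(beta_D = 0.5, beta_S = 1, rho = 0.4,
                                    sigma2_E = 1, seed = 5)
  fit <- fit_paired_model(obs, terms = c("DGE", "SGE"), residual = "iid",
                          method = "ML")
  ols <- lm(y ~ strain + cagemate_strain, data = obs)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$rho, 0)
})

test_that("the compound-symmetry ML likelihood matches the MVN density oracle", {
  obs <- simulate_inbred_experiment(beta_S = 1, rho = -0.3, sigma2_E = 1,
                                    n_bb = 3, n_bd = 3, n_dd = 2, seed = 7)
  fit <- fit_paired_model(obs, terms = "SGE", residual = "cs", method = "ML")
  ll <- oracle_paired_ll(obs, fit$coefficients, fit$sigma2_E, fit$rho, terms = "SGE")
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("paired-model parameters are recovered across replicates", {
  res <- t(sapply(1:200, function(r) {
    obs <- simulate_inbred_experiment(beta_S = 1, rho = -0.3, sigma2_E = 1,
                                      n_bb = 14, n_bd = 16, n_dd = 13, seed = 100 + r)
    fit <- fit_paired_model(obs, terms = "SGE", residual = "cs", method = "REML")
    c(beta = unname(fit$coefficients["cagemate_strain"]), rho = fit$rho)
  }))
  expect_equal(mean(res[, "beta"]), 1, tolerance = 3 * sd(res[, "beta"]) / sqrt(200) + 1e-9)
  expect_equal(mean(res[, "rho"]), -0.3, tolerance = 0.08)
  ## rho respects its bounds on every fit, including anti-correlated pairs
  expect_true(all(res[, "rho"] >= -1 & res[, "rho"] <= 1))
})

test_that("rho stays bounded on adversarial anti-correlated pairs", {
  obs <- simulate_inbred_experiment(rho = 0, sigma2_E = 1, seed = 11)
  ## force near-perfect anti-correlation within every cage
  for (cg in unique(obs$cage)) {
    ix <- which(obs$cage == cg)
    obs$y[ix[2]] <- -obs$y[ix[1]] + 1e-3 * rnorm(1)
  }
  fit <- fit_paired_model(obs, terms = "SGE", residual = "cs", method = "ML")
  expect_gte(fit$rho, -1)
  expect_lte(fit$rho, 1)
  expect_lt(fit$rho, -0.8)
})

test_that("with rho in [0,1] compound symmetry equals a cage random intercept", {
  obs <- simulate_inbred_experiment(beta_S = 0.5, rho = 0.5, sigma2_E = 1,
                                    n_bb = 10, n_bd = 12, n_dd = 10, seed = 19)
  fit <- fit_paired_model(obs, terms = "SGE", residual = "cs", method = "ML")
  expect_gt(fit$rho, 0) # precondition for the equivalence
  lmm <- nlme::lme(y ~ cagemate_strain, random = ~ 1 | cage,
                   data = as.data.frame(obs), method = "ML")
  expect_equal(fit$logLik, as.numeric(logLik(lmm)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(nlme::fixef(lmm)), tolerance = 1e-6)
})

test_that("AIC selection favours the generating model class", {
  ## strong interaction: the DGE+SGE+DGExSGE model should win almost always
  hits <- sum(sapply(1:20, function(r) {
    obs <- simulate_inbred_experiment(beta_D = 1, beta_S = 1, beta_DS = 2,
                                      rho = 0.2, sigma2_E = 0.5,
                                      n_bb = 20, n_bd = 20, n_dd = 20,
                                      seed = 300 + r)
    sel <- suppressWarnings(aic_select(obs))
    grepl("DGExSGE", sel$model[sel$best])
  }))
  expect_gte(hits, 18)
  ## pure noise: the smallest (null) model wins most often
  wins <- sapply(1:20, function(r) {
    obs <- simulate_inbred_experiment(rho = 0, sigma2_E = 1,
                                      n_bb = 15, n_bd = 15, n_dd = 15,
                                      seed = 500 + r)
    sel <- suppressWarnings(aic_select(obs))
    sel$terms[sel$best]
  })
  expect_equal(names(sort(table(wins), decreasing = TRUE))[1], "")
})

test_that("the per-strain SGE test is calibrated and detects planted signal", {
  ## type-I error under beta_S = 0
  pvals <- sapply(1:400, function(r) {
    obs <- simulate_inbred_experiment(beta_S = 0, rho = 0.3, sigma2_E = 1,
                                      seed = 1000 + r)
    sge_test_per_strain(obs, focal = 0)$p_value
  })
  rej <- mean(pvals < 0.05)
  expect_lt(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 400) + 0.02)
  ## permuting cage-mate labels destroys a planted signal
  obs <- simulate_inbred_experiment(beta_S = 2, rho = 0, sigma2_E = 1, seed = 77)
  p_signal <- sge_test_per_strain(obs, focal = 0)$p_value
  expect_lt(p_signal, 0.01)
  obs_perm <- obs
  obs_perm$cagemate_strain <- withr::with_seed(8, sample(obs$cagemate_strain))
  p_perm <- sge_test_per_strain(obs_perm, focal = 0)$p_value
  expect_gt(p_perm, 0.01)
  ## interaction-only signal separates by focal strain
  obs_int <- simulate_inbred_experiment(beta_S = 0, beta_D = 0, beta_DS = 1.5,
                                        rho = 0, sigma2_E = 0.5,
                                        n_bb = 20, n_bd = 20, n_dd = 20, seed = 91)
  p_b6 <- sge_test_per_strain(obs_int, focal = 0)$p_value
  p_d2 <- sge_test_per_strain(obs_int, focal = 1)$p_value
  expect_lt(p_d2, 0.001)
  expect_gt(p_b6, 0.01)
})

test_that("fixed-effect variance matches the closed form and is swap-invariant", {
  ## balanced X_cm in {0,1}, beta_S = 1, sigma2_E = 1, rho = 0:
  ## var(term) ~ 0.25, total ~ 1.25, proportion ~ 20%
  n <- 300
  obs <- tibble::tibble(
    id = sprintf("b%03d", 1:n),
    cage = sprintf("c%03d", 1:n), # one focal per cage: residuals iid
    strain = 0,
    cagemate_strain = rep(c(0, 1), each = n / 2),
    y = rep(c(0, 1), each = n / 2) + withr::with_seed(33, rnorm(n))
  )
  fit <- fit_paired_model(obs, terms = "SGE", residual = "iid", method = "REML")
  fake <- fit
  fake$coefficients[] <- c(0, 1) # (Intercept), cagemate_strain
  fake$sigma2_E <- 1
  fake$rho <- 0
  fev <- fixed_effect_variance(fake, n_draws = 20000, seed = 2)
  expect_equal(fev$proportion_pct[fev$term == "SGE"], 20, tolerance = 0.35)

  ## strain-code swap leaves main-effect variance proportions unchanged
  obs2 <- simulate_inbred_experiment(beta_D = 0.5, beta_S = 1, rho = 0.2,
                                     sigma2_E = 1, seed = 44)
  fitA <- fit_paired_model(obs2, terms = c("DGE", "SGE"), residual = "cs",
                           method = "REML")
  obs_sw <- obs2
  obs_sw$strain <- 1 - obs_sw$strain
  obs_sw$cagemate_strain <- 1 - obs_sw$cagemate_strain
  fitB <- fit_paired_model(obs_sw, terms = c("DGE", "SGE"), residual = "cs",
                           method = "REML")
  fA <- fixed_effect_variance(fitA, n_draws = 4000, seed = 5)
  fB <- fixed_effect_variance(fitB, n_draws = 4000, seed = 5)
  expect_equal(fA$proportion_pct, fB$proportion_pct, tolerance = 0.02)
  ## beta_S = 0 gives proportion exactly 0
  zero <- fit
  zero$coefficients["cagemate_strain"] <- 0
  f0 <- fixed_effect_variance(zero, n_draws = 500, seed = 1)
  expect_equal(f0$proportion_pct[f0$term == "SGE"], 0)
})

test_that("terms without design variation are rejected by name", {
  obs <- simulate_inbred_experiment(seed = 2)
  obs_bb <- obs[obs$cagemate_strain == 0 & obs$strain == 0, ]
  expect_error(fit_paired_model(obs_bb, terms = "SGE"), "SGE")
  expect_error(fit_paired_model(obs, terms = c("DGE", "DGExSGE")), "marginality")
})

test_that("inbred_scan produces calibrated per-trait, per-strain results", {
  set.seed(60)
  rows <- lapply(1:3, function(tr) {
    obs <- simulate_inbred_experiment(
      beta_S = if (tr == 1) 1.5 else 0, rho = 0.2, sigma2_E = 1,
      n_bb = 14, n_bd = 16, n_dd = 13, seed = 700 + tr
    )
    obs$value <- exp(obs$y / 2) # on a skewed raw scale
    obs$trait <- paste0("t", tr)
    obs
  })
  dat <- dplyr::bind_rows(rows)
  res <- suppressMessages(inbred_scan(dat))
  expect_equal(nrow(res), 6) # 3 traits x 2 focal strains
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
  expect_lt(min(res$p_value[res$trait == "t1"]), 0.05)
})
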