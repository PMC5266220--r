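test_that("null-structured data recover a pure direct-environment model", {
  ## relatedness-structured design so genetic and environmental diagonals
  ## are distinguishable; iid phenotypes should land on the residual
  st <- tiny_study(n_families = 30, seed = 37)
  d <- st$design
  set.seed(4)
  y <- rnorm(length(d$ids))
  fit <- suppressMessages(fit_sge(y, design = d, model = "full"))
  expect_true(fit$converged)
  expect_equal(unname(fit$sigma["s2_E"]), 1, tolerance = 0.35)
  expect_lt(unname(fit$sigma["s2_AD"]), 0.2)
  expect_lt(unname(fit$sigma["s2_AS"]), 0.2)
  expect_lt(abs(fit$sigma["cov_E"]), 0.2)
})

test_that("the analytic gradient matches finite differences of the objective", {
  st <- tiny_study(n_families = 8, seed = 31)
  d <- st$design
  y <- simulate_phenotype(sge_scenario("average"), d, n_reps = 1, seed = 5)[, 1]
  X <- matrix(1, length(y), 1)
  spec <- sgemix:::model_spec("full", TRUE, d$kmax)
  Cm <- d$components[spec$keys]
  obj <- sgemix:::make_reml_objective(spec, Cm, y, X, 1e-8)
  theta <- sgemix:::theta_of_sigma(
    spec, c(s2_AD = 0.2, s_ADS = 0.05, s2_AS = 0.1, s2_E = 0.5, cov_E = 0.08)
  )
  g <- obj$gr(theta)
  h <- 1e-6
  g_fd <- vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, 0)
  expect_equal(g, g_fd, tolerance = 1e-4)
})

test_that("the optimum matches an independent contrast-likelihood maximization", {
  ## n = 40 toy: generic Nelder-Mead on the orthonormal-error-contrast
  ## density (never touching the package objective) finds the same restricted
  ## log-likelihood to < 1e-4
  d <- unrelated_pairs_design(40)
  y <- simulate_phenotype(c(s2_ED = 0.7, s2_C = 0.3), d, n_reps = 1, seed = 9)[, 1]
  X <- matrix(1, 40, 1)
  fit <- suppressMessages(fit_sge(y, design = d, model = "full"))

  oracle_obj <- function(par) {
    # par: log s2_AD, log s2_AS, atanh-free s_ADS, log s2_E, rho_e raw
    s2_AD <- exp(par[1]); s2_AS <- exp(par[2])
    s_ADS <- tanh(par[3]) * sqrt(s2_AD * s2_AS)
    s2_E <- exp(par[4])
    rho <- -1 + 2 * plogis(par[5])
    vc <- c(s2_AD = s2_AD, s_ADS = s_ADS, s2_AS = s2_AS)
    V <- build_covariance(vc, d, check = FALSE) +
      s2_E * (diag(40) + rho * d$cages$Z) + diag(1e-8, 40)
    -oracle_restricted_ll(y, X, V)
  }
  o <- optim(c(-3, -3, 0, log(0.9), 0), oracle_obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  o <- optim(o$par, oracle_obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-4)
})

test_that("restricted likelihood is invariant to translation and X recoding", {
  st <- tiny_study(n_families = 10, seed = 17)
  d <- st$design
  n <- length(d$ids)
  y <- simulate_phenotype(sge_scenario("average"), d, n_reps = 1, seed = 2)[, 1]
  X <- cbind(1, rep(c(0, 1), length.out = n))
  f1 <- suppressMessages(fit_sge(y, X, d, model = "full"))
  f2 <- suppressMessages(fit_sge(y + 100, X, d, model = "full"))
  Tm <- matrix(c(1, 1, 2, -1), 2, 2) # invertible recoding of the X basis
  f3 <- suppressMessages(fit_sge(y, X %*% Tm, d, model = "full"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-5)
  expect_equal(f1$sigma, f3$sigma, tolerance = 1e-3)
})

test_that("expected information agrees with averaged finite-difference Hessians", {
  ## the Fisher information is the negative *expected* Hessian of the
  ## restricted likelihood: compare against the Monte-Carlo average of
  ## finite-difference Hessians over fresh phenotype draws at the truth
  d <- unrelated_pairs_design(30)
  truth <- c(s2_AD = 0.3, s_ADS = 0, s2_AS = 0.2, s2_E = 0.5, cov_E = 0.1)
  spec <- sgemix:::model_spec("full", TRUE, d$kmax)
  Cm <- d$components[spec$keys]
  X <- matrix(1, 30, 1)
  V <- build_covariance(truth[c("s2_AD", "s_ADS", "s2_AS")], d, check = FALSE) +
    truth["s2_E"] * diag(30) + truth["cov_E"] * d$cages$Z
  ## analytic expected information on the sigma scale at the truth
  Vi <- solve(V + diag(1e-8, 30))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  nsig <- length(Cm)
  Mk <- lapply(Cm, function(C) P %*% C)
  info <- matrix(0, nsig, nsig)
  for (i in 1:nsig) for (j in 1:nsig) info[i, j] <- 0.5 * sum(Mk[[i]] * t(Mk[[j]]))

  ## MC average of numeric Hessians in sigma (finite difference of the
  ## analytic gradient returned by the objective, chain-rule-free blocks)
  grad_sigma <- function(y, vc) {
    V <- diag(1e-8, 30)
    for (k in seq_along(Cm)) V <- V + vc[k] * Cm[[k]]
    Vi <- solve(V)
    ViX <- Vi %*% X
    Py <- Vi %*% y - ViX %*% solve(crossprod(X, ViX), crossprod(ViX, y))
    P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    vapply(seq_along(Cm), function(k) {
      -0.5 * (sum(P * Cm[[k]]) - sum(Py * (Cm[[k]] %*% Py)))
    }, 0)
  }
  set.seed(77)
  L <- t(chol(V))
  R <- 150
  h <- 1e-4
  Hbar <- matrix(0, nsig, nsig)
  vc0 <- unname(truth)
  for (r in seq_len(R)) {
    y <- as.numeric(L %*% rnorm(30))
    Hy <- matrix(0, nsig, nsig)
    for (k in seq_len(nsig)) {
      vp <- vc0; vm <- vc0
      vp[k] <- vp[k] + h; vm[k] <- vm[k] - h
      Hy[, k] <- (grad_sigma(y, vp) - grad_sigma(y, vm)) / (2 * h)
    }
    Hbar <- Hbar + (-Hy)
  }
  Hbar <- Hbar / R
  expect_lt(norm(Hbar - info, "F") / norm(info, "F"), 0.2)
})

test_that("expected-information SEs shrink like sqrt(n) in a balanced design", {
  ## the expected information does not depend on the realized phenotypes, so
  ## the asymptotic scaling can be checked deterministically at the truth
  se_at_truth <- function(n_families) {
    d <- tiny_study(n_families = n_families, seed = 71)$design
    n <- length(d$ids)
    Cm <- d$components[c("s2_AD", "s2_ED")]
    V <- 0.3 * Cm[[1]] + 0.7 * Cm[[2]] + diag(1e-8, n)
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    Mk <- lapply(Cm, function(C) P %*% C)
    info <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) info[i, j] <- 0.5 * sum(Mk[[i]] * t(Mk[[j]]))
    sqrt(diag(solve(info)))
  }
  ratio <- se_at_truth(20) / se_at_truth(80)
  expect_equal(unname(ratio), c(2, 2), tolerance = 0.3)
})

test_that("rank-deficient covariates are rejected with the offending column", {
  d <- unrelated_pairs_design(30)
  y <- rnorm(30)
  X <- cbind(a = rep(1, 30), b = rep(2, 30))
  expect_error(suppressMessages(fit_sge(y, X, d)), "collinear")
})

test_that("missing phenotypes are dropped while cage mates keep acting socially", {
  st <- tiny_study(n_families = 12, seed = 23)
  d <- st$design
  y <- simulate_phenotype(sge_scenario("average"), d, n_reps = 1, seed = 6)[, 1]
  y2 <- y
  y2[seq(1, 36, by = 3)] <- NA
  fit <- suppressMessages(fit_sge(y2, design = d, model = "full"))
  expect_equal(fit$n, sum(!is.na(y2)))
  expect_true(is.finite(fit$loglik))
})
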