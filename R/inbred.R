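#' Covariate-aware Box-Cox normalization
#'
#' Chooses the Box-Cox power `lambda` that maximizes the profile
#' log-likelihood of the linear model `y(lambda) ~ X` over a grid on
#' `[-2, 2]` refined by golden-section search, and returns the transformed
#' vector `(y^lambda - 1) / lambda` (`log(y)` at `lambda = 0`).  The
#' covariates only inform the choice of `lambda`; they are not regressed out
#' of the returned values.  Non-positive phenotypes are shifted by a logged
#' offset before transforming.
#'
#' @param y Phenotype vector.
#' @param X Informing covariate matrix (default: intercept only).
#' @param grid Lambda grid for the coarse search.
#' @return Numeric vector of transformed phenotypes with attributes `lambda`
#'   and `offset`.
#' @export
boxcox_transform <- function(y, X = NULL, grid = seq(-2, 2, by = 0.1)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  offset <- 0
  if (any(y <= 0)) {
    offset <- -min(y) + 1e-3 * diff(range(y))
    if (min(y) + offset <= 0) stop("phenotype non-positive even after shift", call. = FALSE)
    rlang::inform(sprintf("shifted phenotype by %.4g before Box-Cox", offset),
                  class = "sgemix_boxcox_shift")
    y <- y + offset
  }
  bc <- function(lambda) if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  ## profile log-likelihood of the Gaussian linear model in y(lambda),
  ## including the transformation Jacobian (lambda - 1) * sum(log y)
  pll <- function(lambda) {
    z <- bc(lambda)
    rss <- sum(stats::lm.fit(X, z)$residuals^2)
    -n / 2 * log(rss / n) + (lambda - 1) * sum(log(y))
  }
  vals <- vapply(grid, pll, 0)
  i <- which.max(vals)
  lower <- grid[max(1, i - 1)]
  upper <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(pll, lower = lower, upper = upper, maximum = TRUE,
                         tol = 1e-6)
  lambda <- opt$maximum
  out <- bc(lambda)
  attr(out, "lambda") <- lambda
  attr(out, "offset") <- offset
  out
}

## fixed-effect formula for a term subset, respecting the coding
## strain = 0 (B6) / 1 (D2)
inbred_formula <- function(terms) {
  rhs <- c("1",
           if ("DGE" %in% terms) "strain",
           if ("SGE" %in% terms) "cagemate_strain",
           if ("DGExSGE" %in% terms) "strain:cagemate_strain")
  stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
}

#' Fit a fixed-effect DGE/SGE model to paired inbred data
#'
#' Generalized-least-squares fit of the two-strain fixed-effect model with,
#' optionally, compound-symmetry (exchangeable within-cage) residual
#' correlation, via [nlme::gls()] with a `corCompSymm` structure; the iid
#' mode fixes `rho = 0` and reduces exactly to ordinary least squares.
#'
#' @param obs Data frame with columns `y`, `strain`, `cagemate_strain`,
#'   `cage` (as produced by [simulate_inbred_experiment()]).
#' @param terms Subset of `c("DGE", "SGE", "DGExSGE")`; the interaction
#'   requires both main effects.
#' @param residual `"cs"` (compound symmetry) or `"iid"`.
#' @param method `"ML"` or `"REML"`.
#' @return Object of class `inbred_fit`: coefficients, `sigma2_E`, `rho`,
#'   log-likelihood, AIC, the underlying model object, and the data.
#' @export
fit_paired_model <- function(obs, terms = c("SGE"),
                             residual = c("cs", "iid"),
                             method = c("REML", "ML")) {
  residual <- match.arg(residual)
  method <- match.arg(method)
  terms <- match.arg(terms, c("DGE", "SGE", "DGExSGE"), several.ok = TRUE)
  if ("DGExSGE" %in% terms && !all(c("DGE", "SGE") %in% terms)) {
    stop("interaction requires both main effects (marginality)", call. = FALSE)
  }
  needed <- c(DGE = "strain", SGE = "cagemate_strain")
  for (tm in intersect(terms, names(needed))) {
    if (stats::var(obs[[needed[tm]]]) == 0) {
      stop(sprintf("no design variation for term %s (%s constant)", tm, needed[tm]),
           call. = FALSE)
    }
  }
  form <- inbred_formula(terms)
  obs <- as.data.frame(obs)
  fit <- if (residual == "cs") {
    nlme::gls(form, data = obs,
              correlation = nlme::corCompSymm(form = ~ 1 | cage),
              method = method)
  } else {
    nlme::gls(form, data = obs, method = method)
  }
  rho <- if (residual == "cs") {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else 0
  structure(
    list(
      coefficients = stats::coef(fit),
      sigma2_E = fit$sigma^2,
      rho = rho,
      logLik = as.numeric(stats::logLik(fit)),
      AIC = stats::AIC(fit),
      method = method,
      residual = residual,
      terms = terms,
      model = fit,
      data = obs
    ),
    class = "inbred_fit"
  )
}

#' @export
print.inbred_fit <- function(x, ...) {
  cat(sprintf("<inbred_fit: %s, %s residual, logLik(%s) = %.3f, rho = %.3f>\n",
              paste(x$terms, collapse = "+"), x$residual, x$method, x$logLik, x$rho))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' AIC model selection over DGE/SGE term combinations
#'
#' Fits, by maximum likelihood on identical rows, every
#' marginality-respecting combination of fixed terms
#' (`none`, `DGE`, `SGE`, `DGE+SGE`, `DGE+SGE+DGExSGE`) crossed with
#' iid / compound-symmetry residuals, and ranks by AIC.
#'
#' @param obs Paired observations (see [fit_paired_model()]).
#' @return Tibble of class `inbred_aic` with `model`, `terms`, `residual`,
#'   `df`, `logLik`, `AIC`, `best` (logical), ordered by AIC.
#' @export
aic_select <- function(obs) {
  term_sets <- list(character(0), "DGE", "SGE", c("DGE", "SGE"),
                    c("DGE", "SGE", "DGExSGE"))
  grid <- expand.grid(ts = seq_along(term_sets), residual = c("iid", "cs"),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(ts, residual) {
    terms <- term_sets[[ts]]
    fit <- if (length(terms) == 0) {
      ## intercept-only model fitted directly
      tryCatch({
        obs_df <- as.data.frame(obs)
        m <- if (residual == "cs") {
          nlme::gls(y ~ 1, data = obs_df,
                    correlation = nlme::corCompSymm(form = ~ 1 | cage), method = "ML")
        } else {
          nlme::gls(y ~ 1, data = obs_df, method = "ML")
        }
        list(logLik = as.numeric(stats::logLik(m)), AIC = stats::AIC(m),
             coefficients = stats::coef(m))
      }, error = function(e) NULL)
    } else {
      tryCatch(
        fit_paired_model(obs, terms = terms, residual = residual, method = "ML"),
        error = function(e) NULL
      )
    }
    if (is.null(fit)) {
      warning(sprintf("candidate {%s, %s} failed to fit; excluded",
                      paste(terms, collapse = "+"), residual), call. = FALSE)
      return(NULL)
    }
    k <- length(fit$coefficients) + 1 + (residual == "cs") # betas + sigma2 (+ rho)
    tibble::tibble(
      model = sprintf("%s/%s", if (length(terms)) paste(terms, collapse = "+") else "null",
                      residual),
      terms = paste(terms, collapse = "+"),
      residual = residual,
      df = k,
      logLik = fit$logLik,
      AIC = fit$AIC
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$AIC)
  out$best <- seq_len(nrow(out)) == 1L
  class(out) <- c("inbred_aic", class(out))
  out
}

#' Likelihood-ratio test of SGE within one focal strain
#'
#' Restricts to focal animals of one strain, optionally regresses out
#' covariates, and tests the cage-mate-strain coefficient by a ML
#' likelihood-ratio test with compound-symmetry residuals
#' (chi-squared, 1 df).
#'
#' @param obs Paired observations.
#' @param focal Focal strain code (0 = B6, 1 = D2).
#' @param covariates Optional matrix/data frame of covariates (same rows as
#'   `obs`), regressed out before testing (screened at `p < 0.05` per
#'   covariate).
#' @param method `"ML"` (default) or `"REML"` for the two compared fits.
#' @return Tibble with `focal`, `n`, `beta_S`, `statistic`, `df`, `p_value`.
#' @export
sge_test_per_strain <- function(obs, focal, covariates = NULL,
                                method = c("ML", "REML")) {
  method <- match.arg(method)
  obs <- as.data.frame(obs)
  if (!is.null(covariates)) {
    obs$y <- regress_covariates(obs$y, covariates)
  }
  sub <- obs[obs$strain == focal, , drop = FALSE]
  if (stats::var(sub$cagemate_strain) == 0) {
    stop("both cage-mate strains must be present among the focal subset", call. = FALSE)
  }
  fit1 <- fit_paired_model(sub, terms = "SGE", residual = "cs", method = method)
  m0 <- nlme::gls(y ~ 1, data = sub,
                  correlation = nlme::corCompSymm(form = ~ 1 | cage), method = method)
  stat <- max(0, 2 * (fit1$logLik - as.numeric(stats::logLik(m0))))
  tibble::tibble(
    focal = focal,
    n = nrow(sub),
    beta_S = unname(fit1$coefficients["cagemate_strain"]),
    statistic = stat,
    df = 1,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

## regress out covariates individually significant at p < 0.05 (screening
## threshold logged); returns residuals + grand mean
regress_covariates <- function(y, covariates, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(x) {
    f <- stats::lm(y ~ x)
    stats::anova(f)[["Pr(>F)"]][1] < alpha
  }, TRUE)
  if (!any(keep)) return(y)
  rlang::inform(paste("regressing out covariate(s):",
                      paste(names(covariates)[keep], collapse = ", ")),
                class = "sgemix_covariates")
  f <- stats::lm(y ~ ., data = covariates[, keep, drop = FALSE])
  stats::residuals(f) + mean(y)
}

#' Proportion of variance explained by each fixed term
#'
#' The numerator is the sample variance, across individuals, of the fitted
#' term's contribution (e.g. `var(beta_S * X_cm)` for SGE); the denominator
#' is the average sample variance of phenotypes drawn repeatedly from the
#' fitted model (fixed effects plus correlated residuals).  Standard errors
#' propagate coefficient uncertainty through the ratio to first order.
#'
#' @param fit An [fit_paired_model()] REML fit.
#' @param n_draws Monte-Carlo draws for the denominator.
#' @param seed Seed for the draws.
#' @return Tibble with `term`, `beta`, `proportion_pct`, `se_pct`.
#' @export
fixed_effect_variance <- function(fit, n_draws = 10000, seed = 1) {
  stopifnot(inherits(fit, "inbred_fit"))
  obs <- fit$data
  n <- nrow(obs)
  mm <- stats::model.matrix(inbred_formula(fit$terms), data = obs)
  beta <- fit$coefficients
  mu <- as.numeric(mm %*% beta)
  ## residual draws: exchangeable within cage
  cages <- split(seq_len(n), obs$cage)
  denom <- withr::with_seed(seed, {
    draws <- vapply(seq_len(n_draws), function(r) {
      e <- numeric(n)
      for (ix in cages) {
        k <- length(ix)
        if (k == 1) {
          e[ix] <- stats::rnorm(1, sd = sqrt(fit$sigma2_E))
        } else {
          S <- fit$sigma2_E * ((1 - fit$rho) * diag(k) + fit$rho)
          e[ix] <- as.numeric(t(chol(S)) %*% stats::rnorm(k))
        }
      }
      stats::var(mu + e)
    }, 0)
    mean(draws)
  })
  if (denom <= 0) stop("degenerate phenotypic variance", call. = FALSE)
  vc <- fit$model$varBeta
  terms_map <- c(DGE = "strain", SGE = "cagemate_strain", DGExSGE = "strain:cagemate_strain")
  rows <- lapply(fit$terms, function(tm) {
    col <- terms_map[[tm]]
    x <- mm[, col]
    b <- unname(beta[col])
    num <- stats::var(b * x)
    se_b <- sqrt(vc[col, col])
    se_num <- abs(2 * b * stats::var(x)) * se_b # first-order propagation
    tibble::tibble(
      term = tm,
      beta = b,
      proportion_pct = 100 * num / denom,
      se_pct = 100 * se_num / denom
    )
  })
  dplyr::bind_rows(rows)
}

#' Scan inbred traits for per-strain social genetic effects
#'
#' Applies covariate-aware Box-Cox normalization, the per-strain SGE
#' likelihood-ratio test and REML variance partitioning to each trait, in
#' both focal strains, and adjusts all tests jointly with [qvalues()].
#'
#' @param data Long-format tibble with columns `id`, `cage`, `strain`,
#'   `cagemate_strain`, `trait`, `value`.
#' @param covariates Optional covariate data frame (rows matching each
#'   trait's observations by `id`).
#' @param normalize Apply [boxcox_transform()] per trait (default `TRUE`).
#' @return Tibble: `trait`, `focal`, `n`, `beta_S`, `p_value`, `q_value`,
#'   `sge_pct`, `sge_pct_se`.
#' @export
inbred_scan <- function(data, covariates = NULL, normalize = TRUE) {
  stopifnot(all(c("cage", "strain", "cagemate_strain", "trait", "value") %in% names(data)))
  traits <- unique(data$trait)
  rows <- list()
  for (tr in traits) {
    sub <- data[data$trait == tr, , drop = FALSE]
    sub$y <- if (normalize) {
      X <- stats::model.matrix(~ strain * cagemate_strain, data = sub)
      as.numeric(boxcox_transform(sub$value, X))
    } else sub$value
    for (focal in c(0, 1)) {
      res <- tryCatch({
        test <- sge_test_per_strain(sub, focal, covariates = covariates)
        fsub <- sub[sub$strain == focal, , drop = FALSE]
        fit <- fit_paired_model(fsub, terms = "SGE", residual = "cs", method = "REML")
        fev <- fixed_effect_variance(fit, n_draws = 2000)
        tibble::tibble(
          trait = tr, focal = focal, n = test$n, beta_S = test$beta_S,
          p_value = test$p_value,
          sge_pct = fev$proportion_pct[fev$term == "SGE"],
          sge_pct_se = fev$se_pct[fev$term == "SGE"]
        )
      }, error = function(e) {
        tibble::tibble(trait = tr, focal = focal, n = NA_integer_,
                       beta_S = NA_real_, p_value = NA_real_,
                       sge_pct = NA_real_, sge_pct_se = NA_real_)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  if (any(ok)) out$q_value[ok] <- qvalues(out$p_value[ok])
  out[, c("trait", "focal", "n", "beta_S", "p_value", "q_value", "sge_pct", "sge_pct_se")]
}
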