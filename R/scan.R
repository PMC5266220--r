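#' Storey q-values
#'
#' False-discovery-rate adjusted significance measures: the null proportion
#' `pi0` is estimated from `pi0(lambda) = mean(p > lambda) / (1 - lambda)`
#' over the grid `lambda = 0.05, 0.10, ..., 0.95` with a cubic smoothing
#' spline (df = 3) evaluated at the largest lambda, and
#' `q_i = min over {j : p_j >= p_i} of pi0 * m * p_j / rank(p_j)`, clipped to
#' `[0, 1]`.  With `pi0 = 1` the procedure reduces to Benjamini-Hochberg.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion (estimated when `NULL`).
#' @return Vector of q-values, same order as `p`; the estimate used is
#'   attached as attribute `pi0`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    pi0 <- if (m < 4 * length(lambda)) {
      ## spline smoothing is unstable for short vectors; fall back to the
      ## conservative choice
      1
    } else {
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(sp, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 <= 0) pi0 <- 1e-8
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    j <- ord[i]
    rank_j <- m - i + 1
    running <- min(running, pi0 * m * p[j] / rank_j)
    q[j] <- min(running, 1)
  }
  attr(q, "pi0") <- pi0
  q
}

#' Scan many traits for social genetic effects
#'
#' For each trait column: fits the full and null models, computes the 2-df
#' restricted likelihood-ratio test and the DGE/SGE variance proportions,
#' then adjusts across traits with [qvalues()].
#'
#' @param phenotypes Data frame with an `id` column and one column per trait
#'   (`NA` allowed per trait).
#' @param design A [sge_design()] object covering the housed individuals.
#' @param covariates Optional named list mapping trait -> fixed-effect matrix
#'   (rows in `design$ids` order); traits absent from the list get an
#'   intercept only.
#' @param ... Passed to [fit_sge()].
#' @return Tibble of class `sge_scan` with columns `trait`, `sge_p`, `sge_q`,
#'   `sge_pct`, `sge_pct_se`, `dge_pct`, `dge_pct_se`, `rho_ads`, `status`.
#'   A run manifest (warnings, convergence flags) is attached as attribute
#'   `manifest`.
#' @export
sge_scan <- function(phenotypes, design, covariates = NULL, ...) {
  stopifnot("id" %in% names(phenotypes))
  traits <- setdiff(names(phenotypes), "id")
  if (length(traits) == 0) stop("no trait columns in phenotype table", call. = FALSE)
  ids <- design$ids
  ord <- match(ids, as.character(phenotypes$id))
  events <- list()
  rows <- lapply(traits, function(tr) {
    y <- stats::setNames(as.numeric(phenotypes[[tr]][ord]), ids)
    X <- covariates[[tr]] %||% NULL
    res <- withCallingHandlers(
      tryCatch(
        {
          lr <- lrt_sge(y, X, design, ...)
          fit <- attr(lr, "fit_full")
          vp <- variance_partition(fit)
          rho <- unname(fit$sigma["s_ADS"] /
                          sqrt(pmax(fit$sigma["s2_AD"] * fit$sigma["s2_AS"], 1e-12)))
          tibble::tibble(
            trait = tr,
            sge_p = lr$p_value,
            sge_pct = vp$proportion_pct[vp$component == "s2_AS"],
            sge_pct_se = vp$se_pct[vp$component == "s2_AS"],
            dge_pct = vp$proportion_pct[vp$component == "s2_AD"],
            dge_pct_se = vp$se_pct[vp$component == "s2_AD"],
            rho_ads = rho,
            status = if (fit$converged) "ok" else "not_converged"
          )
        },
        error = function(e) {
          tibble::tibble(trait = tr, sge_p = NA_real_, sge_pct = NA_real_,
                         sge_pct_se = NA_real_, dge_pct = NA_real_,
                         dge_pct_se = NA_real_, rho_ads = NA_real_,
                         status = paste0("error: ", conditionMessage(e)))
        }
      ),
      condition = function(c) {
        if (inherits(c, c("sgemix_jitter", "sgemix_collapse"))) {
          events[[length(events) + 1L]] <<- list(trait = tr, message = conditionMessage(c))
          if (inherits(c, "message")) invokeRestart("muffleMessage")
        }
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$sge_p)
  out$sge_q <- NA_real_
  if (any(ok)) out$sge_q[ok] <- qvalues(out$sge_p[ok])
  out <- out[, c("trait", "sge_p", "sge_q", "sge_pct", "sge_pct_se",
                 "dge_pct", "dge_pct_se", "rho_ads", "status")]
  attr(out, "manifest") <- list(
    n_traits = length(traits),
    status = as.list(stats::setNames(out$status, out$trait)),
    events = events
  )
  class(out) <- c("sge_scan", class(out))
  out
}
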