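#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a variance-component fit
#'
#' One row per variance component: estimate, Fisher standard error, and the
#' component's proportion of the sample phenotypic variance.
#'
#' @param x An [fit_sge()] result.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `proportion_pct`,
#'   `se_pct`.
#' @export
tidy.sge_fit <- function(x, ...) {
  vp <- variance_partition(x)
  tibble::tibble(
    term = vp$component,
    estimate = vp$estimate,
    std.error = unname(x$se[vp$component]),
    proportion_pct = vp$proportion_pct,
    se_pct = vp$se_pct
  )
}

#' @rdname tidy.sge_fit
#' @export
glance.sge_fit <- function(x, ...) {
  rho <- if (all(c("s2_AD", "s2_AS") %in% names(x$sigma)) && x$sigma["s2_AS"] > 1e-8) {
    unname(x$sigma["s_ADS"] / sqrt(x$sigma["s2_AD"] * x$sigma["s2_AS"]))
  } else NA_real_
  tibble::tibble(
    model = x$model,
    n = x$n,
    logLik = x$loglik,
    rho_ads = rho,
    converged = x$converged,
    collapsed_env = x$collapse_env
  )
}

#' Tidy a paired-design inbred fit
#'
#' @param x An [fit_paired_model()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.inbred_fit <- function(x, ...) {
  vb <- x$model$varBeta
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(diag(vb))[names(x$coefficients)]
  )
}

#' @rdname tidy.inbred_fit
#' @export
glance.inbred_fit <- function(x, ...) {
  tibble::tibble(
    terms = paste(x$terms, collapse = "+"),
    residual = x$residual,
    method = x$method,
    sigma2_E = x$sigma2_E,
    rho = x$rho,
    logLik = x$logLik,
    AIC = x$AIC
  )
}

#' Plot a bias study
#'
#' Boxplots of estimated-minus-simulated DGE (and SGE) proportions per
#' analysis model, whiskers at the 1st and 9th deciles.
#'
#' @param object A [run_bias_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sge_bias <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("dge_bias", "sge_bias"),
                            names_to = "component", values_to = "bias")
  df <- df[!is.na(df$bias), ]
  df$component <- toupper(sub("_bias", "", df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$bias,
                                   fill = .data$model)) +
    ggplot2::stat_summary(
      fun.data = function(v) {
        q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9))
        data.frame(ymin = q[1], lower = q[2], middle = q[3], upper = q[4], ymax = q[5])
      },
      geom = "boxplot"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = NULL, y = "estimated - simulated (% of variance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a multi-trait scan
#'
#' Estimated SGE proportion (with one-standard-error bars) against the
#' social-effect q-value per trait.
#'
#' @param object An [sge_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sge_scan <- function(object, ...) {
  df <- object[!is.na(object$sge_p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$sge_q), y = .data$sge_pct)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sge_pct - .data$sge_pct_se,
                                        ymax = .data$sge_pct + .data$sge_pct_se),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ "q-value (SGE)"),
                  y = "SGE variance (%)") +
    ggplot2::theme_minimal()
}
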