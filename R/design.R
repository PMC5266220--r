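#' Assemble an SGE model design
#'
#' Combines a relationship matrix and a cage design into the precomputed
#' component matrices of the phenotypic covariance
#' \deqn{cov(y) = \sigma^2_{AD} H_1 + \sigma_{ADS}(H_2 Z' + Z H_2') +
#'   \sigma^2_{AS} Z H_3 Z' + \sigma^2_{ED} I_1 +
#'   \sigma_{EDS}(I_2 Z' + Z I_2') + \sigma^2_{ES} Z I_3 Z' +
#'   \sigma^2_C W I_4 W'}
#' where each design matrix is scaled to unit sample variance
#' (see [scale_components()]), so every variance parameter is directly the
#' component's contribution to the sample phenotypic variance.
#'
#' @param H Relationship matrix (pedigree, genomic or single-step) over the
#'   housed individuals.
#' @param cages A cage table (`id`, `cage`) or a [cage_design()] object over
#'   the same individuals.
#' @return Object of class `sgemix_design` holding the ordered ids, the cage
#'   design, the scaled matrices and the per-component covariance design
#'   matrices.
#' @export
sge_design <- function(H, cages) {
  if (!inherits(cages, "sgemix_cages")) cages <- cage_design(cages)
  ids <- cages$ids
  if (is.null(rownames(H))) {
    if (nrow(H) != length(ids)) stop("H and cage table sizes differ", call. = FALSE)
    dimnames(H) <- list(ids, ids)
  }
  H <- subset_square(H, ids)
  if (max_asymmetry(H) > 1e-8) stop("H must be symmetric", call. = FALSE)
  H <- symmetrize(H)
  Z <- cages$Z
  W <- cages$W
  sc <- scale_components(H, Z, W)
  H2Z <- sc$H2 %*% Z
  components <- list(
    s2_AD = sc$H1,
    s_ADS = H2Z + t(H2Z),
    s2_AS = Z %*% sc$H3 %*% Z,
    s2_ED = sc$I1,
    s_EDS = 2 * Z / sqrt(sc$s_ZIZ),
    s2_ES = (Z %*% Z) / sc$s_ZIZ,
    s2_C  = tcrossprod(W) / sc$s_WIW,
    cov_E = Z  # off-diagonal indicator for the collapsed residual
  )
  structure(
    list(ids = ids, cages = cages, H = H, scaled = sc,
         components = components, kmax = max(cages$sizes)),
    class = "sgemix_design"
  )
}

#' @export
print.sgemix_design <- function(x, ...) {
  cat(sprintf("<sgemix_design: %d individuals, %d cages (sizes %s)%s>\n",
              length(x$ids), length(x$cages$sizes),
              paste(unique(range(x$cages$sizes)), collapse = "-"),
              if (x$cages$constant_size) ", constant cage size" else ""))
  invisible(x)
}

#' Phenotypic covariance implied by a set of variance components
#'
#' Direct assembly of the model covariance from named components.  Missing
#' components are treated as zero.
#'
#' @param vc Named numeric vector or list with any of `s2_AD`, `s_ADS`,
#'   `s2_AS`, `s2_ED`, `s_EDS`, `s2_ES`, `s2_C` (sample-variance scale).
#' @param design A [sge_design()] object.
#' @param check If `TRUE` (default), reject an indefinite result, reporting
#'   the smallest eigenvalue.
#' @return Symmetric covariance matrix over `design$ids`.
#' @export
build_covariance <- function(vc, design, check = TRUE) {
  stopifnot(inherits(design, "sgemix_design"))
  vc <- unlist(vc)
  known <- c("s2_AD", "s_ADS", "s2_AS", "s2_ED", "s_EDS", "s2_ES", "s2_C")
  extra <- setdiff(names(vc), known)
  if (length(extra)) stop("unknown component(s): ", paste(extra, collapse = ", "), call. = FALSE)
  n <- length(design$ids)
  V <- matrix(0, n, n, dimnames = list(design$ids, design$ids))
  for (k in names(vc)) {
    if (vc[[k]] != 0) V <- V + vc[[k]] * design$components[[k]]
  }
  if (check) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(1, max(abs(V)))) {
      stop(sprintf("assembled covariance is indefinite (smallest eigenvalue %.3g)", ev),
           call. = FALSE)
    }
  }
  V
}
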