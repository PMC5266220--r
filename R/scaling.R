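#' Sample variance of a covariance matrix
#'
#' `sampleVar(M) = Tr(P M P) / (n - 1)` with `P = I - 11'/n` the centring
#' matrix: the average variance the covariance structure `M` induces across a
#' mean-centred sample.  `sample_var(I) = 1` for any n, and the value is
#' invariant to adding a constant to every entry of `M`.
#'
#' @param M Square numeric matrix, `n >= 2`.
#' @return Scalar sample variance.
#' @export
sample_var <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n != ncol(M)) stop("M must be square", call. = FALSE)
  if (n < 2) stop("sample_var requires n >= 2", call. = FALSE)
  # Tr(PMP) = Tr(MP) since P is idempotent; Tr(MP) = Tr(M) - 1'M1/n
  (sum(diag(M)) - sum(M) / n) / (n - 1)
}

#' Scale relationship and identity matrices to unit sample variance
#'
#' Produces the scaled design matrices used by the phenotypic covariance:
#' `H1 = H / sampleVar(H)`, `H3 = H / sampleVar(Z H Z')` and
#' `H2 = H / sqrt(sampleVar(H) * sampleVar(Z H Z'))` (geometric-mean
#' convention, so the direct-social covariance parameter divided by the
#' component standard deviations is a correlation bounded by 1).  The identity
#' analogues `I1`--`I3` use `I` in place of `H`, and
#' `I4 = I / sampleVar(W I W')`.  With this scaling each variance component
#' contributes its own magnitude to the sample variance of the phenotypic
#' covariance matrix.
#'
#' @param H Relationship matrix over the housed individuals.
#' @param Z Cage-mate indicator (zero diagonal), same order as `H`.
#' @param W Cage incidence matrix (individuals x cages).
#' @return List with matrices `H1`, `H2`, `H3`, `I1`, `I2`, `I3`, `I4` and the
#'   underlying scalars `s_H`, `s_ZHZ`, `s_ZIZ`, `s_WIW`.
#' @export
scale_components <- function(H, Z, W) {
  stopifnot(nrow(H) == nrow(Z), nrow(Z) == nrow(W))
  if (any(diag(Z) != 0)) stop("Z must have a zero diagonal", call. = FALSE)
  n <- nrow(H)
  ZHZ <- Z %*% H %*% Z
  s_H <- sample_var(H)
  s_ZHZ <- sample_var(ZHZ)
  s_ZIZ <- sample_var(Z %*% Z)
  s_WIW <- sample_var(tcrossprod(W))
  s <- c(s_H = s_H, s_ZHZ = s_ZHZ, s_ZIZ = s_ZIZ, s_WIW = s_WIW)
  if (any(s <= 0)) {
    stop("degenerate design: non-positive sample variance in ",
         paste(names(s)[s <= 0], collapse = ", "), call. = FALSE)
  }
  I_n <- diag(n)
  dimnames(I_n) <- dimnames(H)
  list(
    H1 = H / s_H,
    H2 = H / sqrt(s_H * s_ZHZ),
    H3 = H / s_ZHZ,
    I1 = I_n,
    I2 = I_n / sqrt(s_ZIZ),
    I3 = I_n / s_ZIZ,
    I4 = I_n / s_WIW,
    s_H = s_H, s_ZHZ = s_ZHZ, s_ZIZ = s_ZIZ, s_WIW = s_WIW
  )
}
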