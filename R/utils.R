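# internal helpers shared across modules

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Cholesky-based symmetric inversion with escalating diagonal jitter.
## Jitter levels follow the package convention 1e-10 -> 1e-6; every jitter
## event is signalled as a condition of class "sgemix_jitter" so callers
## (and run manifests) can record it.
chol_inverse <- function(M, label = "matrix") {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  jitters <- c(0, 1e-10, 1e-8, 1e-6)
  for (j in jitters) {
    Mj <- M
    if (j > 0) diag(Mj) <- diag(Mj) + j
    ch <- tryCatch(chol(Mj), error = function(e) NULL)
    if (!is.null(ch)) {
      if (j > 0) {
        rlang::inform(
          sprintf("added diagonal jitter %.0e to invert %s", j, label),
          class = "sgemix_jitter"
        )
      }
      out <- chol2inv(ch)
      dimnames(out) <- dimnames(M)
      attr(out, "jitter") <- j
      return(out)
    }
  }
  kappa_est <- tryCatch(kappa(M, exact = FALSE), error = function(e) NA_real_)
  stop(sprintf(
    "%s is singular or indefinite even after jitter up to 1e-6 (condition number ~ %.3g)",
    label, kappa_est
  ), call. = FALSE)
}

## max |M - t(M)|, used in validity checks
max_asymmetry <- function(M) max(abs(M - t(M)))

symmetrize <- function(M) (M + t(M)) / 2

## subset a named square matrix by ids, preserving order of `ids`
subset_square <- function(M, ids) {
  idx <- match(ids, rownames(M))
  if (anyNA(idx)) {
    stop("ids not present in matrix: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  M[idx, idx, drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
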