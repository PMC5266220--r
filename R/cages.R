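#' Read a cage-assignment table
#'
#' @param path TSV with header columns `id` and `cage`.
#' @return Tibble with character `id` and `cage`.
#' @export
read_cages <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("id", "cage") %in% names(tbl))) {
    stop("cage file must have header columns id, cage", call. = FALSE)
  }
  tbl[, c("id", "cage")]
}

#' Cage design matrices
#'
#' From a cage-membership table derives the cage-mate indicator
#' `Z` (`Z[i,j] = 1` iff `i != j` and i, j share a cage; zero diagonal) and
#' the cage incidence `W` (individuals x cages, each row one 1).
#'
#' @param cages Data frame with columns `id` and `cage`.
#' @return List of class `sgemix_cages`: `ids`, `cage` (named vector), `Z`,
#'   `W`, `sizes` (per-cage size), `constant_size` (logical).
#' @export
cage_design <- function(cages) {
  ids <- as.character(cages$id)
  if (anyDuplicated(ids)) stop("duplicated individual ids in cage table", call. = FALSE)
  cage <- as.character(cages$cage)
  cage_levels <- unique(cage)
  W <- outer(cage, cage_levels, `==`) * 1
  dimnames(W) <- list(ids, cage_levels)
  Z <- tcrossprod(W)
  diag(Z) <- 0
  dimnames(Z) <- list(ids, ids)
  sizes <- colSums(W)
  structure(
    list(ids = ids, cage = stats::setNames(cage, ids), Z = Z, W = W,
         sizes = sizes, constant_size = length(unique(sizes)) == 1L),
    class = "sgemix_cages"
  )
}

#' @export
print.sgemix_cages <- function(x, ...) {
  cat(sprintf("<sgemix_cages: %d individuals in %d cages (sizes %s)>\n",
              length(x$ids), length(x$sizes),
              paste(range(x$sizes), collapse = "-")))
  invisible(x)
}
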