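#' Read a three-column pedigree
#'
#' Reads a tab-separated pedigree with header columns `id`, `sire`, `dam`.
#' Unknown parents are coded `0` or `NA`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `sgemix_pedigree` with character columns
#'   `id`, `sire`, `dam` (`NA` = unknown parent).
#' @export
read_pedigree <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("id", "sire", "dam") %in% names(tbl))) {
    stop("pedigree file must have header columns id, sire, dam", call. = FALSE)
  }
  as_pedigree(tbl)
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, resolves unknown-parent codes (`"0"`, `""`, `NA`) and
#' verifies that the pedigree is acyclic (a topological order with parents
#' before offspring exists).  Parents that appear only as parents are added as
#' founder records.
#'
#' @param df Data frame with columns `id`, `sire`, `dam`.
#' @return A tibble of class `sgemix_pedigree`, topologically ordered.
#' @export
as_pedigree <- function(df) {
  ped <- tibble::tibble(
    id   = as.character(df$id),
    sire = as.character(df$sire),
    dam  = as.character(df$dam)
  )
  unk <- function(x) ifelse(is.na(x) | x %in% c("0", "", "NA"), NA_character_, x)
  ped$sire <- unk(ped$sire)
  ped$dam <- unk(ped$dam)
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "), call. = FALSE)
  }
  ## implicit founders: ids referenced as parents but lacking a record
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    ped <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }
  ord <- pedigree_toposort(ped)
  ped <- ped[ord, ]
  class(ped) <- c("sgemix_pedigree", class(ped))
  ped
}

## Kahn's algorithm; errors with the offending chain on a cycle
pedigree_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  ## children lists
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[cyc], collapse = " -> "), call. = FALSE)
  }
  out
}

#' Wright's numerator relationship matrix
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree by
#' the tabular method: founders are treated as unrelated and non-inbred,
#' `A[i,i] = 1 + F_i` with inbreeding `F_i = A[sire_i, dam_i] / 2`, and
#' `A[i,j] = (A[j, sire_i] + A[j, dam_i]) / 2` for `j` processed before `i`.
#'
#' @param ped A pedigree from [as_pedigree()] or [read_pedigree()].
#' @param ids Optional character vector: order/subset of individuals for the
#'   returned matrix (defaults to all, pedigree order).
#' @return A symmetric numeric matrix with dimnames set to individual ids and
#'   attribute `kind = "A"`.
#' @export
pedigree_A <- function(ped, ids = NULL) {
  if (!inherits(ped, "sgemix_pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    prev <- seq_len(i - 1L)
    if (length(prev)) {
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + A[prev, s]
      if (!is.na(d)) v <- v + A[prev, d]
      v <- v / 2
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  if (!is.null(ids)) A <- subset_square(A, as.character(ids))
  attr(A, "kind") <- "A"
  A
}
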