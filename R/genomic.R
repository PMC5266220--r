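#' Read a genotype dosage matrix
#'
#' Accepts either a plain TSV matrix (first column = individual id, remaining
#' columns = loci, dosages 0/1/2/NA) or a PLINK-`.raw`-style additive file
#' (columns `FID IID PAT MAT SEX PHENOTYPE` followed by per-SNP dosages).
#' The dialect is auto-detected from the header.
#'
#' @param path Path to the file.
#' @return A named list of class `sgemix_genotypes` with elements `ids`
#'   (character), `loci` (character) and `dosage` (individuals x loci numeric
#'   matrix, possibly with `NA`).
#' @export
read_genotypes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  plink_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_cols %in% names(tbl))) {
    ids <- as.character(tbl$IID)
    dos <- as.matrix(tbl[, setdiff(names(tbl), plink_cols), drop = FALSE])
  } else {
    ids <- as.character(tbl[[1]])
    dos <- as.matrix(tbl[, -1, drop = FALSE])
  }
  storage.mode(dos) <- "double"
  rownames(dos) <- ids
  bad <- dos[!is.na(dos)]
  if (length(bad) && any(bad != round(bad) | bad < 0 | bad > 2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  structure(list(ids = ids, loci = colnames(dos), dosage = dos),
            class = "sgemix_genotypes")
}

#' @export
print.sgemix_genotypes <- function(x, ...) {
  cat(sprintf("<sgemix_genotypes: %d individuals x %d loci>\n",
              length(x$ids), length(x$loci)))
  invisible(x)
}

#' Genomic relationship matrix from dosages
#'
#' Computes `G = M M' / (2 * sum(p_i q_i))` where row `m_i` of `M` holds the
#' individual's dosages centred by twice the observed allele frequency at each
#' locus.  Monomorphic loci are dropped (with a message) and missing dosages
#' are mean-imputed per locus before centring.
#'
#' @param geno A `sgemix_genotypes` object (or a bare dosage matrix with
#'   rownames).
#' @return Symmetric relationship matrix (attribute `kind = "G_raw"`).
#' @export
genomic_G <- function(geno) {
  dos <- if (inherits(geno, "sgemix_genotypes")) geno$dosage else as.matrix(geno)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("ind", seq_len(nrow(dos)))
  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic: genomic denominator is zero", call. = FALSE)
  if (any(!poly)) {
    rlang::inform(sprintf("dropped %d monomorphic locus/loci before G", sum(!poly)),
                  class = "sgemix_monomorphic")
  }
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(dos, 2, 2 * p)
  M[is.na(M)] <- 0 # mean imputation: centred missing dosage is 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  G <- symmetrize(G)
  dimnames(G) <- list(rownames(dos), rownames(dos))
  attr(G, "kind") <- "G_raw"
  G
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' Forms `G* = 0.95 * (a + b * G_raw) + 0.05 * A_gg`, the drift/base-population
#' correction that makes the genomic and pedigree matrices refer to the same
#' base population and guarantees `G*` is a valid covariance matrix.  The
#' default constants are `a = 0.015`, `b = 0.982`; with `method = "match"`,
#' `(a, b)` are instead computed by solving the 2x2 linear system that matches
#' the mean diagonal and mean off-diagonal of `b * G_raw + a` to those of
#' `A_gg`.
#'
#' @param G_raw Raw genomic relationship matrix.
#' @param A_gg Pedigree relationship submatrix over the same individuals.
#' @param a,b Blend constants used when `method = "fixed"`.
#' @param method `"fixed"` or `"match"`.
#' @return Blended matrix (attribute `kind = "G_star"`, attributes `a`, `b`).
#' @export
blend_G <- function(G_raw, A_gg, a = 0.015, b = 0.982,
                    method = c("fixed", "match")) {
  method <- match.arg(method)
  if (!identical(rownames(G_raw), rownames(A_gg))) {
    stop("G_raw and A_gg must cover the identical ordered individual set", call. = FALSE)
  }
  if (method == "match") {
    md_G <- mean(diag(G_raw)); mo_G <- mean(G_raw[upper.tri(G_raw)])
    md_A <- mean(diag(A_gg));  mo_A <- mean(A_gg[upper.tri(A_gg)])
    if (abs(md_G - mo_G) < .Machine$double.eps^0.5) {
      stop("cannot match means: G_raw has equal mean diagonal and off-diagonal", call. = FALSE)
    }
    b <- (md_A - mo_A) / (md_G - mo_G)
    a <- md_A - b * md_G
  }
  Gs <- 0.95 * (a + b * G_raw) + 0.05 * A_gg
  attr(Gs, "kind") <- "G_star"
  attr(Gs, "a") <- a
  attr(Gs, "b") <- b
  Gs
}

#' Single-step (H) relationship matrix
#'
#' Combines pedigree and genomic information so genotyped and non-genotyped
#' individuals share one coherent relationship matrix:
#' `H^-1 = A^-1 + blockdiag(0, G*^-1 - A_gg^-1)` on the
#' (non-genotyped, genotyped) partition, then `H = (H^-1)^-1`, returned in the
#' id order of `A`.  With no genotyped individuals `H = A`; with all
#' individuals genotyped `H = G*`.
#'
#' @param A Pedigree relationship matrix over all individuals.
#' @param G_star Blended genomic matrix over the genotyped individuals.
#' @param genotyped_ids Character vector of genotyped ids (subset of
#'   `rownames(A)`).
#' @return Symmetric matrix over all ids (attribute `kind = "H"`).
#' @export
build_H <- function(A, G_star, genotyped_ids) {
  ids <- rownames(A)
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% ids)) {
    stop("genotyped ids absent from A: ",
         paste(setdiff(genotyped_ids, ids), collapse = ", "), call. = FALSE)
  }
  if (length(genotyped_ids) == 0) {
    H <- A
    attr(H, "kind") <- "H"
    return(H)
  }
  if (!identical(sort(rownames(G_star)), sort(genotyped_ids))) {
    stop("G_star must cover exactly the genotyped ids", call. = FALSE)
  }
  g <- genotyped_ids
  ng <- setdiff(ids, g)
  ordered <- c(ng, g)
  Ao <- subset_square(A, ordered)
  Gs <- subset_square(G_star, g)
  Agg <- subset_square(A, g)
  Ainv <- chol_inverse(Ao, "A")
  Gsinv <- chol_inverse(Gs, "G(*)")
  Agginv <- chol_inverse(Agg, "A_gg")
  gi <- seq.int(length(ng) + 1L, length(ordered))
  Hinv <- Ainv
  Hinv[gi, gi] <- Hinv[gi, gi] + (Gsinv - Agginv)
  H <- chol_inverse(Hinv, "H^-1")
  H <- symmetrize(H)
  dimnames(H) <- list(ordered, ordered)
  H <- subset_square(H, ids)
  attr(H, "kind") <- "H"
  H
}

#' Persist / load a relationship matrix as TSV
#'
#' Small plain-text persistence: first column `id`, remaining columns the
#' matrix entries with ids as header.
#'
#' @param M Named symmetric matrix.
#' @param path Output path.
#' @export
write_relatedness <- function(M, path) {
  tbl <- tibble::as_tibble(M, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(id = rownames(M)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_relatedness
#' @export
read_relatedness <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(id = readr::col_character(),
                                                       .default = readr::col_double()),
                         progress = FALSE)
  M <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(M) <- tbl$id
  if (max_asymmetry(M) > 1e-8) stop("stored relationship matrix is not symmetric", call. = FALSE)
  symmetrize(M)
}
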