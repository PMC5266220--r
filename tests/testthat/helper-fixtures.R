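# shared fixtures and independent oracles, built in code

## recursive-definition kinship oracle: A = 2 * phi, with
## phi(i,i) = 0.5 * (1 + phi(s_i, d_i)), phi(i,j) = 0.5*(phi(j, s_i) + phi(j, d_i))
## for i later in pedigree order than j (memoized, independent of the tabular path)
oracle_A <- function(ped) {
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  phi <- matrix(NA_real_, n, n)
  get_phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      s <- si[i]; d <- di[i]
      0.5 * (1 + get_phi(ifelse(is.na(s), 0, s), ifelse(is.na(d), 0, d)))
    } else {
      a <- max(i, j); b <- min(i, j) # a is later in pedigree order
      s <- si[a]; d <- di[a]
      0.5 * (get_phi(b, ifelse(is.na(s), 0, s)) + get_phi(b, ifelse(is.na(d), 0, d)))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * get_phi(i, j)
  A
}

## five-animal pedigree with a full-sib mating (offspring x inbred, F = 0.25)
ped_fullsib <- function() {
  tibble::tibble(
    id = c("f1", "f2", "k1", "k2", "x"),
    sire = c(NA, NA, "f1", "f1", "k1"),
    dam = c(NA, NA, "f2", "f2", "k2")
  )
}

## pedigree spanning three generations with mixed founders (12 animals)
ped_threegen <- function() {
  tibble::tibble(
    id   = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l"),
    sire = c(NA, NA, NA, NA, "a", "a", "c", "c", "e", "e", "g", "i"),
    dam  = c(NA, NA, NA, NA, "b", "b", "d", "d", "f", "h", "h", "j")
  )
}

## tiny outbred study for fast model tests
tiny_study <- function(n_families = 20, cage_size = 3, seed = 42, weight = 0.5) {
  simulate_sge_study(
    n_families = n_families, family_size = 3, n_loci = 300,
    cage_size = cage_size, cohousing_weight = weight, seed = seed
  )
}

## design with unrelated individuals in cages of two (null structure)
unrelated_pairs_design <- function(n = 60) {
  ids <- sprintf("u%02d", seq_len(n))
  H <- diag(n)
  dimnames(H) <- list(ids, ids)
  cages <- tibble::tibble(id = ids, cage = rep(sprintf("c%02d", seq_len(n / 2)), each = 2))
  sge_design(H, cages)
}

## orthonormal-error-contrast restricted log-likelihood: an oracle for the
## REML objective that never touches the package's internal formula
oracle_restricted_ll <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  A <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE] # orthonormal, A'X = 0
  W <- crossprod(A, V) %*% A
  z <- crossprod(A, y)
  ch <- chol(W)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(z * backsolve(ch, forwardsolve(t(ch), z))))
}

## direct MVN density with per-cage block-exchangeable covariance: oracle for
## the paired-design GLS likelihood
oracle_paired_ll <- function(obs, beta, sigma2, rho, terms = "SGE") {
  mm <- stats::model.matrix(sgemix:::inbred_formula(terms), data = as.data.frame(obs))
  r <- obs$y - as.numeric(mm %*% beta)
  ll <- 0
  for (ix in split(seq_len(nrow(obs)), obs$cage)) {
    k <- length(ix)
    S <- sigma2 * ((1 - rho) * diag(k) + rho)
    ll <- ll + mvn_logdens(r[ix], S)
  }
  ll
}

mvn_logdens <- function(x, S) {
  k <- length(x)
  ch <- chol(S)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(x * backsolve(ch, forwardsolve(t(ch), x))))
}
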