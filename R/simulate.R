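#' Simulate a pedigree-structured population with genotypes
#'
#' Founders (two per family) are drawn in Hardy-Weinberg equilibrium at
#' uniform allele frequencies; descendant genotypes are produced by Mendelian
#' gene dropping through the pedigree.  With `generations = 0` only founders
#' are returned; with `generations >= 2` mating pairs are resampled from the
#' previous generation, deepening the pedigree.  The last generation forms
#' the study cohort (column `study` in the pedigree).
#'
#' @param n_families Number of families per generation.
#' @param family_size Offspring per family.
#' @param n_loci Number of biallelic loci.
#' @param freq_range Founder allele-frequency range, inside (0, 1).
#' @param generations Number of offspring generations (default 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `sgemix_population`: `pedigree` (tibble `id`,
#'   `sire`, `dam`, `generation`, `family`, `study`), `genotypes`
#'   (`sgemix_genotypes` over all individuals), `study_ids`, `family` (named
#'   vector over study ids).
#' @export
simulate_population <- function(n_families = 200, family_size = 3, n_loci = 2000,
                                freq_range = c(0.1, 0.9), generations = 1,
                                seed = 1) {
  stopifnot(n_families >= 1, family_size >= 1, n_loci >= 1, generations >= 0,
            freq_range[1] > 0, freq_range[2] < 1, freq_range[1] <= freq_range[2])
  withr::with_seed(seed, {
    p <- stats::runif(n_loci, freq_range[1], freq_range[2])
    n_founders <- 2L * n_families
    founder_ids <- sprintf("F%04d", seq_len(n_founders))
    dos <- matrix(stats::rbinom(n_founders * n_loci, 2L, rep(p, each = n_founders)),
                  n_founders, n_loci)
    ped <- tibble::tibble(id = founder_ids, sire = NA_character_, dam = NA_character_,
                          generation = 0L, family = NA_integer_)
    gam <- function(d) { # one gamete per locus from a dosage row
      out <- integer(length(d))
      het <- d == 1L
      out[d == 2L] <- 1L
      out[het] <- stats::rbinom(sum(het), 1L, 0.5)
      out
    }
    prev_ids <- founder_ids
    prev_rows <- seq_len(n_founders)
    all_dos <- dos
    g <- 0L
    while (g < generations) {
      g <- g + 1L
      pick <- sample(seq_along(prev_ids), 2L * n_families)
      sires <- prev_ids[pick[seq_len(n_families)]]
      dams <- prev_ids[pick[n_families + seq_len(n_families)]]
      ids_g <- sprintf("G%d_%04d", g, seq_len(n_families * family_size))
      fam_g <- rep(seq_len(n_families), each = family_size)
      kid_dos <- matrix(0L, length(ids_g), n_loci)
      for (i in seq_along(ids_g)) {
        f <- fam_g[i]
        srow <- all_dos[match(sires[f], rownames_all(ped, all_dos)), ]
        drow <- all_dos[match(dams[f], rownames_all(ped, all_dos)), ]
        kid_dos[i, ] <- gam(srow) + gam(drow)
      }
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        id = ids_g, sire = sires[fam_g], dam = dams[fam_g],
        generation = g, family = fam_g
      ))
      all_dos <- rbind(all_dos, kid_dos)
      prev_ids <- ids_g
    }
    rownames(all_dos) <- ped$id
    study_ids <- ped$id[ped$generation == max(ped$generation)]
    ped$study <- ped$id %in% study_ids
    geno <- structure(
      list(ids = ped$id, loci = sprintf("snp%05d", seq_len(n_loci)), dosage = all_dos),
      class = "sgemix_genotypes"
    )
    colnames(geno$dosage) <- geno$loci
    fam <- stats::setNames(ped$family[match(study_ids, ped$id)], study_ids)
    structure(
      list(pedigree = ped, genotypes = geno, study_ids = study_ids, family = fam),
      class = "sgemix_population"
    )
  })
}

## id lookup helper kept out of the hot loop's closure for clarity
rownames_all <- function(ped, dos) ped$id[seq_len(nrow(dos))]

#' @export
print.sgemix_population <- function(x, ...) {
  cat(sprintf("<sgemix_population: %d individuals (%d study), %d loci>\n",
              nrow(x$pedigree), length(x$study_ids), length(x$genotypes$loci)))
  invisible(x)
}

#' Assign individuals to cages with a sibling-cohousing preference
#'
#' Cages are filled sequentially: a random seed individual starts each cage
#' and each remaining slot is filled, with probability `weight`, by a random
#' unassigned member of the seed's family (when one exists), otherwise by a
#' random unassigned individual.  `weight = 0` gives fully random assignment;
#' `weight = 1` packs full-sib groups, reproducing the above-average
#' within-cage relatedness seen in real group-housed colonies.
#'
#' @param ids Character vector of individuals to house.
#' @param family Named vector mapping id -> family label.
#' @param cage_size Either a single size or a data frame with columns `size`
#'   and `prob` giving the cage-size distribution.
#' @param weight Sibling-cohousing weight in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble with columns `id` and `cage`.
#' @export
assign_cages <- function(ids, family, cage_size = 3, weight = 0.5, seed = 1) {
  stopifnot(weight >= 0, weight <= 1)
  ids <- as.character(ids)
  n <- length(ids)
  withr::with_seed(seed, {
    sizes <- if (is.data.frame(cage_size)) {
      draw <- integer(0)
      while (sum(draw) < n) {
        draw <- c(draw, sample(cage_size$size, 1, prob = cage_size$prob))
      }
      draw
    } else {
      if (cage_size < 1) stop("cage size must be >= 1", call. = FALSE)
      rep(as.integer(cage_size), ceiling(n / cage_size))
    }
    ## trim the final cage to the remaining animals
    cum <- cumsum(sizes)
    k <- which(cum >= n)[1]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- sizes[k] - (cum[k] - n)
    if (sizes[k] < 1) sizes <- sizes[-k]
    if (sum(sizes) != n) stop("infeasible cage partition", call. = FALSE)

    unassigned <- ids
    fam <- family[ids]
    out_id <- character(0)
    out_cage <- character(0)
    for (cg in seq_along(sizes)) {
      seed_i <- sample(unassigned, 1)
      members <- seed_i
      unassigned <- setdiff(unassigned, seed_i)
      while (length(members) < sizes[cg] && length(unassigned) > 0) {
        sibs <- unassigned[!is.na(fam[unassigned]) &
                             fam[unassigned] %in% fam[seed_i]]
        nxt <- if (length(sibs) > 0 && stats::runif(1) < weight) {
          if (length(sibs) == 1) sibs else sample(sibs, 1)
        } else {
          if (length(unassigned) == 1) unassigned else sample(unassigned, 1)
        }
        members <- c(members, nxt)
        unassigned <- setdiff(unassigned, nxt)
      }
      out_id <- c(out_id, members)
      out_cage <- c(out_cage, rep(sprintf("cage%04d", cg), length(members)))
    }
    tibble::tibble(id = out_id, cage = out_cage)[match(ids, out_id), ]
  })
}

#' Simulation scenario parameter sets
#'
#' Named variance-component scenarios on the percent scale, matching the
#' package's reference simulation study: `"average"` uses the contribution of
#' every component averaged over organismal phenotypes
#' (`s2_AD = 15`, `s2_AS = 4`, `rho_ADS = 0.5`, `s2_ED = 52`, `s2_ES = 0`,
#' `rho_EDS = 0`, `s2_C = 22`); `"high-sge"` averages the six phenotypes with
#' strongest social effects (`s2_AD = 5`, `s2_AS = 27`, `rho_ADS = 0.92`,
#' `s2_ED = 5`, `s2_ES = 0`, `rho_EDS = 0`, `s2_C = 51`).  Individual values
#' can be overridden.
#'
#' @param name `"average"` or `"high-sge"`.
#' @param ... Named overrides (percent scale for variances; correlations on
#'   `[-1, 1]`).
#' @return Named numeric vector with elements `s2_AD`, `s2_AS`, `rho_ADS`,
#'   `s2_ED`, `s2_ES`, `rho_EDS`, `s2_C` (variances in percent of total).
#' @export
sge_scenario <- function(name = c("average", "high-sge"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "average" = c(s2_AD = 15, s2_AS = 4, rho_ADS = 0.5,
                  s2_ED = 52, s2_ES = 0, rho_EDS = 0, s2_C = 22),
    "high-sge" = c(s2_AD = 5, s2_AS = 27, rho_ADS = 0.92,
                   s2_ED = 5, s2_ES = 0, rho_EDS = 0, s2_C = 51)
  )
  over <- unlist(list(...))
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown scenario parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    base[names(over)] <- over
  }
  base
}

## percent-scale scenario -> sample-variance-scale components
scenario_components <- function(scn) {
  v <- scn / 100
  c(
    s2_AD = unname(v["s2_AD"]),
    s_ADS = unname(scn["rho_ADS"] * sqrt(v["s2_AD"] * v["s2_AS"])),
    s2_AS = unname(v["s2_AS"]),
    s2_ED = unname(v["s2_ED"]),
    s_EDS = unname(scn["rho_EDS"] * sqrt(v["s2_ED"] * v["s2_ES"])),
    s2_ES = unname(v["s2_ES"]),
    s2_C = unname(v["s2_C"])
  )
}

#' Draw phenotypes from the full SGE model
#'
#' Draws `(a_D, a_S)` jointly from the 2n-dimensional normal with covariance
#' `[[s2_AD * H1, s_ADS * H2], [s_ADS * H2, s2_AS * H3]]` (a Kronecker
#' product, thanks to the shared `H` kernel), `(e_D, e_S)` analogously with
#' identity kernels, cage effects from `s2_C * I4`, and assembles
#' `y = X b + a_D + Z a_S + e_D + Z e_S + W c`.  Because every design matrix
#' is scaled to unit sample variance, each component's expected contribution
#' to the sample phenotypic variance equals its requested magnitude.
#'
#' @param params Scenario on the percent scale (from [sge_scenario()]) or a
#'   named vector of sample-variance-scale components (`s2_AD`, `s_ADS`, ...).
#' @param design A [sge_design()] object.
#' @param X,b Optional fixed-effect matrix and coefficients (default: none,
#'   mean zero).
#' @param n_reps Number of replicate phenotype vectors.
#' @param seed Integer seed.
#' @return `n x n_reps` matrix of phenotypes (rownames = ids).
#' @export
simulate_phenotype <- function(params, design, X = NULL, b = NULL,
                               n_reps = 1, seed = 1) {
  stopifnot(inherits(design, "sgemix_design"))
  vc <- if ("rho_ADS" %in% names(params)) scenario_components(params) else {
    out <- c(s2_AD = 0, s_ADS = 0, s2_AS = 0, s2_ED = 0, s_EDS = 0, s2_ES = 0, s2_C = 0)
    out[names(params)] <- params
    out
  }
  if (any(vc[c("s2_AD", "s2_AS", "s2_ED", "s2_ES", "s2_C")] < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  rho_g <- if (vc["s2_AD"] > 0 && vc["s2_AS"] > 0) {
    vc["s_ADS"] / sqrt(vc["s2_AD"] * vc["s2_AS"])
  } else if (vc["s_ADS"] != 0) Inf else 0
  rho_e <- if (vc["s2_ED"] > 0 && vc["s2_ES"] > 0) {
    vc["s_EDS"] / sqrt(vc["s2_ED"] * vc["s2_ES"])
  } else if (vc["s_EDS"] != 0) Inf else 0
  if (abs(rho_g) > 1 || abs(rho_e) > 1) {
    stop("requested correlation exceeds 1 in magnitude: joint covariance indefinite",
         call. = FALSE)
  }
  sc <- design$scaled
  n <- length(design$ids)
  Z <- design$cages$Z
  W <- design$cages$W
  ## 2x2 Kronecker factors (H2 is the geometric mean of the H1/H3 scalings,
  ## so the 2n genetic covariance is exactly Kg (x) H)
  Kg <- matrix(c(vc["s2_AD"] / sc$s_H,
                 vc["s_ADS"] / sqrt(sc$s_H * sc$s_ZHZ),
                 vc["s_ADS"] / sqrt(sc$s_H * sc$s_ZHZ),
                 vc["s2_AS"] / sc$s_ZHZ), 2, 2)
  Ke <- matrix(c(vc["s2_ED"],
                 vc["s_EDS"] / sqrt(sc$s_ZIZ),
                 vc["s_EDS"] / sqrt(sc$s_ZIZ),
                 vc["s2_ES"] / sc$s_ZIZ), 2, 2)
  Lh <- t(chol(design$H + diag(1e-8, n)))
  ## exactly-zero blocks draw nothing (so zero components give y = X b exactly)
  Lg <- if (all(Kg == 0)) Kg else t(chol(Kg + diag(1e-12, 2)))
  Le <- if (all(Ke == 0)) Ke else t(chol(Ke + diag(1e-12, 2)))
  sd_c <- sqrt(vc["s2_C"] / sc$s_WIW)
  mu <- if (!is.null(X) && !is.null(b)) as.numeric(X %*% b) else numeric(n)
  withr::with_seed(seed, {
    Y <- matrix(0, n, n_reps, dimnames = list(design$ids, NULL))
    for (r in seq_len(n_reps)) {
      Ag <- Lh %*% matrix(stats::rnorm(2 * n), n, 2) %*% t(Lg)
      Ee <- matrix(stats::rnorm(2 * n), n, 2) %*% t(Le)
      cg <- stats::rnorm(ncol(W), sd = sd_c)
      Y[, r] <- mu + Ag[, 1] + Z %*% Ag[, 2] + Ee[, 1] + Z %*% Ee[, 2] + W %*% cg
    }
    Y
  })
}

#' Simulate the paired two-inbred-strain experiment
#'
#' Generates cages of two mice each in three groups (both B6, mixed, both D2)
#' with phenotypes from the fixed-effect model
#' `y = bD * Xf + bS * Xcm + bDS * Xf * Xcm + e`, strain coded 0 (B6) /
#' 1 (D2), and within-cage exchangeable residual correlation `rho`.
#'
#' @param beta_D,beta_S,beta_DS Fixed-effect sizes (direct, social,
#'   interaction).
#' @param rho Within-cage residual correlation, in `[-1, 1]`.
#' @param sigma2_E Residual variance.
#' @param n_bb,n_bd,n_dd Cage counts per group.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `cage`, `strain` (0/1), `cagemate_strain`
#'   (0/1), `y`.
#' @export
simulate_inbred_experiment <- function(beta_D = 0, beta_S = 0, beta_DS = 0,
                                       rho = 0, sigma2_E = 1,
                                       n_bb = 14, n_bd = 16, n_dd = 13,
                                       seed = 1) {
  if (abs(rho) > 1) stop("|rho| must not exceed 1", call. = FALSE)
  stopifnot(sigma2_E > 0, n_bb >= 1, n_bd >= 1, n_dd >= 1)
  groups <- c(rep("BB", n_bb), rep("BD", n_bd), rep("DD", n_dd))
  withr::with_seed(seed, {
    L <- t(chol(sigma2_E * matrix(c(1, rho, rho, 1), 2, 2)))
    rows <- lapply(seq_along(groups), function(i) {
      s <- switch(groups[i], BB = c(0, 0), BD = c(0, 1), DD = c(1, 1))
      e <- as.numeric(L %*% stats::rnorm(2))
      y <- beta_D * s + beta_S * rev(s) + beta_DS * s * rev(s) + e
      tibble::tibble(
        id = sprintf("m%03d_%d", i, 1:2),
        cage = sprintf("c%03d", i),
        strain = s,
        cagemate_strain = rev(s),
        y = y
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Build the reference synthetic SGE study
#'
#' Convenience wrapper: simulates a three-generation population whose last
#' generation holds 200 full-sib families of 3 (2,000 loci), assigns cages of 3 with sibling-cohousing weight 0.5, builds
#' the pedigree A, genomic G, blended G* (mean-matching constants) over a
#' genotyped subset (default 80% of study mice), the single-step H, and
#' returns the ready-to-fit [sge_design()].
#'
#' @param n_families,family_size,n_loci,generations,cage_size,cohousing_weight,genotyped_fraction
#'   Population and housing parameters (defaults are the package's reference
#'   study conditions; three generations give the graded relatedness --
#'   full sibs, cousins, remoter kin -- seen in a closed breeding colony).
#' @param seed Integer seed.
#' @return List of class `sgemix_study`: `population`, `cages`, `A`, `H`,
#'   `design`, `genotyped_ids`.
#' @export
simulate_sge_study <- function(n_families = 200, family_size = 3, n_loci = 2000,
                               generations = 3, cage_size = 3,
                               cohousing_weight = 0.5,
                               genotyped_fraction = 0.8, seed = 1) {
  pop <- simulate_population(n_families = n_families, family_size = family_size,
                             n_loci = n_loci, generations = generations,
                             seed = seed)
  cages <- assign_cages(pop$study_ids, pop$family, cage_size = cage_size,
                        weight = cohousing_weight, seed = seed + 1L)
  A <- pedigree_A(pop$pedigree)
  gt <- withr::with_seed(seed + 2L, {
    sort(sample(pop$study_ids, round(genotyped_fraction * length(pop$study_ids))))
  })
  H <- if (length(gt) > 0) {
    dos <- pop$genotypes$dosage[gt, , drop = FALSE]
    G <- genomic_G(dos)
    Agg <- subset_square(A, gt)
    Gs <- blend_G(G, Agg, method = "match")
    build_H(A, Gs, gt)
  } else A
  design <- sge_design(subset_square(H, pop$study_ids), cages)
  structure(
    list(population = pop, cages = cages, A = A, H = H, design = design,
         genotyped_ids = gt),
    class = "sgemix_study"
  )
}

#' @export
print.sgemix_study <- function(x, ...) {
  cat(sprintf("<sgemix_study: %d study mice, %d cages, %d genotyped>\n",
              length(x$population$study_ids), length(x$design$cages$sizes),
              length(x$genotyped_ids)))
  invisible(x)
}
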