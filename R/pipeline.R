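#' Run a multi-trait SGE scan from a configuration
#'
#' File-based front end to [sge_scan()]: validates a run configuration
#' (a YAML file path or an equivalent named list), reads the phenotype, cage
#' and relatedness tables, fits every trait, applies multiple-testing
#' correction across the scanned traits, and (optionally) writes the result
#' table (TSV) and a JSON run manifest recording the package version, config
#' hash, seed and per-trait status.
#'
#' Config fields: `phenotypes` (TSV: `id` + one column per trait),
#' `cages` (TSV: `id`, `cage`), `relatedness` (TSV matrix from
#' [write_relatedness()]), optional `covariates` (named list:
#' trait -> character vector of phenotype-table columns to use as fixed
#' effects), optional `out` (output directory), optional `seed`.
#'
#' @param config Path to a YAML file or a named list.
#' @return The [sge_scan()] tibble; the run manifest is attached as
#'   attribute `manifest`.
#' @export
run_scan <- function(config) {
  cfg <- load_config(config)
  for (f in c("phenotypes", "cages", "relatedness")) {
    if (is.null(cfg[[f]])) stop("config is missing field: ", f, call. = FALSE)
    if (!file.exists(cfg[[f]])) stop("input not found: ", cfg[[f]], call. = FALSE)
  }
  phen <- readr::read_tsv(cfg$phenotypes, col_types = readr::cols(id = readr::col_character(),
                                                                  .default = readr::col_double()),
                          progress = FALSE)
  if (ncol(phen) < 2) stop("phenotype table has no trait columns", call. = FALSE)
  cages <- read_cages(cfg$cages)
  H <- read_relatedness(cfg$relatedness)
  design <- sge_design(H, cages)
  cov_cols <- cfg$covariates %||% list()
  trait_names <- setdiff(names(phen), "id")
  covariates <- NULL
  if (length(cov_cols)) {
    ord <- match(design$ids, phen$id)
    covariates <- lapply(cov_cols, function(cols) {
      cbind(`(Intercept)` = 1, as.matrix(phen[ord, cols, drop = FALSE]))
    })
    trait_names <- setdiff(trait_names, unique(unlist(cov_cols)))
  }
  scan <- sge_scan(phen[, c("id", trait_names)], design, covariates = covariates)
  manifest <- c(
    attr(scan, "manifest"),
    list(
      package_version = as.character(utils::packageVersion("sgemix")),
      config_hash = config_hash(cfg),
      seed = cfg$seed %||% NA
    )
  )
  attr(scan, "manifest") <- manifest
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(scan, file.path(cfg$out, "sge_scan.tsv"))
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  scan
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a YAML path or a named list", call. = FALSE)
  }
}

## order-stable hash of the configuration values
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, force = TRUE)
  ## small polynomial rolling hash (stays within exact double integers)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Heritability-bias study under misspecified models
#'
#' Reproduces the package's simulation-based bias analysis: phenotypes are
#' drawn from the full model under a chosen scenario, then each replicate is
#' analysed with (i) a DGE-only model, (ii) a DGE + cage model and (iii) the
#' full model with SGE.  The output holds, per replicate and model, the
#' estimated minus simulated DGE (and SGE, where estimated) proportions of
#' phenotypic variance.  When cage mates are relatives and the DGE-SGE
#' covariance is positive, ignoring SGE inflates DGE estimates (and deflates
#' them when the covariance is negative).
#'
#' @param scenario A scenario name for [sge_scenario()], or a scenario
#'   parameter vector (percent scale).
#' @param study A [simulate_sge_study()] object (built with defaults from
#'   `seed` when `NULL`).
#' @param n_reps Number of simulation replicates.
#' @param seed Integer seed.
#' @param models Models to fit per replicate.
#' @return Tibble of class `sge_bias`: `rep`, `model`, `dge_pct`, `sge_pct`,
#'   `dge_bias`, `sge_bias`, `converged`; generating values as attribute
#'   `scenario`.
#' @export
run_bias_study <- function(scenario = "average", study = NULL, n_reps = 100,
                           seed = 1,
                           models = c("dge_only", "dge_cage", "full")) {
  scn <- if (is.character(scenario)) sge_scenario(scenario) else scenario
  if (is.null(study)) study <- simulate_sge_study(seed = seed)
  design <- study$design
  Y <- simulate_phenotype(scn, design, n_reps = n_reps, seed = seed + 1000L)
  rows <- list()
  for (r in seq_len(n_reps)) {
    y <- Y[, r]
    for (m in models) {
      fit <- fit_sge(y, design = design, model = m)
      vp <- variance_partition(fit)
      dge <- vp$proportion_pct[vp$component == "s2_AD"]
      sge <- if (m == "full") vp$proportion_pct[vp$component == "s2_AS"] else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = r, model = m,
        dge_pct = dge, sge_pct = sge,
        dge_bias = dge - unname(scn["s2_AD"]),
        sge_bias = sge - unname(scn["s2_AS"]),
        converged = fit$converged
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario") <- scn
  class(out) <- c("sge_bias", class(out))
  out
}
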