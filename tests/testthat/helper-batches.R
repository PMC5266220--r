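# heavy shared simulation batches for the acceptance-style tests, computed
# once per test run and cached across test blocks

.batch_cache <- new.env(parent = emptyenv())

reference_study <- function() {
  if (is.null(.batch_cache$study)) {
    .batch_cache$study <- suppressMessages(simulate_sge_study(seed = 20260929))
  }
  .batch_cache$study
}

## 100 full-model REML fits on phenotypes drawn under a named scenario from
## the reference 600-mouse study
recovery_batch <- function(scenario, n_reps = 100) {
  key <- paste0("batch_", scenario)
  if (is.null(.batch_cache[[key]])) {
    design <- reference_study()$design
    scn <- sge_scenario(scenario)
    Y <- simulate_phenotype(scn, design, n_reps = n_reps,
                            seed = 1000 + match(scenario, c("average", "high-sge")))
    fits <- lapply(seq_len(n_reps), function(r) {
      suppressMessages(fit_sge(Y[, r], design = design, model = "full"))
    })
    .batch_cache[[key]] <- list(Y = Y, fits = fits, scn = scn)
  }
  .batch_cache[[key]]
}
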