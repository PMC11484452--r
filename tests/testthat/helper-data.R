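# Shared fixtures, built in code and cached across test files.

.evcargo_cache <- new.env(parent = emptyenv())

# One full default-scenario dataset, reused wherever a realistic paired
# dataset is needed.
get_sim <- function() {
  if (is.null(.evcargo_cache$sim))
    .evcargo_cache$sim <- simulate_dataset(default_scenario())
  .evcargo_cache$sim
}

# A cheap degenerate configuration (no planted MEGs, everything maintained):
# the share calibration is skipped, so it runs in milliseconds. Used for
# pure-mechanics tests (determinism, conservation, formats).
degenerate_cfg <- function(seed = 11L, n_genes = 3000L, ...) {
  sim_config(n_genes = n_genes, n_meg_shared = 0L, n_meg_breed_specific = 0L,
             maintain_prob = c(Top100 = 1, Mid = 1, Other = 1),
             seed = seed, ...)
}

sim_degenerate <- function(seed = 11L, ...) {
  suppressWarnings(simulate_dataset(degenerate_cfg(seed = seed, ...)))
}

# One end-to-end analysis of a fresh default-scenario replicate: the
# quantities the recovery studies look at, computed by the pipeline's own
# functions.
run_scenario_once <- function(seed) {
  cfg <- default_scenario(seed = seed)
  sim <- simulate_dataset(cfg)
  fpkm <- compute_fpkm(sim$counts, sim$annotation)
  filt <- filter_low_expression(fpkm)
  sdf <- as.data.frame(sim$samples)
  ms <- sdf$sample_id[sdf$compartment == "muscle"]
  es <- sdf$sample_id[sdf$compartment == "MEV"]
  classes <- assign_rank_classes(filt$expr[, ms, drop = FALSE])
  mf <- maintained_fractions(filt$expr[, ms, drop = FALSE],
                             filt$expr[, es, drop = FALSE],
                             sim$samples, classes)
  shares <- cumulative_share(filt$expr, 1000L, sim$samples)
  de <- meg_de(sim$counts, sim$samples, "Global", genes = rownames(filt$expr))
  catalog <- call_megs(de)
  rel <- delta_delta_ct(sim$qpcr)
  conc <- lapply(c(muscle = "muscle", MEV = "MEV"), function(cp)
    validate_concordance(rel, fpkm, sim$panel, sim$samples, cp))
  list(class_means = tapply(mf$fraction_maintained, mf$class, mean),
       comp_means = attr(shares, "compartment_means"),
       rank_summary = mf,
       catalog = catalog,
       planted_shared = sim$truth$meg_shared,
       planted_all = unique(c(sim$truth$meg_shared,
                              unlist(sim$truth$meg_specific))),
       concordance = conc)
}

# Ten independent default-scenario replicates (fixed seed set), cached.
get_recovery_runs <- function() {
  if (is.null(.evcargo_cache$recovery))
    .evcargo_cache$recovery <-
      lapply(1:10, function(i) run_scenario_once(5000L + i))
  .evcargo_cache$recovery
}

# Small deterministic count matrix for DE mechanics.
toy_counts <- function(n_genes = 50L, n_per_group = 2L, mu = 100,
                       alpha = 0.05, seed = 1L, fold = 1) {
  with_seed(seed, {
    n <- n_genes
    muv <- rep(mu, n)
    cols <- c(replicate(n_per_group, rnbinom(n, mu = muv, size = 1 / alpha)),
              replicate(n_per_group, rnbinom(n, mu = muv * fold,
                                             size = 1 / alpha)))
    m <- matrix(cols, nrow = n,
                dimnames = list(sprintf("g%03d", seq_len(n)),
                                paste0("s", seq_len(2 * n_per_group))))
    m
  })
}
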