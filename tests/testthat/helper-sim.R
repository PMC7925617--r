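# Shared simulated fixtures. The default study design (5000 genes, 6 lines,
# 5 replicates) is expensive enough that tests needing it share one cached
# analysis per seed.

.sim_cache <- new.env(parent = emptyenv())

default_analysis <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- sim_config(seed = seed)
  sim <- simulate_counts(cfg)
  de <- de_all_lines(sim$counts, c(cfg$wt_line, cfg$gof_lines))
  part <- partition_genes(lapply(de, `[[`, "calls"), cfg$wt_line, cfg$gof_lines)
  res <- list(cfg = cfg, sim = sim, de = de, part = part)
  .sim_cache[[key]] <- res
  res
}

# Scaled-down study design (~1/4 program sizes) for fast unit tests.
small_config <- function(n_genes = 400, seed = 1, ...) {
  args <- list(...)
  if (is.null(args$program_sizes)) {
    args$program_sizes <- list(
      common_up = 12, gof_shared_up = 10,
      private_up = c(R274W = 4, R321S = 3, T419R = 12, N574I = 8),
      mixed_up = 8, wt_only_up = 1,
      down = c(WT = 1, R274W = 3, R321S = 3, T419R = 12, N574I = 5),
      baseline_up = c(T419R = 1, N574I = 6),
      baseline_down = c(T419R = 4, N574I = 12)
    )
  }
  do.call(sim_config, c(list(n_genes = n_genes, seed = seed), args))
}

null_config <- function(seed, n_genes = 2000) {
  builder <- if (n_genes < 500) small_config else sim_config
  builder(
    n_genes = n_genes, seed = seed,
    effect_sizes = list(common = 1, gof_shared = 1, private = 1, mixed = 1,
                        wt_only = 1, down = 1,
                        baseline_up = c(T419R = 1, N574I = 1),
                        baseline_down = c(T419R = 1, N574I = 1)),
    gof_amplification = 1
  )
}
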