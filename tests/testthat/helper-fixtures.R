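# Shared fixtures. Reduced-scale simulation settings keep the suite fast;
# the methods vignette documents the problem sizes. Expensive grids are
# built once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

# small population template used throughout the reduced-scale checks
small_template <- function(...) {
  sim_params(n_cells_init = 200L, ...)
}

# inference grid: h0 0..1 step 0.1, fitness 0..2 step 0.1 (the package's
# default fitness spacing; a coarser fitness grid quantises the kNN
# averages), 5 reps at 200 founding cells
inference_grid <- function() {
  if (is.null(.fixture_env$inference_grid)) {
    .fixture_env$inference_grid <- build_suppressivity_grid(
      seq(0, 1, by = 0.1), seq(0, 2, by = 0.1), reps = 5,
      template = small_template(), master_seed = 101
    )
  }
  .fixture_env$inference_grid
}

# 25-strain recovery panel at known fitness values, 100-colony assay noise
recovery_panel <- function(seed = 202) {
  cfg <- synth_config(
    seed = seed,
    panel_fitness = rep(c(0.8, 1, 1.2, 1.4, 1.6), each = 5),
    panel_copy_numbers = seq(25, 150, length.out = 25),
    assay_colonies = 100
  )
  gen_strain_panel(cfg, small_template())
}

panel_to_obs <- function(panel) {
  data.frame(strain_id = panel$strain_id, h0 = panel$h0,
             suppressivity = panel$suppressivity_pct / 100)
}

# empirical distribution of one daughter's mutant count over many
# divisions (vectorised internal division path, the same code
# run_simulation uses)
daughter_mut_distribution <- function(w, m, f, n, mode, n_draws,
                                      seed = 1) {
  set.seed(seed)
  d <- rhodrift:::.divide_counts(rep(w, n_draws), rep(m, n_draws),
                                 f, n, mode)
  tabulate(d[[1]] + 1L, nbins = n + 1) / n_draws
}
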