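# The benchmark-task grid used by the statistical acceptance checks: the
# full 4-rule x 3-topology x 10-seed study at the package's default reduced
# problem size. Computed once per test session and shared across test blocks.
.grid_cache <- new.env(parent = emptyenv())

benchmark_grid <- function() {
  if (is.null(.grid_cache$grid)) {
    cfg <- experiment_config(task = "benchmark", master_seed = 1L)
    .grid_cache$grid <- run_grid(cfg)
  }
  .grid_cache$grid
}
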