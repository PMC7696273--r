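# Shared setup for the numbered analysis drivers. Volumetric intermediates
# go under scratch/ (large, regenerable); tables and JSON summaries are
# copied to results/tables by each driver.

library(resifc)

analysis_config <- function() {
  default_config(rng_seed = 20260924L,
                 n_ms = 26L, n_hc = 14L,
                 grid_dim = c(24L, 16L, 22L),   # compact seed-covering grid
                 drift_order = 3L,
                 voxel_p = 0.001, alpha = 0.05, n_sims = 1000L,
                 connectivity = "faces")
}

pipeline_dir <- "scratch/pipeline"
tables_dir <- "results/tables"

collect_tables <- function(patterns) {
  dir.create(tables_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in patterns) {
    for (f in list.files(pipeline_dir, pattern = p, full.names = TRUE))
      file.copy(f, file.path(tables_dir, basename(f)), overwrite = TRUE)
  }
}
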