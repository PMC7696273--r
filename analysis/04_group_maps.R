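#!/usr/bin/env Rscript
# Group inference: per seed and per group, voxelwise mixed-effects model
# z ~ condition * centered-VAS-F + run with a random subject intercept.
# The reported map is the condition-by-fatigue interaction (2-back minus
# 0-back fatigue slope), converted to signed Z.

source("analysis/00_setup.R")

cfg <- analysis_config()
run_pipeline(cfg, "group", out_dir = pipeline_dir)

grid <- study_grid(cfg$grid_dim)
cat("\n--- group interaction maps (peak |Z| per seed x group) ---\n")
for (sn in default_seeds()$name) {
  for (g in c("MS", "HC")) {
    z <- read_volume(file.path(pipeline_dir,
           sprintf("group_z_seed-%s_%s.nii.gz", sn, g)))$data
    pk <- which.max(abs(z))
    mm <- voxel_to_mm(grid, arrayInd(pk, grid$dim))
    cat(sprintf("%-9s %-3s peak Z %+6.2f at (%5.1f, %5.1f, %5.1f) mm\n",
                sn, g, z[pk], mm[1], mm[2], mm[3]))
  }
}

collect_tables(c("^group_sidecar"))
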