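#!/usr/bin/env Rscript
# Cluster-extent correction: Monte-Carlo calibration of the extent
# threshold at voxel p < 0.001 from the estimated residual smoothness,
# then per-seed, per-group cluster tables (peak mm coordinates, voxel
# count, signed Z).

source("analysis/00_setup.R")

cfg <- analysis_config()
run_pipeline(cfg, "clusters", out_dir = pipeline_dir)

thr <- jsonlite::fromJSON(file.path(pipeline_dir, "cluster_threshold.json"))
cat("\n--- cluster correction ---\n")
cat(sprintf("extent threshold k = %d voxels (voxel p < %g, corrected alpha %g, %d null sims, FWHM %.2f mm)\n",
            thr$k, thr$voxel_p, thr$alpha, thr$n_sims, thr$fwhm_mm))
for (sn in default_seeds()$name) {
  for (g in c("MS", "HC")) {
    tab <- read_table_tsv(file.path(pipeline_dir,
             sprintf("clusters_seed-%s_%s.tsv", sn, g)))
    cat(sprintf("%-9s %-3s: %d significant cluster(s)\n", sn, g, nrow(tab)))
    if (nrow(tab)) print(tab)
  }
}

collect_tables(c("^cluster_threshold", "^clusters_seed-"))
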