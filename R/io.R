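#' Write a volume to NIfTI-1
#'
#' Data, affine (sform/qform, code 2) and TR survive a round trip
#' bit-exactly (double datatype).
#'
#' @param data 3-D or 4-D array, or an `fc_bold`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid An [fc_grid()] supplying affine and TR (ignored for
#'   `fc_bold`, which carries its own).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, grid = NULL) {
  if (inherits(data, "fc_bold")) {
    grid <- data$grid
    data <- data$data
  }
  if (is.null(grid)) abort_arg("grid required")
  img <- RNifti::asNifti(data, datatype = "double")
  aff <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  hdr_pixdim <- c(1, rep(grid$voxel_mm, 3), grid$tr, 0, 0, 0)
  img$pixdim <- hdr_pixdim
  img$xyzt_units <- 10L  # mm + s
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @return List: `data` (array), `affine` (4x4), `tr` (s).
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_arg("malformed NIfTI at ", path,
                                                ": ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  list(data = array(as.vector(img), dim(img)),
       affine = unclass(RNifti::xform(img))[1:4, 1:4],
       tr = hdr$pixdim[5])
}

#' Write a TSV table
#'
#' Tab-separated, header row, full floating-point precision.
#' @param table data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 0)
  invisible(path)
}

#' Read a TSV table
#'
#' Ragged rows are a format error (reported with the line number by the
#' reader).
#' @param path File path.
#' @return data.frame with columns in file order.
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  fill = FALSE, data.table = FALSE))
}

#' Default pipeline configuration
#'
#' All knobs of the simulation + analysis pipeline in one JSON-serializable
#' list: seed, cohort sizes, grid, plant, model options. `grid_dim` below
#' the full 30 x 36 x 30 default keeps desk-scale demonstrations fast; the
#' geometry always uses 3 mm voxels with the seed-covering origin.
#'
#' @param rng_seed Master seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_ms,n_hc Cohort sizes.
#' @param grid_dim Grid dimensions.
#' @param drift_order Drift polynomial order in the first-level model.
#' @param voxel_p,alpha,n_sims,connectivity Cluster-correction settings.
#' @param plant Plant parameters as a named list (see [plant_spec()]);
#'   regions are defined at run time from `plant_seed_name` and a target
#'   block offset.
#' @param plant_seed_name Which seed's region receives the planted
#'   coupling.
#' @export
default_config <- function(rng_seed = 1L, n_ms = 26L, n_hc = 14L,
                           grid_dim = c(30L, 36L, 30L), drift_order = 3L,
                           voxel_p = 0.001, alpha = 0.05, n_sims = 1000L,
                           connectivity = "faces",
                           plant = list(coupling_intercept = 0.1,
                                        coupling_slope_2back = 0.3,
                                        coupling_slope_0back = 0,
                                        noise_sd = 0.6, task_amplitude = 2,
                                        smoothing_fwhm = 6),
                           plant_seed_name = "DLPFC") {
  cfg <- list(rng_seed = as.integer(rng_seed), n_ms = as.integer(n_ms),
              n_hc = as.integer(n_hc), grid_dim = as.integer(grid_dim),
              drift_order = as.integer(drift_order), voxel_p = voxel_p,
              alpha = alpha, n_sims = as.integer(n_sims),
              connectivity = connectivity, plant = plant,
              plant_seed_name = plant_seed_name)
  cfg$config_hash <- config_hash(cfg)
  cfg
}

#' @rdname default_config
#' @param config A configuration list (without its hash field).
#' @export
config_hash <- function(config) {
  config$config_hash <- NULL
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

#' Read/write a pipeline configuration as JSON
#' @param config Configuration list.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$grid_dim <- as.integer(cfg$grid_dim)
  stored <- cfg$config_hash
  if (!is.null(stored) && !identical(stored, config_hash(cfg)))
    abort_arg("config hash mismatch: file was edited after generation")
  cfg
}

#' Run the simulation + analysis pipeline
#'
#' Stages run in dependency order and exchange artifacts through
#' `out_dir`; every artifact set carries the config hash, and a stage
#' refuses inputs produced under a different configuration. BOLD volumes
#' are a pure function of the configuration, so the heavy stages
#' regenerate them deterministically instead of storing hundreds of runs;
#' `first-level` writes one subject's residual volume for audit.
#'
#' Stages: `simulate` (cohort, schedules, events, ratings, behavior,
#' confounds tables), `first-level` (audit residual NIfTI + design TSV),
#' `connectivity` (per subject x condition x run x seed Fisher-z maps,
#' stored as one matrix per seed with a manifest), `behavior` (run-level
#' fatigue, Box-Cox, mixed models, Tukey contrasts), `group` (per seed x
#' group voxelwise interaction maps), `clusters` (Monte-Carlo extent
#' calibration + cluster tables), `all`.
#'
#' @param config See [default_config()].
#' @param stage Stage name.
#' @param out_dir Artifact directory.
#' @return Invisible list of artifact paths written by the stage(s).
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("all", "simulate", "first-level",
                                   "connectivity", "behavior", "group",
                                   "clusters"),
                         out_dir = "results/pipeline") {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    for (s in c("simulate", "first-level", "connectivity", "behavior",
                "group", "clusters"))
      run_pipeline(config, s, out_dir)
    return(invisible(list.files(out_dir, recursive = TRUE)))
  }
  switch(stage,
         "simulate" = stage_simulate(config, out_dir),
         "first-level" = stage_first_level(config, out_dir),
         "connectivity" = stage_connectivity(config, out_dir),
         "behavior" = stage_behavior(config, out_dir),
         "group" = stage_group(config, out_dir),
         "clusters" = stage_clusters(config, out_dir))
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    abort_arg("missing artifact ", path, "; run stage '", produced_by,
              "' first")
  path
}

check_hash <- function(dir, config) {
  p <- file.path(dir, "config.json")
  if (file.exists(p)) {
    old <- read_config(p)
    if (!identical(old$config_hash, config$config_hash))
      abort_arg("artifacts in ", dir, " were produced under a different ",
                "config (hash ", old$config_hash, " vs ",
                config$config_hash, "); refusing to mix")
  }
}
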