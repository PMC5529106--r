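#' Quantify oligomer uptake in one stack
#'
#' End-to-end analysis of a single field: binarize the neuron-marker
#' channel plane by plane, label neuron instances, detect 3-D spots in the
#' raw oligomer channel, classify them by axial overlap with the mask,
#' assign them to neurons, and summarize. The ImageJ-style particle count of
#' the mask-multiplied oligomer channel's maximum-intensity projection is
#' reported alongside (`mip_particle_count`): spots merging in the
#' projection make it a lower bound on the 3-D count.
#'
#' @param stack An [image_stack()] with `neuron_marker` and `oligomer` roles.
#' @param cfg An [analysis_config()].
#' @param binarize_method Threshold for the marker channel (see
#'   [binarize_marker()]).
#' @param min_volume_um3 Minimum neuron volume for [label_neurons()].
#' @param field_id Identifier copied into the summary row.
#' @param mean_over Passed to [summarize_field()].
#' @return List with `spots` (classified, assigned tibble), `summary`
#'   (one-row tibble including `mip_particle_count`), `mask`, `labels`.
#' @export
quantify_stack <- function(stack, cfg = analysis_config(),
                           binarize_method = "otsu", min_volume_um3 = 50,
                           field_id = 1L,
                           mean_over = c("internalizing", "all")) {
  mean_over <- match.arg(mean_over)
  mask <- binarize_marker(stack, method = binarize_method)
  nuclei <- if (!is.null(stack$channels) && "nucleus" %in% stack$channels$role) {
    nuc_chan <- get_channel(stack, "nucleus")
    thr <- compute_threshold(as.vector(nuc_chan), "otsu")
    binary_mask(array(as.integer(nuc_chan > thr), dim(nuc_chan)),
                stack$spacing, source = "nucleus")
  }
  labels <- label_neurons(mask, nuclei = nuclei, min_volume = min_volume_um3)
  spots <- detect_spots(stack, cfg = cfg)
  spots <- classify_spots(spots, mask, cfg = cfg)
  spots <- assign_spots(spots, labels, proximity_um = cfg$proximity_um)
  summary <- summarize_field(spots, labels, field_id = field_id,
                             mean_over = mean_over)
  masked <- multiply_mask(mask, stack)
  summary$mip_particle_count <- mip_count(masked, cfg = cfg)
  list(spots = spots, summary = summary, mask = mask, labels = labels)
}

default_pipeline_config <- function() {
  list(
    roles = "neuron_marker=0,oligomer=1",
    binarize = list(method = "otsu"),
    label = list(min_volume_um3 = 50),
    analysis = list(min_xy_area = 2e-4, min_z_height = 1.5,
                    overlap_internalized = 0.65, overlap_attached_max = 0.30,
                    proximity_um = 0.2, spot_threshold = "otsu",
                    connectivity = 26, overlap_metric = "axial"),
    summary = list(mean_over = "internalizing"),
    simulation = list(),
    n_fields = 1,
    seed = 1
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown top-level keys are rejected. Missing keys fall back to defaults.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  base <- default_pipeline_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "oligouptake_validation_error")
  }
  modifyList(base, user)
}

analysis_config_from <- function(cfg) {
  do.call(analysis_config, cfg$analysis)
}

simulation_config_from <- function(cfg) {
  sim <- cfg$simulation
  if (!is.null(sim$spacing)) sim$spacing <- do.call(voxel_spacing, as.list(sim$spacing))
  if (is.null(sim$seed)) sim$seed <- cfg$seed
  do.call(simulation_config, sim)
}

write_manifest <- function(files, out_dir, config_checksum) {
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    config_md5 = config_checksum,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

config_checksum <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate fields to disk
#'
#' Writes one OME-TIFF stack plus one truth CSV per field, and a manifest
#' with per-file checksums and the configuration checksum.
#'
#' @param config A config list from [read_pipeline_config()] (its
#'   `simulation`, `n_fields` and `seed` entries are used) or a path to a
#'   YAML file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config() else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- simulation_config_from(cfg)
  files <- character()
  for (i in seq_len(cfg$n_fields)) {
    sim_cfg$seed <- as.integer(cfg$seed) + i - 1L
    field <- simulate_field(sim_cfg)
    stack_path <- file.path(out_dir, sprintf("field_%03d.ome.tif", i))
    write_stack(field$stack, stack_path)
    truth_path <- file.path(out_dir, sprintf("field_%03d_truth.csv", i))
    utils::write.csv(field$truth, truth_path, row.names = FALSE)
    files <- c(files, stack_path, paste0(stack_path, ".ome.xml"), truth_path)
  }
  manifest <- write_manifest(files, out_dir, config_checksum(cfg))
  invisible(manifest)
}

#' Quantify a set of stacks to CSV tables
#'
#' Processes every stack, writing one spot CSV per stack and a combined
#' field-summary CSV. A stack that fails to read or quantify is reported and
#' skipped; the function then signals a warning-level condition and marks
#' the run failed in its return value, so callers (and the CLI) can exit
#' non-zero while keeping the valid results.
#'
#' @param paths Character vector of stack paths.
#' @param config Config list or YAML path (roles, thresholds, summary unit).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `summary` (tibble), `failed` (character
#'   vector of paths that could not be processed), `summary_path`.
#' @export
run_quantify <- function(paths, config = NULL, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config() else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acfg <- analysis_config_from(cfg)
  summaries <- list()
  failed <- character()
  files <- character()
  for (i in seq_along(paths)) {
    res <- tryCatch({
      stack <- read_stack(paths[i], roles = cfg$roles)
      quantify_stack(stack, cfg = acfg,
                     binarize_method = cfg$binarize$method,
                     min_volume_um3 = cfg$label$min_volume_um3,
                     field_id = tools::file_path_sans_ext(basename(paths[i])),
                     mean_over = cfg$summary$mean_over)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("FAILED %s: %s", paths[i], conditionMessage(res)))
      failed <- c(failed, paths[i])
      next
    }
    spot_path <- file.path(out_dir, sprintf(
      "%s_spots.csv", tools::file_path_sans_ext(basename(paths[i]))))
    utils::write.csv(
      dplyr::select(res$spots, -dplyr::any_of("voxels")),
      spot_path, row.names = FALSE)
    files <- c(files, spot_path)
    summaries[[length(summaries) + 1L]] <- res$summary
  }
  summary <- if (length(summaries)) dplyr::bind_rows(summaries) else {
    dplyr::mutate(summarize_field(empty_spot_table(), 1L)[0, ],
                  mip_particle_count = integer())
  }
  summary_path <- file.path(out_dir, "field_summary.csv")
  utils::write.csv(summary, summary_path, row.names = FALSE)
  write_manifest(c(files, summary_path), out_dir, config_checksum(cfg))
  if (length(failed)) {
    warn(sprintf("%d of %d stacks failed to process", length(failed),
                 length(paths)))
  }
  invisible(list(summary = summary, failed = failed,
                 summary_path = summary_path))
}

#' Compare uptake metrics between groups of a field-summary CSV
#'
#' @param summary_csv Path to a field-summary CSV (from [run_quantify()])
#'   carrying a grouping column.
#' @param group_col Grouping column name.
#' @param reference Reference group label.
#' @param out_json Optional path for a JSON report (means, SEM, t, df, p,
#'   percent reduction per metric, plus the thresholds used).
#' @param config Config list or YAML path, echoed into the report.
#' @return The comparison tibble from [compare_summaries()].
#' @export
run_compare <- function(summary_csv, group_col = "group", reference = NULL,
                        out_json = NULL, config = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config() else config
  summaries <- tibble::as_tibble(utils::read.csv(summary_csv))
  groups <- unique(summaries[[group_col]])
  counts <- table(summaries[[group_col]])
  if (length(groups) < 2L || any(counts < 2L)) {
    abort("need >= 2 groups with >= 2 rows each",
          class = "oligouptake_validation_error")
  }
  cmp <- compare_summaries(summaries, group_col = group_col,
                           reference = reference)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(comparisons = cmp, thresholds = cfg$analysis,
           config_md5 = config_checksum(cfg)),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cmp
}
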