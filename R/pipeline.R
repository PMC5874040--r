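#' Run the alignment pipeline from a configuration
#'
#' Binds the modules into the published end-to-end flow. The configuration
#' (a YAML file or an equivalent nested list) selects the steps to run:
#' `simulate` entries generate synthetic bundles; `align` maps each test
#' bundle onto the reference; `quantify` adds stage-wise overlap tables.
#' Stage toggles, registration parameters and seeds all live in the config,
#' and every numeric output is reproducible from it.
#'
#' Config keys: `out_dir`; optional `simulate` (list of per-embryo specs:
#' `seed`, `temporal_offset_min`, `total_rotation_deg`, ...,
#' plus shared `grid`: `voxel_size_um`, `shape_voxels`, `fast_count`, ...);
#' `reference` (directory or index into the simulated list); `tests`
#' (directories or indices); optional `align` (fields of [align_config()]);
#' `quantify: yes/no`.
#'
#' @param config Path to a YAML file or a nested list.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `alignments` (per test embryo) and
#'   `overlaps` (if quantified); artifacts are written under `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  bundles <- list()
  if (!is.null(config$simulate)) {
    gcfg <- config$simulate$grid %||% list()
    grid <- acquisition_grid(
      voxel_size_um = gcfg$voxel_size_um %||% 0.1625,
      shape_voxels = unlist(gcfg$shape_voxels %||% c(352L, 192L, 192L)),
      slow_interval_min = gcfg$slow_interval_min %||% 10,
      fast_interval_min = gcfg$fast_interval_min %||% 2,
      slow_count = gcfg$slow_count %||% 20L,
      fast_count = gcfg$fast_count %||% 125L)
    for (em in config$simulate$embryos) {
      args <- em
      args$grid <- grid
      spec <- do.call(synthetic_embryo_spec, args)
      say("simulating embryo seed %d", spec$seed)
      b <- simulate_embryo(spec)
      bundles[[length(bundles) + 1]] <- b
      write_bundle(b, file.path(out_dir, b$embryo_id))
    }
  }

  get_bundle <- function(ref) {
    if (is.numeric(ref)) bundles[[ref]] else read_bundle(ref)
  }
  results <- list()
  overlaps <- list()
  if (!is.null(config$reference) && length(config$tests %||% list()) > 0) {
    ref <- get_bundle(config$reference)
    acfg <- do.call(align_config, config$align %||% list())
    for (tref in config$tests) {
      tb <- get_bundle(tref)
      say("aligning %s onto %s", tb$embryo_id, ref$embryo_id)
      res <- align_embryo(tb, ref, acfg)
      results[[tb$embryo_id]] <- res
      write_alignment_json(
        res, file.path(out_dir, paste0(tb$embryo_id, "_alignment.json")),
        transforms_csv = file.path(out_dir,
                                   paste0(tb$embryo_id, "_transforms.csv")))
      if (isTRUE(config$quantify)) {
        ov <- overlap_by_stage(tb, ref, res,
                               channels = config$channels %||% "fiducial")
        ov$embryo_id <- tb$embryo_id
        overlaps[[tb$embryo_id]] <- ov
      }
    }
    if (length(overlaps)) {
      readr::write_csv(dplyr::bind_rows(overlaps),
                       file.path(out_dir, "overlap_by_stage.csv"),
                       progress = FALSE)
    }
  }
  invisible(list(alignments = results,
                 overlaps = if (length(overlaps)) dplyr::bind_rows(overlaps)))
}
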