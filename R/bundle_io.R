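#' Write an embryo movie bundle to a directory
#'
#' Lays out the on-disk bundle format consumed by the command-line
#' pipeline: `counts.csv` (columns `t,time_min,count`), `nuclei.csv`
#' (the nuclei table), per-timepoint label volumes under `fiducial/` and
#' `reporter/` as multi-page TIFFs with YAML sidecars, and `bundle.yaml`
#' with grid and provenance metadata.
#'
#' @param bundle An `embryo_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- tibble::tibble(t = seq_len(nrow(bundle$counts)),
                           time_min = bundle$counts$time_min,
                           count = bundle$counts$count)
  readr::write_csv(counts, file.path(dir, "counts.csv"), progress = FALSE)
  write_nuclei_table(bundle$nuclei, file.path(dir, "nuclei.csv"))
  for (ch in c("fiducial", "reporter")) {
    if (length(bundle[[ch]]) == 0) next
    sub <- file.path(dir, ch)
    dir.create(sub, showWarnings = FALSE)
    for (nm in names(bundle[[ch]])) {
      write_label_volume(bundle[[ch]][[nm]],
                         file.path(sub, sprintf("t%04d.tif", as.integer(nm))))
    }
  }
  g <- bundle$grid
  yaml::write_yaml(list(
    embryo_id = bundle$embryo_id,
    twitch_time_min = bundle$twitch_time_min,
    grid = list(voxel_size_um = g$voxel_size_um,
                shape_voxels = as.integer(g$shape_voxels),
                slow_interval_min = g$slow_interval_min,
                fast_interval_min = g$fast_interval_min,
                slow_count = g$slow_count, fast_count = g$fast_count)),
    file.path(dir, "bundle.yaml"))
  invisible(dir)
}

#' Read an embryo movie bundle from a directory
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the same layout).
#' @return An `embryo_bundle` (without ground truth).
#' @export
read_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  grid <- acquisition_grid(
    voxel_size_um = meta$grid$voxel_size_um,
    shape_voxels = unlist(meta$grid$shape_voxels),
    slow_interval_min = meta$grid$slow_interval_min,
    fast_interval_min = meta$grid$fast_interval_min,
    slow_count = meta$grid$slow_count,
    fast_count = meta$grid$fast_count)
  counts_tab <- readr::read_csv(file.path(dir, "counts.csv"),
                                show_col_types = FALSE, progress = FALSE)
  read_channel <- function(ch) {
    sub <- file.path(dir, ch)
    if (!dir.exists(sub)) return(list())
    files <- sort(list.files(sub, pattern = "^t\\d+\\.tif$",
                             full.names = TRUE))
    vols <- lapply(files, read_label_volume, grid = grid)
    stats::setNames(vols, vapply(vols, function(v) {
      as.character(v$timepoint_index)
    }, character(1)))
  }
  structure(list(
    grid = grid,
    counts = count_series(counts_tab$time_min, counts_tab$count),
    nuclei = read_nuclei_table(file.path(dir, "nuclei.csv"), grid),
    fiducial = read_channel("fiducial"),
    reporter = read_channel("reporter"),
    twitch_time_min = meta$twitch_time_min,
    embryo_id = meta$embryo_id,
    ground_truth = NULL, spec = NULL), class = "embryo_bundle")
}

#' Serialize an alignment result to JSON
#'
#' Writes the alignment summary, per-timepoint refinement table, rotation
#' tracks and QC flags as JSON; 4x4 homogeneous per-timepoint transforms of
#' the full composition go to a CSV alongside when `transforms_csv` is
#' given.
#'
#' @param result An `alignment_result`.
#' @param path Output JSON path.
#' @param transforms_csv Optional CSV path for the per-timepoint composed
#'   transform matrices (one row per matrix entry).
#' @return `path`, invisibly.
#' @export
write_alignment_json <- function(result, path, transforms_csv = NULL) {
  obj <- list(
    summary = as.list(glance(result)),
    temporal = as.list(tidy(result$temporal)),
    scale = as.list(tidy(result$scale)),
    refinements = result$refinement_table,
    track_test = result$track_test,
    track_ref = result$track_ref,
    qc = result$qc[c("early_fail", "capped_timepoints")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(transforms_csv)) {
    rows <- lapply(seq_len(nrow(result$pairs)), function(k) {
      tp <- result$pairs$t_test[k]
      # affine 3x4 of the full composition, recovered from basis points
      base <- rbind(c(0, 0, 0), diag(3))
      img <- map_points(result, base, tp, "full")
      M <- t(img[2:4, ] - matrix(img[1, ], 3, 3, byrow = TRUE))
      tibble::tibble(t_test = tp, t_ref = result$pairs$t_ref[k],
                     row = rep(1:3, 4),
                     col = rep(1:4, each = 3),
                     value = c(as.vector(M), img[1, ]))
    })
    readr::write_csv(dplyr::bind_rows(rows), transforms_csv,
                     progress = FALSE)
  }
  invisible(path)
}
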