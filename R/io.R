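#' Per-timepoint nuclear centers from a segmenter
#'
#' A nuclei time series is a tibble with one row per segmented nucleus:
#' columns `t` (integer timepoint, contiguous from 1), `x_um`, `y_um`,
#' `z_um` (center coordinates in micrometers, voxel-center convention) and
#' optionally `intensity`. The attached grid supplies frame extent and
#' acquisition times.
#'
#' @param records Data frame with columns `t, x_um, y_um, z_um[, intensity]`.
#' @param grid An [acquisition_grid()].
#' @return A tibble of class `nuclei_series` with attribute `grid`.
#' @export
nuclei_series <- function(records, grid) {
  req <- c("t", "x_um", "y_um", "z_um")
  if (!all(req %in% names(records))) {
    stop("records need columns t, x_um, y_um, z_um", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  records$t <- as.integer(records$t)
  tps <- sort(unique(records$t))
  if (tps[1] != 1L || !identical(tps, seq_len(length(tps)))) {
    stop("timepoint indices must be contiguous from 1", call. = FALSE)
  }
  ext <- grid_extent_um(grid)
  xyz <- as.matrix(records[, c("x_um", "y_um", "z_um")])
  bad <- which(xyz[, 1] < 0 | xyz[, 1] > ext[1] |
                 xyz[, 2] < 0 | xyz[, 2] > ext[2] |
                 xyz[, 3] < 0 | xyz[, 3] > ext[3])
  if (length(bad)) {
    stop(sprintf(
      "record %d (t=%d) lies outside the physical frame extent (%s um)",
      bad[1], records$t[bad[1]], paste(round(ext, 2), collapse = " x ")),
      call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$t)
  structure(records, grid = grid,
            class = c("nuclei_series", class(records)))
}

#' Read a nuclei table written by a nuclear segmenter
#'
#' @param path CSV file with header `t,x_um,y_um,z_um[,intensity]`.
#' @param grid An [acquisition_grid()] used to validate coordinates.
#' @return A [nuclei_series()] tibble.
#' @export
read_nuclei_table <- function(path, grid) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    stop(sprintf("parse error in %s at line %d: %s", path,
                 prob$row[1] + 1L, prob$expected[1]), call. = FALSE)
  }
  nuclei_series(tab, grid)
}

#' Write a nuclei table
#' @param series A [nuclei_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclei_table <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path, progress = FALSE)
  invisible(path)
}

#' Nuclear counts per timepoint
#'
#' @param series A [nuclei_series()].
#' @return A [count_series()] tibble with acquisition times from the grid.
#' @export
nuclei_counts <- function(series) {
  grid <- attr(series, "grid")
  tab <- dplyr::count(tibble::as_tibble(series), .data$t)
  count_series(grid_times_min(grid, tab$t), tab$n)
}

#' Write a label volume as a multi-page TIFF with YAML sidecar
#'
#' One 8-bit page per z-slice, nonzero = labeled; the sidecar
#' (`<path>.yaml`) records voxel size, channel, timepoint and shape.
#' @param volume A [label_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  pages <- lapply(seq_len(dim(volume$mask)[3]), function(k) {
    t(volume$mask[, , k]) * 1   # rows = y, cols = x
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(voxel_size_um = volume$grid$voxel_size_um,
                        channel = volume$channel,
                        timepoint_index = volume$timepoint_index,
                        shape_voxels = as.integer(dim(volume$mask))),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a label volume from a multi-page TIFF
#'
#' @param path TIFF path (one page per z-slice, nonzero = labeled).
#' @param channel Channel name; `NULL` takes it from the YAML sidecar.
#' @param t Timepoint index; `NULL` takes it from the sidecar.
#' @param grid An [acquisition_grid()] to validate against; `NULL`
#'   reconstructs a grid from the sidecar voxel size (or the config
#'   default when no sidecar exists).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, channel = NULL, t = NULL, grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0 || length(pages[[1]]) == 0) {
    stop("empty TIFF: ", path, call. = FALSE)
  }
  side_path <- paste0(path, ".yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  channel <- channel %||% side$channel %||% "fiducial_gfp"
  t <- t %||% side$timepoint_index %||% 1L
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]]); nz <- length(pages)
  if (is.null(grid)) {
    grid <- acquisition_grid(
      voxel_size_um = side$voxel_size_um %||% 0.1625,
      shape_voxels = c(nx, ny, nz))
  }
  if (!identical(as.integer(grid$shape_voxels), as.integer(c(nx, ny, nz)))) {
    stop(sprintf("TIFF shape (%dx%dx%d) does not match configured grid (%s): %s",
                 nx, ny, nz, paste(grid$shape_voxels, collapse = "x"), path),
         call. = FALSE)
  }
  mask <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) mask[, , k] <- t(pages[[k]]) > 0
  label_volume(mask, grid, channel, t)
}

#' Linearly interpolate a stack in z to isotropic voxels
#'
#' Raw stacks are acquired with coarser z-spacing than the in-plane pixel
#' size; this resamples along z so voxels become isotropic. The output
#' slice count is `ceiling(nz * z_spacing_um / voxel_size_um)`, covering
#' the same physical extent.
#'
#' @param stack Numeric 3D array (x, y, z).
#' @param z_spacing_um Input slice spacing in micrometers.
#' @param voxel_size_um Target isotropic voxel size.
#' @return Resampled 3D array.
#' @export
interpolate_z <- function(stack, z_spacing_um, voxel_size_um) {
  stopifnot(z_spacing_um > 0, voxel_size_um > 0)
  nz <- dim(stack)[3]
  n_out <- ceiling(nz * z_spacing_um / voxel_size_um)
  z_in <- (seq_len(nz) - 0.5) * z_spacing_um
  z_out <- (seq_len(n_out) - 0.5) * voxel_size_um
  out <- array(0, c(dim(stack)[1:2], n_out))
  for (k in seq_len(n_out)) {
    z <- min(max(z_out[k], z_in[1]), z_in[nz])
    j <- min(max(findInterval(z, z_in), 1L), nz - 1L)
    w <- (z - z_in[j]) / (z_in[j + 1] - z_in[j])
    out[, , k] <- (1 - w) * stack[, , j] + w * stack[, , j + 1]
  }
  out
}
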