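#' Acquisition grid and imaging schedule
#'
#' Describes the isotropic voxel grid and the two-phase imaging schedule:
#' a slow pre-morphogenesis phase (default 20 stacks at 10-minute
#' intervals, timepoints T1-T20) followed by a fast phase through
#' morphogenesis to twitching (default 125 stacks at 2-minute intervals,
#' T21-T145).
#'
#' @param voxel_size_um Isotropic voxel edge in micrometers (default
#'   0.1625).
#' @param shape_voxels Integer triple (x, y, z) of grid extent in voxels.
#' @param slow_interval_min,fast_interval_min Frame intervals in minutes.
#' @param slow_count,fast_count Numbers of slow and fast timepoints.
#' @return An object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(voxel_size_um = 0.1625,
                             shape_voxels = c(352L, 192L, 192L),
                             slow_interval_min = 10,
                             fast_interval_min = 2,
                             slow_count = 20L,
                             fast_count = 125L) {
  stopifnot(voxel_size_um > 0, length(shape_voxels) == 3,
            all(shape_voxels >= 1), slow_interval_min > 0,
            fast_interval_min > 0, slow_count >= 0, fast_count >= 0)
  structure(list(voxel_size_um = voxel_size_um,
                 shape_voxels = as.integer(shape_voxels),
                 slow_interval_min = slow_interval_min,
                 fast_interval_min = fast_interval_min,
                 slow_count = as.integer(slow_count),
                 fast_count = as.integer(fast_count)),
            class = "acquisition_grid")
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat(sprintf("<acquisition_grid> %s voxels @ %.4f um; T1-T%d every %g min, T%d-T%d every %g min\n",
              paste(x$shape_voxels, collapse = "x"), x$voxel_size_um,
              x$slow_count, x$slow_count + 1, x$slow_count + x$fast_count,
              x$fast_interval_min))
  invisible(x)
}

#' Physical extent of a grid
#' @param grid An `acquisition_grid`.
#' @return Length-3 numeric, extent along x, y, z in micrometers.
#' @export
grid_extent_um <- function(grid) {
  grid$shape_voxels * grid$voxel_size_um
}

#' Acquisition times in minutes
#'
#' Timepoint Tk maps to the start-relative clock: slow frames at
#' `0, s, 2s, ...` and fast frames continuing at the fast interval.
#' @param grid An `acquisition_grid`.
#' @param timepoints Integer timepoint indices (default all).
#' @return Numeric vector of times in minutes.
#' @export
grid_times_min <- function(grid, timepoints = NULL) {
  slow <- (seq_len(grid$slow_count) - 1) * grid$slow_interval_min
  t_last <- if (grid$slow_count > 0) {
    (grid$slow_count - 1) * grid$slow_interval_min
  } else {
    -grid$fast_interval_min
  }
  fast <- t_last + seq_len(grid$fast_count) * grid$fast_interval_min
  all_t <- c(slow, fast)
  if (is.null(timepoints)) all_t else all_t[timepoints]
}

#' Fast-phase timepoint indices
#' @param grid An `acquisition_grid`.
#' @return Integer vector of timepoint indices in the fast imaging phase.
#' @export
fast_timepoints <- function(grid) {
  grid$slow_count + seq_len(grid$fast_count)
}

# voxel-center physical coordinates: 1-based index i -> (i - 0.5) * voxel
index_to_um <- function(idx, grid) {
  unname((as.matrix(idx) - 0.5) * grid$voxel_size_um)
}

um_to_index <- function(um, grid) {
  pmin(pmax(round(as.matrix(um) / grid$voxel_size_um + 0.5), 1),
       matrix(grid$shape_voxels, nrow(as.matrix(um)), 3, byrow = TRUE))
}
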