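#' Sample fiducial voxel centers at random
#'
#' Draws up to `n` labeled-voxel centers uniformly without replacement
#' (all of them when the mask has fewer), with an explicit seed so every
#' stochastic draw in the pipeline is reproducible. The RNG state of the
#' session is left untouched.
#'
#' @param volume A nonempty [label_volume()].
#' @param n Number of voxels to sample (default 5000).
#' @param seed Integer seed.
#' @return Numeric matrix (<= n x 3) of voxel centers in micrometers.
#' @export
sample_fiducial_points <- function(volume, n = 5000L, seed = 1L) {
  pts <- mask_coords_um(volume)
  if (nrow(pts) == 0) stop("empty fiducial mask", call. = FALSE)
  if (nrow(pts) <= n) return(pts)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pts[sample.int(nrow(pts), n), , drop = FALSE]
}

# coordinates of 3D points in the (P2, P3) plane of a frame
project_p2p3 <- function(points_um, frame) {
  rel <- sweep(as.matrix(points_um), 2, frame$origin_um)
  cbind(p2 = as.numeric(rel %*% frame$axes[, 2]),
        p3 = as.numeric(rel %*% frame$axes[, 3]))
}

#' Replace the translation of a 2D transform by a frame-center correction
#'
#' Fiducial nuclei exhibit small concerted linear movements independent of
#' the bulk rotation; left uncorrected, these make the (stationary)
#' eggshell drift through the image frame. This keeps the rotation but
#' resets the translation so that `frame_center` is a fixed point,
#' producing a pure rotation about the long axis in the P2-P3 plane.
#'
#' @param transform A 2D `rigid_transform`.
#' @param frame_center 2D point held fixed.
#' @return A 2D `rigid_transform` with the same rotation and
#'   `T(frame_center) == frame_center`.
#' @export
center_correction <- function(transform, frame_center = c(0, 0)) {
  stopifnot(inherits(transform, "rigid_transform"),
            transform$dimension == 2)
  R <- transform$rotation
  rigid_transform(R, frame_center - as.numeric(R %*% frame_center))
}

#' Bulk rotation between two consecutive fiducial masks
#'
#' Samples fiducial voxels at both timepoints, projects them onto the plane
#' perpendicular to the long axis, registers the projected clouds rigidly,
#' and replaces the translation by the frame-center correction so the
#' result is a pure rotation about the long axis. The sign is
#' counterclockwise-positive about +P1 viewed from the anterior.
#'
#' @param mask_t,mask_t1 Fiducial [label_volume()]s at consecutive
#'   timepoints.
#' @param frame An [embryo_frame()].
#' @param params [cpd_params()] for the 2D registration.
#' @param n_sample Voxels sampled per mask (default 5000).
#' @param seed Sampling seed.
#' @return Signed angle in degrees, with the registration's `converged`
#'   attribute propagated.
#' @export
step_rotation <- function(mask_t, mask_t1, frame, params = cpd_params(),
                          n_sample = 5000L, seed = 1L) {
  a <- project_p2p3(sample_fiducial_points(mask_t, n_sample, seed), frame)
  b <- project_p2p3(sample_fiducial_points(mask_t1, n_sample, seed + 1L),
                    frame)
  tr <- cpd_rigid(a, b, params)
  pure <- center_correction(tr, c(0, 0))
  ang <- rotation_angle_deg(pure)
  attr(ang, "converged") <- attr(tr, "converged")
  ang
}

#' Accumulate per-step rotations into a track
#'
#' @param angles_deg Signed per-step angles over consecutive fast-imaging
#'   pairs.
#' @param sample_seed,n_sample Bookkeeping: recorded in attributes.
#' @return A tibble of class `rotation_track` with columns `step`,
#'   `angle_deg`, `cumulative_deg`; the total rotation is
#'   `cumulative_deg[n]`.
#' @export
accumulate_rotations <- function(angles_deg, sample_seed = NA_integer_,
                                 n_sample = NA_integer_) {
  stopifnot(all(is.finite(angles_deg)) || length(angles_deg) == 0)
  structure(
    tibble::tibble(step = seq_along(angles_deg),
                   angle_deg = as.numeric(angles_deg),
                   cumulative_deg = cumsum(as.numeric(angles_deg))),
    sample_seed = sample_seed, n_sample = n_sample,
    class = c("rotation_track", class(tibble::tibble())))
}

#' Track bulk rotation about the long axis across a movie
#'
#' Runs [step_rotation()] over consecutive (or strided) pairs of fiducial
#' masks and accumulates the signed angles, giving the cumulative rotation
#' of each frame relative to the first. The movie can then be displayed in
#' a time-invariant internal coordinate system by composing the summed
#' angles and rotating each stack once from the first frame.
#'
#' @param masks List of fiducial [label_volume()]s in time order.
#' @param frame An [embryo_frame()].
#' @param params [cpd_params()].
#' @param n_sample,seed Sampling controls (see [sample_fiducial_points()]).
#' @param stride Register frames `i` and `i + stride` (default 1); angles
#'   are attributed per elapsed pair.
#' @return A `rotation_track` tibble (one row per registered pair), with
#'   attribute `warnings` listing non-converged steps.
#' @export
rotation_track <- function(masks, frame, params = cpd_params(),
                           n_sample = 5000L, seed = 1L, stride = 1L) {
  stopifnot(length(masks) >= 2, stride >= 1)
  pairs <- seq(1L, length(masks) - stride, by = stride)
  ang <- numeric(length(pairs))
  bad <- integer(0)
  for (k in seq_along(pairs)) {
    i <- pairs[k]
    a <- step_rotation(masks[[i]], masks[[i + stride]], frame, params,
                       n_sample, seed + 2L * (k - 1L))
    ang[k] <- as.numeric(a)
    if (!isTRUE(attr(a, "converged"))) bad <- c(bad, i)
  }
  out <- accumulate_rotations(ang, sample_seed = seed, n_sample = n_sample)
  attr(out, "warnings") <- bad
  out
}

#' Cumulative rotation of a track at a given step
#' @param track A `rotation_track`.
#' @param step Step index (0 gives 0 degrees).
#' @return Cumulative signed angle in degrees.
#' @export
cumulative_rotation <- function(track, step) {
  if (step <= 0) return(0)
  track$cumulative_deg[min(step, nrow(track))]
}
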