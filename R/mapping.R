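#' Perpendicular (P2/P3) axes from fiducial asymmetry
#'
#' Constructs the vector from the mean posterior fiducial position to the
#' mean anterior fiducial position (split at the plane through the embryo
#' centroid normal to P1), projects it onto the plane perpendicular to the
#' long axis, and normalizes it to give P2; P3 completes the right-handed
#' frame.
#'
#' @param fiducial A fiducial [label_volume()] with voxels on both sides of
#'   the centroid plane.
#' @param p1 Oriented long-axis unit vector (+P1 = anterior).
#' @param centroid_um Embryo centroid.
#' @return List with unit vectors `p2` and `p3`.
#' @export
perpendicular_axes <- function(fiducial, p1, centroid_um) {
  pts <- mask_coords_um(fiducial)
  if (nrow(pts) == 0) stop("empty fiducial mask", call. = FALSE)
  p1 <- unit(p1)
  proj <- as.numeric(sweep(pts, 2, centroid_um) %*% p1)
  if (!any(proj > 0) || !any(proj < 0)) {
    stop("all fiducial voxels lie on one side of the centroid plane",
         call. = FALSE)
  }
  v <- colMeans(pts[proj > 0, , drop = FALSE]) -
    colMeans(pts[proj < 0, , drop = FALSE])
  v_perp <- v - sum(v * p1) * p1
  if (sqrt(sum(v_perp^2)) < 1e-9) {
    stop("ambiguous axes: posterior-to-anterior vector is parallel to P1",
         call. = FALSE)
  }
  p2 <- unit(v_perp)
  list(p2 = p2, p3 = cross3(p1, p2))
}

#' Estimate an embryo's intrinsic coordinate frame
#'
#' Convenience wrapper running the frame-construction chain on a bundle:
#' convex-hull moments per timepoint in the averaging window, time-averaged
#' long axis, anterior orientation from the fiducial channel, and
#' perpendicular axes from fiducial asymmetry at an early fast timepoint.
#'
#' @param bundle An `embryo_bundle`.
#' @param axis_window Timepoint window for moment averaging (default
#'   T15-T30).
#' @param axis_timepoint Fast timepoint whose fiducial mask fixes the
#'   anterior sign and P2 (default: first fast timepoint with a mask).
#' @return List with `frame` ([embryo_frame()]), `summaries` (hull moments
#'   per window timepoint) and `window_timepoints`.
#' @export
estimate_frame <- function(bundle, axis_window = c(15, 30),
                           axis_timepoint = NULL) {
  nuc <- tibble::as_tibble(bundle$nuclei)
  tps <- intersect(axis_window[1]:axis_window[2], unique(nuc$t))
  if (length(tps) == 0) stop("no nuclei tables in the axis window",
                             call. = FALSE)
  summaries <- lapply(tps, function(tt) {
    hull_moments(as.matrix(nuc[nuc$t == tt, c("x_um", "y_um", "z_um")]))
  })
  p1 <- long_axis(summaries, timepoints = tps, window = axis_window)
  centroid <- rowMeans(vapply(summaries, function(s) s$centroid_um,
                              numeric(3)))
  tp <- axis_timepoint %||% as.integer(names(bundle$fiducial)[1])
  fid <- bundle$fiducial[[as.character(tp)]]
  if (is.null(fid)) stop("no fiducial mask at the axis timepoint",
                         call. = FALSE)
  p1 <- p1 * anterior_orientation(fid, p1, centroid)
  ax <- perpendicular_axes(fid, p1, centroid)
  list(frame = embryo_frame(p1, ax$p2, centroid, anterior_sign = 1),
       summaries = summaries, window_timepoints = tps,
       axis_timepoint = tp)
}

# minimal rotation mapping unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rot3(180, p))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

#' Coarse rotation about P1 aligning the P2 axes
#'
#' With the long axes already co-oriented (anterior to anterior), returns
#' the signed angle about P1 that rotates the test embryo's P2 axis onto
#' the reference P2 axis.
#'
#' @param test_frame,ref_frame [embryo_frame()] objects.
#' @return Signed angle in degrees (counterclockwise about +P1).
#' @export
coarse_align <- function(test_frame, ref_frame) {
  n <- unit(ref_frame$axes[, 1])
  a <- test_frame$axes[, 2]
  a <- unit(a - sum(a * n) * n)
  b <- ref_frame$axes[, 2]
  b <- unit(b - sum(b * n) * n)
  signed_angle_about(a, b, n)
}

#' Early-timepoint rotational refinement
#'
#' After coarse P2 alignment, registers the projected fiducial clouds of
#' test and reference at one early fast timepoint and returns the residual
#' rotation about the long axis. Corrections beyond `fail_deg` reproduce
#' the failure signature of a missed coarse alignment and are flagged.
#'
#' @param test_points,ref_points 2D (P2, P3)-projected fiducial samples,
#'   coarse alignment already applied.
#' @param params [cpd_params()].
#' @param fail_deg QC threshold on |rotation| (default 40).
#' @return Signed angle in degrees with attribute `qc_fail` (logical).
#' @export
refine_early <- function(test_points, ref_points, params = cpd_params(),
                         fail_deg = 40) {
  tr <- cpd_rigid(as.matrix(test_points), as.matrix(ref_points), params)
  ang <- rotation_angle_deg(center_correction(tr, c(0, 0)))
  qc <- abs(ang) > fail_deg
  if (qc) {
    warning(sprintf("early refinement rotation %.1f deg exceeds %.0f deg: likely alignment failure",
                    ang, fail_deg), call. = FALSE)
  }
  attr(ang, "qc_fail") <- qc
  ang
}

#' Per-timepoint 3D refinement with damped rotations
#'
#' Registers matched 3D fiducial clouds with the rotation-damped variant,
#' allowing translations of arbitrary size but only small rotational
#' corrections; rotations beyond `cap_deg` are clipped to the cap (about
#' the same axis) and flagged.
#'
#' @param test_cloud,ref_cloud 3D fiducial samples at a matched timepoint
#'   (all earlier stages already applied to `test_cloud`).
#' @param params [cpd_params()].
#' @param cap_deg Rotation magnitude cap (default 10).
#' @param damping_factor,release_width_um Damping controls, see
#'   [cpd_rigid_damped()].
#' @return A 3D `rigid_transform` with attribute `qc_capped` (logical).
#' @export
refine_per_timepoint <- function(test_cloud, ref_cloud,
                                 params = cpd_params(), cap_deg = 10,
                                 damping_factor = 0.1,
                                 release_width_um = NULL) {
  tr <- cpd_rigid_damped(as.matrix(test_cloud), as.matrix(ref_cloud), params,
                         damping_factor = damping_factor,
                         release_width_um = release_width_um)
  ang <- rotation_angle_deg(tr)
  capped <- abs(ang) > cap_deg
  if (capped) {
    # keep the axis and the centroid mapping, clip the angle to the cap
    ctr <- colMeans(as.matrix(test_cloud))
    image_ctr <- apply_transform(tr, ctr)
    R <- damp_rotation(tr$rotation, cap_deg / abs(ang))
    tr <- rigid_transform(R, image_ctr - as.numeric(R %*% ctr))
  }
  attr(tr, "qc_capped") <- capped
  tr
}

#' Configuration for the alignment pipeline
#'
#' @param temporal,scaling,rotation_tracking,early_refinement,final_refinement
#'   Stage toggles; disabled stages contribute identity corrections.
#' @param axis_window Timepoint window for moment/axis averaging.
#' @param interp_factor Count-curve interpolation factor.
#' @param max_offset_min,min_overlap_frac Passed to [temporal_offset()].
#' @param n_sample Fiducial voxels sampled per registration.
#' @param seed Seed for all voxel sampling.
#' @param cpd [cpd_params()] for the early 2D refinement; `NULL` derives
#'   voxel-aware defaults from the grid (width floor at one voxel, so soft
#'   correspondences are never finer than the lattice).
#' @param cpd_track [cpd_params()] for consecutive-frame rotation tracking;
#'   `NULL` derives a narrow-capture, voxel-floored schedule (consecutive
#'   frames are nearly aligned).
#' @param cpd_refine [cpd_params()] for the final 3D refinement; `NULL`
#'   derives voxel-aware defaults.
#' @param rotation_cap_deg Cap for the final per-timepoint refinement.
#' @param early_timepoint Fast-timepoint pair index used by the early
#'   refinement (default 1 = first matched pair).
#' @param fail_deg Early-refinement QC threshold.
#' @return A list of class `align_config`.
#' @export
align_config <- function(temporal = TRUE, scaling = TRUE,
                         rotation_tracking = TRUE, early_refinement = TRUE,
                         final_refinement = TRUE,
                         axis_window = c(15, 30), interp_factor = 5L,
                         max_offset_min = 60, min_overlap_frac = 0.25,
                         n_sample = 5000L, seed = 1L,
                         cpd = NULL, cpd_track = NULL, cpd_refine = NULL,
                         rotation_cap_deg = 10,
                         early_timepoint = 1L, fail_deg = 40) {
  structure(as.list(environment()), class = "align_config")
}

slow_counts <- function(bundle) {
  cs <- bundle$counts[seq_len(bundle$grid$slow_count), ]
  count_series(cs$time_min, cs$count)
}

#' Align a test embryo onto a reference embryo
#'
#' Runs the full pipeline: temporal offset from nuclear-count curves;
#' intrinsic frames from hull moments, anterior orientation and fiducial
#' asymmetry; length/width scale factors; bulk-rotation tracks for both
#' embryos; coarse P2 alignment; early-timepoint rotational refinement; and
#' per-timepoint rotation-damped 3D refinement. Every stage can be toggled
#' off in the config, in which case it contributes an identity correction.
#'
#' @param test_bundle,ref_bundle `embryo_bundle` objects (nuclei tables,
#'   counts, fiducial masks per fast timepoint).
#' @param config An [align_config()].
#' @param ref_track Optional precomputed [rotation_track()] of the
#'   reference (reused when aligning a cohort against one reference).
#' @return An object of class `alignment_result`; see [tidy.alignment_result()]
#'   and [map_points()].
#' @export
align_embryo <- function(test_bundle, ref_bundle, config = align_config(),
                         ref_track = NULL) {
  grid_t <- test_bundle$grid
  grid_r <- ref_bundle$grid
  vox <- grid_r$voxel_size_um
  cpd_early <- config$cpd %||%
    cpd_params(final_width_um = vox, polish = FALSE)
  cpd_track_p <- config$cpd_track %||%
    cpd_params(initial_width_um = 5 * vox, final_width_um = vox,
               anneal = 0.85, polish = FALSE)
  cpd_refine_p <- config$cpd_refine %||%
    cpd_params(initial_width_um = 8 * vox, final_width_um = vox,
               anneal = 0.88, polish = FALSE)

  temporal <- if (config$temporal) {
    temporal_offset(
      interpolate_counts(slow_counts(test_bundle), config$interp_factor),
      interpolate_counts(slow_counts(ref_bundle), config$interp_factor),
      max_offset_min = config$max_offset_min,
      min_overlap_frac = config$min_overlap_frac)
  } else {
    structure(list(offset_min = 0, normalized_sse = NA_real_,
                   overlap_points = NA_integer_), class = "temporal_offset")
  }

  ref_est <- estimate_frame(ref_bundle, config$axis_window)
  test_est <- estimate_frame(test_bundle, config$axis_window)

  scale <- if (config$scaling) {
    # match the reference ball-stage window on the test clock via the offset
    ref_times <- grid_times_min(grid_r, ref_est$window_timepoints)
    test_times <- grid_times_min(grid_t)
    nuc_t <- unique(tibble::as_tibble(test_bundle$nuclei)$t)
    matched <- unique(vapply(ref_times, function(tm) {
      which.min(abs(test_times + temporal$offset_min - tm))
    }, integer(1)))
    matched <- intersect(matched, nuc_t)
    test_sum <- if (length(matched) == 0) test_est$summaries else {
      nuc <- tibble::as_tibble(test_bundle$nuclei)
      lapply(matched, function(tt) {
        hull_moments(as.matrix(nuc[nuc$t == tt, c("x_um", "y_um", "z_um")]))
      })
    }
    scale_factors(ref_est$summaries, test_sum)
  } else {
    structure(list(a_ref = NA, a_test = NA, b_ref = NA, b_test = NA,
                   q1 = 1, q2 = 1, r_l = 1, r_s = 1),
              class = "scale_factors")
  }

  # matched fast timepoints: test fast frame -> nearest reference fast frame
  fast_t <- as.integer(names(test_bundle$fiducial))
  fast_r <- as.integer(names(ref_bundle$fiducial))
  need_t <- fast_timepoints(grid_t)
  missing_t <- setdiff(need_t, fast_t)
  if (length(missing_t) > 0) {
    stop("test bundle is missing fiducial masks for timepoints ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  times_t <- grid_times_min(grid_t, fast_t)
  times_r <- grid_times_min(grid_r, fast_r)
  j_near <- vapply(times_t + temporal$offset_min, function(tm) {
    j <- which.min(abs(times_r - tm))
    if (abs(times_r[j] - tm) <= grid_r$fast_interval_min / 2 + 1e-9) j
    else NA_integer_
  }, integer(1))
  pairs <- tibble::tibble(t_test = fast_t, t_ref = fast_r[j_near])
  pairs <- pairs[!is.na(pairs$t_ref), ]
  if (nrow(pairs) == 0) stop("no matched fast timepoints", call. = FALSE)

  track_t <- track_r <- NULL
  if (config$rotation_tracking) {
    track_t <- rotation_track(test_bundle$fiducial, test_est$frame,
                              cpd_track_p, config$n_sample, config$seed)
    track_r <- ref_track %||%
      rotation_track(ref_bundle$fiducial, ref_est$frame,
                     cpd_track_p, config$n_sample, config$seed + 10000L)
  }
  phi <- function(track, fast_ids, t) {
    if (is.null(track)) return(0)
    cumulative_rotation(track, match(t, fast_ids) - 1L)
  }

  # indirect transform (everything except final 3D refinement) for a pair
  indirect_transform <- function(t_test, t_ref, early_deg = 0) {
    A_t <- test_est$frame$axes; o_t <- test_est$frame$origin_um
    A_r <- ref_est$frame$axes; o_r <- ref_est$frame$origin_um
    S <- diag(c(scale$r_l, scale$r_s, scale$r_s))
    M <- A_r %*% rot3(phi(track_r, fast_r, t_ref), "x") %*%
      rot3(early_deg, "x") %*% S %*%
      rot3(-phi(track_t, fast_t, t_test), "x") %*% t(A_t)
    # not a pure rotation when scaling != 1; keep as affine pieces
    list(M = M, o_t = o_t, o_r = o_r)
  }
  apply_indirect <- function(tf, pts) {
    sweep(sweep(as.matrix(pts), 2, tf$o_t) %*% t(tf$M), 2, tf$o_r, "+")
  }

  coarse_deg <- coarse_align(test_est$frame, ref_est$frame)

  early_deg <- 0
  early_qc <- FALSE
  if (config$early_refinement) {
    k <- min(max(config$early_timepoint, 1L), nrow(pairs))
    tf0 <- indirect_transform(pairs$t_test[k], pairs$t_ref[k], 0)
    tp <- apply_indirect(tf0, sample_fiducial_points(
      test_bundle$fiducial[[as.character(pairs$t_test[k])]],
      config$n_sample, config$seed + 20000L))
    rp <- sample_fiducial_points(
      ref_bundle$fiducial[[as.character(pairs$t_ref[k])]],
      config$n_sample, config$seed + 20001L)
    ed <- refine_early(project_p2p3(tp, ref_est$frame),
                       project_p2p3(rp, ref_est$frame),
                       cpd_early, fail_deg = config$fail_deg)
    early_deg <- as.numeric(ed)
    early_qc <- attr(ed, "qc_fail")
  }

  refinements <- vector("list", nrow(pairs))
  qc_capped <- logical(nrow(pairs))
  ref_angle <- ref_shift <- rep(NA_real_, nrow(pairs))
  if (config$final_refinement) {
    for (k in seq_len(nrow(pairs))) {
      tf <- indirect_transform(pairs$t_test[k], pairs$t_ref[k], early_deg)
      tp <- apply_indirect(tf, sample_fiducial_points(
        test_bundle$fiducial[[as.character(pairs$t_test[k])]],
        config$n_sample, config$seed + 30000L + k))
      rp <- sample_fiducial_points(
        ref_bundle$fiducial[[as.character(pairs$t_ref[k])]],
        config$n_sample, config$seed + 40000L + k)
      tr <- refine_per_timepoint(tp, rp, cpd_refine_p,
                                 cap_deg = config$rotation_cap_deg)
      refinements[[k]] <- tr
      qc_capped[k] <- attr(tr, "qc_capped")
      ref_angle[k] <- rotation_angle_deg(tr)
      ref_shift[k] <- sqrt(sum((apply_transform(tr, colMeans(tp)) -
                                  colMeans(tp))^2))
    }
  } else {
    refinements <- lapply(seq_len(nrow(pairs)),
                          function(k) identity_transform(3L))
    ref_angle[] <- 0; ref_shift[] <- 0
  }

  structure(list(
    embryo_id = test_bundle$embryo_id,
    reference_id = ref_bundle$embryo_id,
    temporal = temporal,
    scale = scale,
    test_frame = test_est$frame, ref_frame = ref_est$frame,
    coarse_p2_rotation_deg = coarse_deg,
    early_refinement_deg = early_deg,
    track_test = track_t, track_ref = track_r,
    fast_test = fast_t, fast_ref = fast_r,
    pairs = pairs,
    refinements = refinements,
    refinement_table = tibble::tibble(
      t_test = pairs$t_test, t_ref = pairs$t_ref,
      refine_angle_deg = ref_angle, refine_shift_um = ref_shift,
      qc_capped = qc_capped),
    qc = list(early_fail = early_qc,
              capped_timepoints = pairs$t_test[qc_capped],
              track_warnings_test = attr(track_t, "warnings"),
              track_warnings_ref = attr(track_r, "warnings")),
    config = config,
    .indirect = indirect_transform,
    .apply_indirect = apply_indirect
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s -> %s\n", x$embryo_id, x$reference_id))
  cat(sprintf("  offset: %+.1f min | r_l %.4f r_s %.4f | coarse %+.1f deg | early %+.2f deg\n",
              x$temporal$offset_min, x$scale$r_l, x$scale$r_s,
              x$coarse_p2_rotation_deg, x$early_refinement_deg))
  cat(sprintf("  %d matched timepoints; mean final refinement %.2f deg / %.2f um\n",
              nrow(x$pairs), mean(x$refinement_table$refine_angle_deg),
              mean(x$refinement_table$refine_shift_um)))
  invisible(x)
}

#' Map test-embryo coordinates into the reference frame
#'
#' Applies the composed per-timepoint transform of an alignment (or one of
#' its partial stages) to points in the test embryo's image coordinates.
#' Stages mirror the alignment ablation: `"none"` (identity), `"long_axis"`
#' (anterior-posterior axes and centroids aligned), `"indirect"` (all steps
#' except the final 3D refinement) and `"full"`.
#'
#' @param result An `alignment_result`.
#' @param points Numeric matrix (n x 3) in test image coordinates (um).
#' @param t_test Test fast timepoint the points belong to.
#' @param stage One of `"none"`, `"long_axis"`, `"indirect"`, `"full"`.
#' @return Transformed points (n x 3) in reference image coordinates.
#' @export
map_points <- function(result, points, t_test,
                       stage = c("full", "indirect", "long_axis", "none")) {
  stage <- match.arg(stage)
  pts <- as.matrix(points)
  if (stage == "none") return(pts)
  if (stage == "long_axis") {
    R <- rotation_between(result$test_frame$axes[, 1],
                          result$ref_frame$axes[, 1])
    return(sweep(sweep(pts, 2, result$test_frame$origin_um) %*% t(R), 2,
                 result$ref_frame$origin_um, "+"))
  }
  k <- match(t_test, result$pairs$t_test)
  if (is.na(k)) stop("timepoint ", t_test, " has no matched reference frame",
                     call. = FALSE)
  tf <- result$.indirect(result$pairs$t_test[k], result$pairs$t_ref[k],
                         result$early_refinement_deg)
  out <- result$.apply_indirect(tf, pts)
  if (stage == "full") out <- apply_transform(result$refinements[[k]], out)
  out
}

#' @describeIn align_embryo one row per matched timepoint with the final
#'   refinement magnitudes and QC flags.
#' @param x An `alignment_result`.
#' @param ... Unused.
#' @export
tidy.alignment_result <- function(x, ...) {
  x$refinement_table
}

#' @describeIn align_embryo one-row summary of the whole alignment.
#' @export
glance.alignment_result <- function(x, ...) {
  tibble::tibble(
    embryo_id = x$embryo_id,
    offset_min = x$temporal$offset_min,
    r_l = x$scale$r_l, r_s = x$scale$r_s,
    coarse_p2_rotation_deg = x$coarse_p2_rotation_deg,
    early_refinement_deg = x$early_refinement_deg,
    total_rotation_test_deg = if (is.null(x$track_test)) NA_real_ else
      x$track_test$cumulative_deg[nrow(x$track_test)],
    n_matched = nrow(x$pairs),
    mean_refine_angle_deg = mean(x$refinement_table$refine_angle_deg),
    mean_refine_shift_um = mean(x$refinement_table$refine_shift_um),
    early_qc_fail = x$qc$early_fail,
    n_capped = length(x$qc$capped_timepoints))
}
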