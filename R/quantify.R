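#' Bidirectional 1-micrometer overlap fraction
#'
#' For each direction, the fraction of labeled voxels whose Euclidean
#' distance to the nearest labeled voxel of the other mask is at most
#' `radius_um` (inclusive), computed in physical units via exact
#' nearest-neighbour queries. An empty own-mask gives fraction 0 with a QC
#' note.
#'
#' @param test,ref [label_volume()]s on the same grid.
#' @param radius_um Distance threshold (default 1.0).
#' @return Named numeric vector
#'   `c(frac_test_near_ref = ..., frac_ref_near_test = ...)`, with
#'   attribute `qc` if either mask was empty.
#' @export
overlap_fraction <- function(test, ref, radius_um = 1.0) {
  stopifnot(inherits(test, "label_volume"), inherits(ref, "label_volume"),
            radius_um > 0)
  if (!isTRUE(all.equal(test$grid$voxel_size_um, ref$grid$voxel_size_um)) ||
      !identical(test$grid$shape_voxels, ref$grid$shape_voxels)) {
    stop("masks are on different grids", call. = FALSE)
  }
  pt <- mask_coords_um(test)
  pr <- mask_coords_um(ref)
  qc <- NULL
  frac <- function(a, b) {
    if (nrow(a) == 0) {
      qc <<- c(qc, "empty mask: fraction defined as 0")
      return(0)
    }
    if (nrow(b) == 0) return(0)
    d <- RANN::nn2(b, a, k = 1)$nn.dists[, 1]
    mean(d <= radius_um + 1e-9)
  }
  out <- c(frac_test_near_ref = frac(pt, pr),
           frac_ref_near_test = frac(pr, pt))
  if (!is.null(qc)) attr(out, "qc") <- qc
  out
}

#' Manually traced nerve-ring polyline
#'
#' @param points_um Ordered matrix/data frame of 3D points (um) along the
#'   traced ring; >= 10 points with consecutive spacing under 5 um.
#' @param embryo_id,timepoint Provenance.
#' @return A tibble of class `neurite_trace`.
#' @export
neurite_trace <- function(points_um, embryo_id = NA_character_,
                          timepoint = NA_integer_) {
  if (is.data.frame(points_um)) {
    points_um <- as.matrix(points_um[, c("x_um", "y_um", "z_um")])
  }
  pts <- as.matrix(points_um)
  if (nrow(pts) < 10) stop("a trace needs at least 10 points", call. = FALSE)
  gaps <- sqrt(rowSums(diff(pts)^2))
  if (any(gaps >= 5)) {
    stop("consecutive trace points must be closer than 5 um", call. = FALSE)
  }
  structure(tibble::tibble(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]),
            embryo_id = embryo_id, timepoint = timepoint,
            class = c("neurite_trace", class(tibble::tibble())))
}

#' Read a neurite trace polyline from CSV
#' @param path CSV with columns `x_um,y_um,z_um` in trace order.
#' @param embryo_id,timepoint Provenance.
#' @return A [neurite_trace()].
#' @export
read_neurite_trace <- function(path, embryo_id = NA_character_,
                               timepoint = NA_integer_) {
  neurite_trace(readr::read_csv(path, show_col_types = FALSE,
                                progress = FALSE),
                embryo_id, timepoint)
}

#' Fit a nerve-ring trace to a plane by vector decomposition
#'
#' Splits the ring into top and bottom arms relative to a center line,
#' forms vectors from bottom-arm points to top-arm points, and decomposes
#' them: the side-to-side vector is the componentwise average of the
#' inter-arm vectors under a linear (L1) cost — the geometric median —
#' rather than a squared-error mean; the forward vector is the geometric
#' median of the residual vectors after removing their side-to-side
#' components (each residual first flipped into a common half-space, since
#' residuals come in opposing pairs); the out vector is their normalized
#' cross product, fixed to the hemisphere of `hemisphere`. The linear cost
#' is used instead of a least-squares plane fit because squared error
#' overfits to the non-planar stubs near the cell bodies at the arm ends.
#'
#' @param trace A [neurite_trace()] or point matrix.
#' @param center_line List with `point_um` (a point on the line) and
#'   `split_direction` (unit vector; points with positive component of
#'   (p - point) along it form the top arm). Set from the reference-embryo
#'   geometry.
#' @param hemisphere Direction fixing the sign of `out` (default +x, the
#'   anterior).
#' @param max_pairs Inter-arm pairs are deterministically thinned to at
#'   most this many (averaging is pair-order invariant).
#' @return An object of class `plane_fit`: list with unit vectors
#'   `side_to_side`, `forward`, `out` and the trace `centroid_um`.
#' @export
fit_nr_plane <- function(trace, center_line, hemisphere = c(1, 0, 0),
                         max_pairs = 1e4) {
  pts <- if (is.data.frame(trace)) {
    as.matrix(trace[, c("x_um", "y_um", "z_um")])
  } else as.matrix(trace)
  s <- as.numeric(sweep(pts, 2, center_line$point_um) %*%
                    unit(center_line$split_direction))
  top <- pts[s > 0, , drop = FALSE]
  bottom <- pts[s < 0, , drop = FALSE]
  if (nrow(top) == 0 || nrow(bottom) == 0) {
    stop("an arm of the ring is empty after the center-line split",
         call. = FALSE)
  }
  ij <- as.matrix(expand.grid(i = seq_len(nrow(bottom)),
                              j = seq_len(nrow(top))))
  if (nrow(ij) > max_pairs) {
    ij <- ij[seq(1, nrow(ij), length.out = max_pairs), , drop = FALSE]
  }
  v <- top[ij[, 2], , drop = FALSE] - bottom[ij[, 1], , drop = FALSE]
  s2s <- unit(geometric_median(v))
  resid <- v - outer(as.numeric(v %*% s2s), s2s)
  keep <- sqrt(rowSums(resid^2)) > 1e-9
  resid <- resid[keep, , drop = FALSE]
  if (nrow(resid) == 0) {
    stop("degenerate fit: inter-arm vectors are all parallel to side-to-side",
         call. = FALSE)
  }
  # residuals come in opposing directions; flip into the dominant half-space
  pc1 <- svd(resid, nu = 0, nv = 1)$v[, 1]
  flip <- sign(as.numeric(resid %*% pc1))
  flip[flip == 0] <- 1
  fwd_raw <- geometric_median(resid * flip)
  if (sqrt(sum(fwd_raw^2)) < 1e-9) {
    stop("degenerate fit: no forward direction", call. = FALSE)
  }
  forward <- unit(fwd_raw)
  if (abs(sum(forward * s2s)) > 1 - 1e-6) {
    stop("degenerate fit: side-to-side and forward are near-parallel",
         call. = FALSE)
  }
  out <- unit(cross3(s2s, forward))
  if (sum(out * hemisphere) < 0) out <- -out
  structure(list(side_to_side = s2s, forward = forward, out = out,
                 centroid_um = colMeans(pts)),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("<plane_fit>\n")
  cat(sprintf("  out:      %s\n", paste(sprintf("%+.4f", x$out), collapse = ", ")))
  cat(sprintf("  centroid: %s um\n",
              paste(sprintf("%.2f", x$centroid_um), collapse = ", ")))
  invisible(x)
}

#' @describeIn fit_nr_plane tidy one-row summary.
#' @param x A `plane_fit`.
#' @param ... Unused.
#' @export
tidy.plane_fit <- function(x, ...) {
  tibble::tibble(out_x = x$out[1], out_y = x$out[2], out_z = x$out[3],
                 centroid_x_um = x$centroid_um[1],
                 centroid_y_um = x$centroid_um[2],
                 centroid_z_um = x$centroid_um[3])
}

#' Per-embryo deviation of a landmark from the cohort mean position
#'
#' @param positions Matrix (n x 3) or data frame of aligned per-embryo 3D
#'   positions for one named cell or ring center.
#' @return A tibble with `embryo` index and `deviation_um` (absolute
#'   distance from the mean position), plus attributes `mean_um` and
#'   `sd_um` summarizing the deviations.
#' @export
centroid_deviation <- function(positions) {
  P <- as.matrix(positions)
  if (nrow(P) < 2) stop("need >= 2 embryos", call. = FALSE)
  ctr <- colMeans(P)
  dev <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  structure(tibble::tibble(embryo = seq_len(nrow(P)), deviation_um = dev),
            mean_um = mean(dev), sd_um = stats::sd(dev),
            mean_position_um = ctr)
}

#' Per-embryo angles of plane normals from the mean direction
#'
#' @param out_vectors Matrix (n x 3) of hemisphere-consistent unit normals.
#' @return A tibble with `embryo` and `angle_deg` (angle to the normalized
#'   mean direction), plus attributes `mean_deg` and `sd_deg`.
#' @export
plane_angle_deviation <- function(out_vectors) {
  V <- as.matrix(out_vectors)
  if (nrow(V) < 2) stop("need >= 2 vectors", call. = FALSE)
  V <- V / sqrt(rowSums(V^2))
  m <- colSums(V)
  if (sqrt(sum(m^2)) < 1e-9) {
    stop("zero-norm vector sum: directions cancel", call. = FALSE)
  }
  m <- unit(m)
  ang <- rad2deg(acos(pmin(pmax(as.numeric(V %*% m), -1), 1)))
  structure(tibble::tibble(embryo = seq_len(nrow(V)), angle_deg = ang),
            mean_deg = mean(ang), sd_deg = stats::sd(ang),
            mean_direction = m)
}

#' Overlap fractions across alignment ablation stages
#'
#' Recomputes the bidirectional overlap between the transformed test masks
#' and the reference masks under each partial composition of the pipeline:
#' no transformation; long-axis (AP) alignment only; indirect alignment
#' (all steps except the final 3D refinement); and full alignment.
#' Evaluated by default at the last matched timepoint before twitching.
#'
#' @param test_bundle,ref_bundle `embryo_bundle`s.
#' @param alignment An `alignment_result` for the pair.
#' @param channels Channels to evaluate (present in both bundles).
#' @param timepoint Test fast timepoint (default: last matched pair).
#' @param radius_um Overlap radius.
#' @return A tibble: `stage`, `channel`, `frac_test_near_ref`,
#'   `frac_ref_near_test`, `overlap` (mean of the two directions).
#' @export
overlap_by_stage <- function(test_bundle, ref_bundle, alignment,
                             channels = c("fiducial", "reporter"),
                             timepoint = NULL, radius_um = 1.0) {
  tp <- timepoint %||% alignment$pairs$t_test[nrow(alignment$pairs)]
  k <- match(tp, alignment$pairs$t_test)
  if (is.na(k)) stop("timepoint has no matched stage transforms",
                     call. = FALSE)
  tr <- alignment$pairs$t_ref[k]
  stages <- c("none", "long_axis", "indirect", "full")
  rows <- list()
  for (ch in channels) {
    tv <- test_bundle[[ch]][[as.character(tp)]]
    rv <- ref_bundle[[ch]][[as.character(tr)]]
    if (is.null(tv) || is.null(rv)) {
      stop(sprintf("channel %s missing at timepoint %d/%d", ch, tp, tr),
           call. = FALSE)
    }
    pts <- mask_coords_um(tv)
    for (st in stages) {
      mapped <- map_points(alignment, pts, tp, stage = st)
      tv_mapped <- voxelize_points(mapped, rv$grid, rv$channel, tr)
      ov <- overlap_fraction(tv_mapped, rv, radius_um)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stage = st, channel = ch,
        frac_test_near_ref = ov[["frac_test_near_ref"]],
        frac_ref_near_test = ov[["frac_ref_near_test"]],
        overlap = mean(ov))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$stage <- factor(out$stage, levels = stages)
  out
}
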