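#' Embryo-intrinsic orthonormal coordinate frame
#'
#' The P1/P2/P3 frame: P1 is the long (anterior-posterior) axis from the
#' smallest principal moment, oriented so +P1 is anterior; P2 is fixed by
#' the fiducial-nucleus asymmetry; P3 = P1 x P2 completes a right-handed
#' triple. The origin is the embryo (hull) centroid.
#'
#' @param p1,p2 Orthonormal unit vectors (p2 is re-orthogonalized against
#'   p1 and both are normalized).
#' @param origin_um Frame origin in micrometers.
#' @param anterior_sign +1 once the anterior test has been applied to p1.
#' @return An object of class `embryo_frame` with `axes` (3x3, columns
#'   P1, P2, P3), `origin_um`, `anterior_sign`.
#' @export
embryo_frame <- function(p1, p2, origin_um = c(0, 0, 0), anterior_sign = 1) {
  p1 <- unit(p1)
  p2 <- p2 - sum(p2 * p1) * p1
  p2 <- unit(p2)
  p3 <- cross3(p1, p2)
  axes <- cbind(P1 = p1, P2 = p2, P3 = p3)
  stopifnot(abs(det(axes) - 1) < 1e-9)
  structure(list(axes = axes, origin_um = as.numeric(origin_um),
                 anterior_sign = anterior_sign),
            class = "embryo_frame")
}

#' @export
print.embryo_frame <- function(x, ...) {
  cat("<embryo_frame>\n")
  cat(sprintf("  origin: %s um\n",
              paste(sprintf("%.2f", x$origin_um), collapse = ", ")))
  for (j in 1:3) {
    cat(sprintf("  P%d: %s\n", j,
                paste(sprintf("%+.4f", x$axes[, j]), collapse = ", ")))
  }
  invisible(x)
}

#' Time-averaged embryonic long axis
#'
#' Averages the smallest-moment principal axis over a window of timepoints
#' (by default T15-T30, the ball-bean period of maximal extent). Principal
#' axes carry a sign ambiguity, so each axis is first sign-aligned to the
#' first one in the window (flipped when the dot product is negative), then
#' the mean is renormalized.
#'
#' @param summaries List of [hull_moments()] summaries.
#' @param timepoints Integer timepoint index of each summary (default
#'   `seq_along(summaries)`).
#' @param window Inclusive timepoint range used (default `c(15, 30)`).
#' @return Unit 3-vector.
#' @export
long_axis <- function(summaries, timepoints = seq_along(summaries),
                      window = c(15, 30)) {
  keep <- timepoints >= window[1] & timepoints <= window[2]
  if (!any(keep)) stop("no summaries in the averaging window", call. = FALSE)
  axes <- vapply(summaries[keep], function(s) s$principal_axes[, 1],
                 numeric(3))
  ref <- axes[, 1]
  flip <- colSums(axes * ref) < 0
  axes[, flip] <- -axes[, flip]
  unit(rowMeans(axes))
}

#' Orient the long axis toward the anterior
#'
#' The fiducial reporter is expressed more strongly anteriorly, so the side
#' of the embryo with the larger labeled-voxel count identifies the
#' anterior. Voxels are counted on each side of the plane through the
#' centroid normal to `p1`; an exact tie is an error.
#'
#' @param fiducial A nonempty fiducial [label_volume()].
#' @param p1 Long-axis unit vector.
#' @param centroid_um Embryo centroid.
#' @return `+1` if +`p1` already points anterior, `-1` otherwise.
#' @export
anterior_orientation <- function(fiducial, p1, centroid_um) {
  pts <- mask_coords_um(fiducial)
  if (nrow(pts) == 0) stop("empty fiducial mask", call. = FALSE)
  proj <- as.numeric(sweep(pts, 2, centroid_um) %*% unit(p1))
  n_pos <- sum(proj > 0)
  n_neg <- sum(proj < 0)
  if (n_pos == n_neg) {
    stop("ambiguous orientation: equal fiducial signal on both sides",
         call. = FALSE)
  }
  if (n_pos > n_neg) 1 else -1
}

#' Anisotropic embryo scale factors from moments of inertia
#'
#' Computes the two multiplicative factors (length `r_l` along P1, width
#' `r_s` along P2/P3) that bring a test embryo's ball-stage size into
#' correspondence with the reference. With `a` the moment about the long
#' axis and `b` the mean of the two short-axis moments (the embryo is
#' treated as rotationally symmetric about P1), the intermediate ratios are
#' `q1 = a_ref / a_test` and `q2 = (b_ref - a_ref/2) / (b_test - a_test/2)`,
#' and
#' \deqn{r_l = q_1^{-1/5} q_2^{2/5}, \qquad r_s = q_1^{3/10} q_2^{-1/10}.}
#' The exotic exponents arise because moments of inertia of a uniform solid
#' scale as the fifth power of distance (three powers from the mass, two
#' from the distance weighting).
#'
#' @param ref_summaries,test_summaries Lists of [hull_moments()] summaries
#'   over the ball-stage averaging window (matched developmental period).
#' @return An object of class `scale_factors` with fields `a_ref`, `a_test`,
#'   `b_ref`, `b_test`, `q1`, `q2`, `r_l`, `r_s`.
#' @export
scale_factors <- function(ref_summaries, test_summaries) {
  if (length(ref_summaries) == 0 || length(test_summaries) == 0) {
    stop("empty summary window", call. = FALSE)
  }
  ab <- function(ss) {
    m <- vapply(ss, function(s) s$principal_moments, numeric(3))
    c(a = mean(m[1, ]), b = mean((m[2, ] + m[3, ]) / 2))
  }
  r <- ab(ref_summaries); t <- ab(test_summaries)
  if (r["b"] - r["a"] / 2 <= 0 || t["b"] - t["a"] / 2 <= 0) {
    stop("geometry error: b - a/2 <= 0; input moments are not those of a genuine solid",
         call. = FALSE)
  }
  q1 <- unname(r["a"] / t["a"])
  q2 <- unname((r["b"] - r["a"] / 2) / (t["b"] - t["a"] / 2))
  structure(list(a_ref = unname(r["a"]), a_test = unname(t["a"]),
                 b_ref = unname(r["b"]), b_test = unname(t["b"]),
                 q1 = q1, q2 = q2,
                 r_l = q1^(-1 / 5) * q2^(2 / 5),
                 r_s = q1^(3 / 10) * q2^(-1 / 10)),
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("<scale_factors> r_l = %.4f, r_s = %.4f (q1 = %.4f, q2 = %.4f)\n",
              x$r_l, x$r_s, x$q1, x$q2))
  invisible(x)
}

#' @describeIn scale_factors tidy one-row summary.
#' @param x A `scale_factors` object.
#' @param ... Unused.
#' @export
tidy.scale_factors <- function(x, ...) {
  tibble::tibble(a_ref = x$a_ref, a_test = x$a_test, b_ref = x$b_ref,
                 b_test = x$b_test, q1 = x$q1, q2 = x$q2,
                 r_l = x$r_l, r_s = x$r_s)
}

#' Apply anisotropic scale factors in an embryo frame
#'
#' Scales coordinates relative to the frame origin by `r_l` along P1 and
#' `r_s` along P2 and P3. Point matrices are transformed exactly; label
#' volumes are resampled with nearest-neighbour lookup (each output voxel
#' takes the value at its inverse-scaled position).
#'
#' @param x Numeric point matrix (n x 3, micrometers) or a
#'   [label_volume()].
#' @param factors A [scale_factors()] object (or list with `r_l`, `r_s`).
#' @param frame An [embryo_frame()].
#' @return Scaled points or resampled volume, same class as `x`.
#' @export
apply_scaling <- function(x, factors, frame) {
  if (factors$r_l <= 0 || factors$r_s <= 0) {
    stop("scale factors must be positive", call. = FALSE)
  }
  A <- frame$axes
  S <- A %*% diag(c(factors$r_l, factors$r_s, factors$r_s)) %*% t(A)
  if (inherits(x, "label_volume")) {
    Sinv <- A %*% diag(1 / c(factors$r_l, factors$r_s, factors$r_s)) %*% t(A)
    idx <- which(array(TRUE, dim(x$mask)), arr.ind = TRUE)
    src_um <- sweep(sweep(index_to_um(idx, x$grid), 2, frame$origin_um) %*%
                      t(Sinv), 2, frame$origin_um, "+")
    src_idx <- um_to_index(src_um, x$grid)
    new_mask <- array(x$mask[src_idx], dim(x$mask))
    return(label_volume(new_mask, x$grid, x$channel, x$timepoint_index))
  }
  pts <- as.matrix(x)
  sweep(sweep(pts, 2, frame$origin_um) %*% t(S), 2, frame$origin_um, "+")
}
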