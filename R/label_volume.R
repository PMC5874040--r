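#' Binary label volume for one channel at one timepoint
#'
#' A boolean mask on the acquisition voxel grid. Coordinates reported in
#' micrometers use the voxel-center convention: the voxel with 1-based
#' index `i` is centered at `(i - 0.5) * voxel_size_um`.
#'
#' @param mask Logical (or coercible) 3D array matching `grid$shape_voxels`.
#' @param grid An [acquisition_grid()].
#' @param channel One of `"pan_nuclear"`, `"fiducial_gfp"`, `"reporter_gfp"`.
#' @param timepoint_index Integer timepoint.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(mask, grid, channel = c("fiducial_gfp",
                                                 "pan_nuclear",
                                                 "reporter_gfp"),
                         timepoint_index = 1L) {
  channel <- match.arg(channel)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), as.integer(grid$shape_voxels))) {
    stop(sprintf("mask shape (%s) does not match grid shape (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(grid$shape_voxels, collapse = "x")), call. = FALSE)
  }
  structure(list(mask = mask, grid = grid, channel = channel,
                 timepoint_index = as.integer(timepoint_index)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, T%d, %s voxels, %d labeled\n",
              x$channel, x$timepoint_index,
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Labeled voxel centers in micrometers
#' @param volume A `label_volume`.
#' @return Numeric matrix (n x 3) of voxel-center coordinates.
#' @export
mask_coords_um <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  idx <- which(volume$mask, arr.ind = TRUE)
  index_to_um(idx, volume$grid)
}

#' Build a label volume from micrometer points
#'
#' Marks the voxel containing each point; points may optionally be dilated
#' into solid balls of a given radius (used to voxelize nuclei).
#' @param points_um Numeric matrix (n x 3) of coordinates in micrometers.
#' @param grid An [acquisition_grid()].
#' @param channel,timepoint_index Passed to [label_volume()].
#' @param radius_um If positive, every voxel whose center lies within
#'   `radius_um` of a point is labeled.
#' @return A `label_volume`.
#' @export
voxelize_points <- function(points_um, grid, channel = "fiducial_gfp",
                            timepoint_index = 1L, radius_um = 0) {
  mask <- array(FALSE, dim = grid$shape_voxels)
  pts <- as.matrix(points_um)
  if (nrow(pts) > 0) {
    if (radius_um <= 0) {
      idx <- um_to_index(pts, grid)
      mask[idx] <- TRUE
    } else {
      r_vox <- ceiling(radius_um / grid$voxel_size_um)
      off <- as.matrix(expand.grid(x = -r_vox:r_vox, y = -r_vox:r_vox,
                                   z = -r_vox:r_vox))
      for (i in seq_len(nrow(pts))) {
        ctr <- um_to_index(pts[i, , drop = FALSE], grid)
        cand <- sweep(off, 2, as.numeric(ctr), "+")
        ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
          cand[, 1] <= grid$shape_voxels[1] &
          cand[, 2] <= grid$shape_voxels[2] &
          cand[, 3] <= grid$shape_voxels[3]
        cand <- cand[ok, , drop = FALSE]
        d2 <- rowSums((index_to_um(cand, grid) -
                         matrix(pts[i, ], nrow(cand), 3, byrow = TRUE))^2)
        mask[cand[d2 <= radius_um^2, , drop = FALSE]] <- TRUE
      }
    }
  }
  label_volume(mask, grid, channel, timepoint_index)
}

#' Subtract channel bleedthrough
#'
#' Removes red-channel bleedthrough from the green channel by subtracting a
#' fixed multiple of the red intensity (1/15 at the original imaging
#' conditions), clamping at zero since intensities are nonnegative counts.
#'
#' @param green,red Numeric arrays of identical shape (intensity volumes).
#' @param factor Nonnegative bleedthrough factor (default 1/15).
#' @return Array `pmax(green - factor * red, 0)`.
#' @examples
#' subtract_bleedthrough(array(150, c(1, 1, 1)), array(150, c(1, 1, 1)))
#' @export
subtract_bleedthrough <- function(green, red, factor = 1 / 15) {
  if (!identical(dim(green), dim(red))) {
    stop("green and red volumes must have identical shape", call. = FALSE)
  }
  stopifnot(factor >= 0)
  pmax(green - factor * red, 0)
}

# separable Gaussian blur of a 3D numeric array, sigma in voxels
gaussian_blur_3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  conv_first_dim <- function(m, k) {
    n <- nrow(m); r <- (length(k) - 1L) / 2L
    mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  d <- dim(a)
  # blur along each axis by rotating it into the first position
  a <- array(conv_first_dim(matrix(a, d[1]), k), d)
  a <- aperm(a, c(2, 3, 1))
  a <- array(conv_first_dim(matrix(a, d[2]), k), c(d[2], d[3], d[1]))
  a <- aperm(a, c(2, 3, 1))
  a <- array(conv_first_dim(matrix(a, d[3]), k), c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

#' Connected components of a 3D mask (26-connectivity)
#' @param mask Logical 3D array.
#' @return Integer array of component labels (0 = background), with the
#'   number of components as attribute `n`.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  coords <- arrayInd(idx, d)
  key <- (coords[, 3] - 1) * (d[1] * d[2]) + (coords[, 2] - 1) * d[1] + coords[, 1]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbkey <- (nb[ok, 3] - 1) * (d[1] * d[2]) + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- match(nbkey, key)
    src <- which(ok)[!is.na(hit)]
    if (length(src)) edges[[length(edges) + 1]] <- cbind(src, hit[!is.na(hit)])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  lab[idx] <- as.integer(memb)
  attr(lab, "n") <- length(unique(memb))
  lab
}

#' Refine a fiducial-nucleus segmentation mask
#'
#' Cleans a thresholded fiducial (GFP) nuclear mask for registration by
#' (optionally) restricting to the anterior half of the embryo, coring out
#' a cylinder around the nerve ring, filling gaps with a Gaussian blur
#' followed by re-thresholding at 0.5, and keeping only the largest
#' connected objects (26-connectivity), up to `max_objects`.
#'
#' @param volume A `label_volume`.
#' @param core_cylinder `NULL`, or a list with `point_um` (a point on the
#'   cylinder axis), `direction` (axis direction), `radius_um` and
#'   `half_length_um`; voxels inside are removed.
#' @param blur_sigma_um Gaussian sigma in micrometers (0 disables blurring).
#' @param max_objects Maximum number of connected objects kept (default 17,
#'   the cap used during imaging); ties in size break toward the earlier
#'   label for determinism.
#' @param anterior_half_only If `TRUE`, voxels whose coordinate along `p1`
#'   falls below the embryo centroid are removed before anything else.
#' @param p1,centroid_um Long-axis direction and embryo centroid; required
#'   when `anterior_half_only = TRUE` and for the cylinder default axis.
#' @return A refined `label_volume`.
#' @export
refine_fiducial_mask <- function(volume, core_cylinder = NULL,
                                 blur_sigma_um = 0, max_objects = 17L,
                                 anterior_half_only = FALSE,
                                 p1 = NULL, centroid_um = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  mask <- volume$mask
  grid <- volume$grid
  if (!any(mask)) return(volume)

  if (anterior_half_only) {
    if (is.null(p1) || is.null(centroid_um)) {
      stop("anterior_half_only requires p1 and centroid_um", call. = FALSE)
    }
    idx <- which(mask, arr.ind = TRUE)
    proj <- as.numeric(sweep(index_to_um(idx, grid), 2, centroid_um) %*% p1)
    mask[idx[proj < 0, , drop = FALSE]] <- FALSE
  }
  if (!is.null(core_cylinder)) {
    stopifnot(core_cylinder$radius_um > 0, core_cylinder$half_length_um > 0)
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx)) {
      u <- unit(core_cylinder$direction)
      rel <- sweep(index_to_um(idx, grid), 2, core_cylinder$point_um)
      ax <- as.numeric(rel %*% u)
      rad2 <- rowSums(rel^2) - ax^2
      inside <- abs(ax) <= core_cylinder$half_length_um &
        rad2 <= core_cylinder$radius_um^2
      mask[idx[inside, , drop = FALSE]] <- FALSE
    }
  }
  if (blur_sigma_um > 0 && any(mask)) {
    blurred <- gaussian_blur_3d(array(as.numeric(mask), dim(mask)),
                                blur_sigma_um / grid$voxel_size_um)
    mask <- blurred > 0.5
  }
  if (any(mask) && is.finite(max_objects)) {
    lab <- label_components_3d(mask)
    n <- attr(lab, "n")
    if (n > max_objects) {
      sizes <- tabulate(lab[lab > 0], nbins = n)
      keep <- order(sizes, decreasing = TRUE)[seq_len(max_objects)]
      mask <- array(lab %in% keep, dim(mask))
    }
  }
  label_volume(mask, grid, volume$channel, volume$timepoint_index)
}
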