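#' 3D convex hull by incremental insertion
#'
#' Builds the convex hull of a 3D point set. Faces are returned with
#' outward-oriented, counterclockwise vertex order (seen from outside).
#'
#' @param points Numeric matrix, one 3D point per row (>= 4 rows, not all
#'   coplanar).
#' @return List with `faces` (integer matrix, one triangle per row, indices
#'   into `points`) and `vertices` (indices of points on the hull).
#' @export
convex_hull_3d <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 3) stop("points must be 3D", call. = FALSE)
  n <- nrow(P)
  if (n < 4) stop("degenerate geometry: need at least 4 points", call. = FALSE)
  scale <- max(apply(P, 2, function(x) diff(range(x))), 1e-12)
  eps <- 1e-10 * scale

  # initial simplex: extreme pair, then furthest from line, then from plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (max(abs(P[i1, ] - P[i2, ])) < eps) {
    rng <- apply(P, 2, range)
    ax <- which.max(rng[2, ] - rng[1, ])
    i1 <- which.min(P[, ax]); i2 <- which.max(P[, ax])
  }
  d12 <- P[i2, ] - P[i1, ]
  if (sqrt(sum(d12^2)) < eps) {
    stop("degenerate geometry: all points coincident", call. = FALSE)
  }
  rel <- sweep(P, 2, P[i1, ])
  crossn <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
                  rel[, 3] * d12[1] - rel[, 1] * d12[3],
                  rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dline <- sqrt(rowSums(crossn^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps * sqrt(sum(d12^2))) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  nrm <- cross3(d12, P[i3, ] - P[i1, ])
  dplane <- abs(as.numeric(rel %*% nrm)) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) {
    stop("degenerate geometry: points are coplanar", call. = FALSE)
  }

  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  orient_out <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    if (sum(cross3(b - a, c - a) * (a - interior)) < 0) tri[c(1, 3, 2)] else tri
  }
  faces <- rbind(orient_out(c(i1, i2, i3)), orient_out(c(i1, i2, i4)),
                 orient_out(c(i1, i3, i4)), orient_out(c(i2, i3, i4)))

  face_geom <- function(faces) {
    a <- P[faces[, 1], , drop = FALSE]
    b <- P[faces[, 2], , drop = FALSE]
    c <- P[faces[, 3], , drop = FALSE]
    u <- b - a; v <- c - a
    nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
    list(normal = nrm, base = a)
  }

  todo <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (ip in todo) {
    g <- face_geom(faces)
    vis <- rowSums(g$normal * sweep(-g$base, 2, P[ip, ], "+")) >
      eps * sqrt(rowSums(g$normal^2))
    if (!any(vis)) next
    visible <- faces[vis, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    # horizon: edges of visible faces that occur exactly once among them
    ed <- rbind(visible[, c(1, 2)], visible[, c(2, 3)], visible[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- cbind(horizon, ip)
    # interior point stays inside; orient each new face outward
    for (k in seq_len(nrow(newf))) newf[k, ] <- orient_out(newf[k, ])
    faces <- rbind(faces, newf)
  }
  list(faces = unname(faces), vertices = sort(unique(as.vector(faces))))
}

#' Principal moments of inertia of a uniform-density convex hull
#'
#' Models the embryo volume as the convex hull of segmented nuclear centers
#' filled at uniform density, and computes its centroid, inertia tensor and
#' principal axes exactly, by signed tetrahedral decomposition of the hull
#' from an interior point (each face triangle forms a tetrahedron whose
#' volume and second-moment integrals have closed forms). The axis of the
#' smallest principal moment is the embryo's long (anterior-posterior) axis.
#'
#' @param points Numeric matrix of 3D nuclear centers in micrometers
#'   (>= 4 non-coplanar rows). A tibble/data frame with columns
#'   `x_um, y_um, z_um` is also accepted.
#' @return An object of class `inertia_summary`: list with `centroid_um`,
#'   `principal_moments` (ascending, unit density, mass um^2), `principal_axes`
#'   (columns matched to moments, orthonormal, right-handed),
#'   `hull_volume_um3`, and `inertia_tensor`.
#' @examples
#' cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
#' hull_moments(cube)$principal_moments  # each 1/6 for the unit cube
#' @export
hull_moments <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  }
  P <- as.matrix(points)
  hull <- convex_hull_3d(P)
  c0 <- colMeans(P[hull$vertices, , drop = FALSE])

  vol <- 0
  m1 <- c(0, 0, 0)        # first moment  (integral of x)
  S <- matrix(0, 3, 3)    # second moment (integral of x x^T), about origin
  for (k in seq_len(nrow(hull$faces))) {
    tri <- hull$faces[k, ]
    v <- rbind(c0, P[tri[1], ], P[tri[2], ], P[tri[3], ])
    V <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) / 6
    vol <- vol + V
    m1 <- m1 + V * colSums(v) / 4
    s <- colSums(v)
    # integral over a tetrahedron: V/20 * (sum_i v_i v_i' + s s')
    S <- S + V / 20 * (crossprod(v) + tcrossprod(s))
  }
  if (vol <= 0) stop("degenerate geometry: hull has nonpositive volume",
                     call. = FALSE)
  centroid <- as.numeric(m1 / vol)
  C <- S - vol * tcrossprod(centroid)      # central second moments
  inertia <- sum(diag(C)) * diag(3) - C    # unit-density inertia tensor
  eig <- eigen((inertia + t(inertia)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  moments <- eig$values[ord]
  axes <- eig$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-|component| entry positive per axis
  for (j in 1:3) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]

  structure(list(centroid_um = centroid,
                 principal_moments = moments,
                 principal_axes = axes,
                 hull_volume_um3 = vol,
                 inertia_tensor = inertia),
            class = "inertia_summary")
}

#' @export
print.inertia_summary <- function(x, ...) {
  cat("<inertia_summary>\n")
  cat(sprintf("  hull volume: %.2f um^3\n", x$hull_volume_um3))
  cat(sprintf("  centroid:    %s um\n",
              paste(sprintf("%.3f", x$centroid_um), collapse = ", ")))
  cat(sprintf("  moments:     %s\n",
              paste(sprintf("%.4g", x$principal_moments), collapse = ", ")))
  invisible(x)
}

#' @describeIn hull_moments tidy one-row summary (volume, moments, long-axis
#'   components).
#' @param x An `inertia_summary`.
#' @param ... Unused.
#' @export
tidy.inertia_summary <- function(x, ...) {
  tibble::tibble(
    hull_volume_um3 = x$hull_volume_um3,
    moment_1 = x$principal_moments[1],
    moment_2 = x$principal_moments[2],
    moment_3 = x$principal_moments[3],
    long_axis_x = x$principal_axes[1, 1],
    long_axis_y = x$principal_axes[2, 1],
    long_axis_z = x$principal_axes[3, 1]
  )
}
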