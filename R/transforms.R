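#' Rigid transforms in 2D and 3D
#'
#' A rigid transform is a proper rotation plus a translation, acting on row
#' matrices of points as `x %*% t(R) + t`. It is the unit of every
#' registration step in the alignment pipeline.
#'
#' @param rotation Square orthogonal matrix (2x2 or 3x3) with determinant +1.
#' @param translation Numeric translation vector in micrometers, one entry
#'   per dimension.
#' @return An object of class `rigid_transform` with elements `rotation`,
#'   `translation` and `dimension`.
#' @examples
#' tr <- rigid_transform(rot2(30), c(1, 2))
#' apply_transform(tr, matrix(c(0, 0), ncol = 2))
#' @export
rigid_transform <- function(rotation, translation = rep(0, nrow(rotation))) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  if (!d %in% c(2L, 3L) || ncol(rotation) != d) {
    stop("rotation must be a 2x2 or 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != d) {
    stop("translation length must match rotation dimension", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-8) {
    stop("rotation matrix is not orthogonal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation matrix must have determinant +1 (no reflections)",
         call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         dimension = d),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %dD>\n", x$dimension))
  cat(sprintf("  angle: %.4f deg\n", rotation_angle_deg(x)))
  cat(sprintf("  translation (um): %s\n",
              paste(sprintf("%.4f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Identity transform
#' @param dimension 2 or 3.
#' @return A `rigid_transform` that maps every point to itself.
#' @export
identity_transform <- function(dimension = 3L) {
  rigid_transform(diag(dimension), rep(0, dimension))
}

#' 2D rotation matrix
#' @param angle_deg Counterclockwise angle in degrees.
#' @return A 2x2 rotation matrix.
#' @export
rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' 3D rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param angle_deg Rotation angle in degrees; positive is counterclockwise
#'   about the axis by the right-hand rule.
#' @param axis Either one of `"x"`, `"y"`, `"z"` or a length-3 numeric axis.
#' @return A 3x3 rotation matrix.
#' @export
rot3 <- function(angle_deg, axis = "x") {
  if (is.character(axis)) {
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be x, y, z or a numeric vector"))
  }
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points Numeric matrix with one point per row (or a single vector).
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, nrow = 1) else as.matrix(points)
  if (ncol(pts) != transform$dimension) {
    stop("point dimension does not match transform dimension", call. = FALSE)
  }
  out <- pts %*% t(transform$rotation) +
    matrix(transform$translation, nrow(pts), transform$dimension, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first and
#' then `a` (i.e. `a(b(x))`), matching matrix-composition order.
#' @param a,b `rigid_transform` objects of equal dimension.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"),
            a$dimension == b$dimension)
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#'
#' In 2D, the signed counterclockwise angle; in 3D, the (nonnegative)
#' axis-angle magnitude.
#' @param transform A `rigid_transform`.
#' @return Angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  R <- transform$rotation
  if (transform$dimension == 2) {
    atan2(R[2, 1], R[1, 1]) * 180 / pi
  } else {
    # clamp: numerical noise can push the trace argument out of [-1, 1]
    acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  }
}

#' Axis-angle view of a 3D rotation
#' @param transform A 3D `rigid_transform`.
#' @return List with unit `axis` and `angle_deg` (>= 0).
#' @export
rotation_axis_angle <- function(transform) {
  stopifnot(transform$dimension == 3)
  R <- transform$rotation
  ang <- rotation_angle_deg(transform)
  if (ang < 1e-9) return(list(axis = c(1, 0, 0), angle_deg = 0))
  if (abs(ang - 180) < 1e-6) {
    # R = 2 u u^T - I at half-turn
    B <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(B), 0))
    i <- which.max(u)
    s <- sign(B[i, ])
    s[s == 0] <- 1
    u <- u * s / s[i]
    return(list(axis = u / sqrt(sum(u^2)), angle_deg = 180))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  list(axis = v / sqrt(sum(v^2)), angle_deg = ang)
}

#' Scale a 3D rotation toward the identity
#'
#' Multiplies the axis-angle magnitude by `factor`, leaving the axis fixed.
#' Used by the rotation-damped registration variant.
#' @param rotation 2x2 or 3x3 rotation matrix.
#' @param factor Multiplier in (0, 1].
#' @return A rotation matrix.
#' @keywords internal
damp_rotation <- function(rotation, factor) {
  d <- nrow(rotation)
  if (d == 2) {
    ang <- atan2(rotation[2, 1], rotation[1, 1]) * 180 / pi
    rot2(ang * factor)
  } else {
    aa <- rotation_axis_angle(rigid_transform(rotation))
    rot3(aa$angle_deg * factor, aa$axis)
  }
}

#' Closed-form least-squares rigid transform from known correspondences
#'
#' Solves the orthogonal Procrustes problem for paired point sets by SVD
#' (the Kabsch algorithm), with the usual reflection correction so the
#' result is a proper rotation. Exact for noiseless rigidly-related pairs;
#' serves as the closed-form oracle against which the iterative
#' registration is checked. Three non-collinear correspondences suffice to
#' determine a 3D rigid transform; two leave a one-parameter family of
#' rotations about the connecting axis and are rejected.
#'
#' @param source,target Equal-size numeric matrices of corresponded points
#'   (one point per row, 2 or 3 columns).
#' @param weights Optional nonnegative per-pair weights.
#' @return A `rigid_transform` mapping `source` onto `target`.
#' @export
kabsch <- function(source, target, weights = NULL) {
  X <- as.matrix(source)
  Y <- as.matrix(target)
  if (!all(dim(X) == dim(Y))) stop("source/target sizes differ", call. = FALSE)
  d <- ncol(X)
  if (!d %in% c(2L, 3L)) stop("points must be 2D or 3D", call. = FALSE)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  if (n < d) {
    stop(sprintf(
      "degenerate configuration: %d correspondences cannot determine a %dD rigid transform (rotational ambiguity about the connecting axis)",
      n, d), call. = FALSE)
  }
  w <- weights / sum(weights)
  mx <- colSums(X * w)
  my <- colSums(Y * w)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  # rank check: collinear 3D / coincident 2D configurations are ambiguous
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[d - 1] < 1e-9 * max(sv_x[1], 1e-300)) {
    stop(paste0(
      "degenerate configuration: points are ",
      if (d == 3) "collinear" else "coincident",
      "; the rotation is not uniquely determined"), call. = FALSE)
  }
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  S <- diag(d)
  S[d, d] <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, my - as.numeric(R %*% mx))
}
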