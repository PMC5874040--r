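#' Parameters for coherent-point-drift rigid registration
#'
#' The registration models the moving cloud as centroids of an isotropic
#' Gaussian mixture fit to the fixed cloud by expectation-maximization, with
#' a uniform outlier component, under a deterministic-annealing schedule
#' that shrinks the Gaussian width geometrically from a coarse,
#' data-scale width down to a floor, moving the correspondence problem from
#' coarse to fine.
#'
#' @param outlier_weight Mixture weight `w` of the uniform outlier
#'   component, in `[0, 1)`.
#' @param max_iterations Maximum EM iterations.
#' @param tolerance Convergence tolerance on the relative change of the
#'   negative log-likelihood once the width floor is reached.
#' @param initial_width_um Starting Gaussian standard deviation; `NULL`
#'   sets it from the data scale (RMS spread of the joint cloud).
#' @param final_width_um Width floor; `NULL` sets `initial_width_um / 100`.
#' @param anneal Geometric per-iteration width decay factor in (0, 1).
#' @param rotation_damping `NULL` for the plain algorithm, or a list with
#'   `damping_factor` in (0, 1] and `release_width_um` (Gaussian width below
#'   which full rotations are gradually reintroduced; `NULL` means twice the
#'   mean nearest-neighbour spacing of the fixed cloud).
#' @param polish If `TRUE`, follow EM convergence with one hard-assignment
#'   (nearest-neighbour, distance-gated) Procrustes step, which snaps exact
#'   correspondences to machine precision. Disable for clouds quantized on
#'   a shared voxel lattice, where hard assignment biases toward the
#'   lattice; the damped variant never polishes.
#' @return A list of class `cpd_params`.
#' @export
cpd_params <- function(outlier_weight = 0.1,
                       max_iterations = 200L,
                       tolerance = 1e-6,
                       initial_width_um = NULL,
                       final_width_um = NULL,
                       anneal = 0.93,
                       rotation_damping = NULL,
                       polish = TRUE) {
  stopifnot(outlier_weight >= 0, outlier_weight < 1,
            max_iterations >= 1, tolerance > 0,
            anneal > 0, anneal < 1)
  if (!is.null(initial_width_um)) stopifnot(initial_width_um > 0)
  if (!is.null(final_width_um)) stopifnot(final_width_um > 0)
  if (!is.null(rotation_damping)) {
    stopifnot(is.list(rotation_damping),
              rotation_damping$damping_factor > 0,
              rotation_damping$damping_factor <= 1)
  }
  structure(list(outlier_weight = outlier_weight,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 initial_width_um = initial_width_um,
                 final_width_um = final_width_um,
                 anneal = anneal,
                 rotation_damping = rotation_damping,
                 polish = isTRUE(polish)),
            class = "cpd_params")
}

mean_nn_spacing <- function(points) {
  if (nrow(points) < 2) return(1)
  nn <- RANN::nn2(points, points, k = 2)
  mean(nn$nn.dists[, 2])
}

#' Rigid point-set registration by coherent point drift
#'
#' Registers `source` onto `target` with a rotation and translation (no
#' scaling). Each EM iteration computes soft correspondences under the
#' current Gaussian width and solves the weighted orthogonal Procrustes
#' problem in closed form. The procedure is fully deterministic: there is
#' no internal randomness, so identical inputs and parameters always give
#' identical results.
#'
#' With `params$rotation_damping` set (see [cpd_rigid_damped()]), the
#' per-iteration rotation increment is shrunk toward the identity while the
#' annealing width is above the release width, permitting translations of
#' arbitrary size but only rotations that match points to nearby points;
#' full rotations are reintroduced linearly as the width drops from the
#' release width to the floor.
#'
#' @param source,target Numeric matrices of points (rows), 2 or 3 columns,
#'   same dimension.
#' @param params A [cpd_params()] object.
#' @return A `rigid_transform` mapping `source` toward `target`, with
#'   attributes `converged` (logical; `FALSE` flags best-so-far return at
#'   the iteration cap), `iterations`, and `sigma_um` (final width).
#' @export
cpd_rigid <- function(source, target, params = cpd_params()) {
  Y <- as.matrix(source)
  X <- as.matrix(target)
  if (nrow(Y) == 0 || nrow(X) == 0) stop("empty point set", call. = FALSE)
  if (ncol(Y) != ncol(X)) stop("dimension mismatch", call. = FALSE)
  d <- ncol(X)
  if (!d %in% c(2L, 3L)) stop("points must be 2D or 3D", call. = FALSE)
  M <- nrow(Y); N <- nrow(X)
  w <- params$outlier_weight

  joint <- rbind(X, Y)
  data_scale <- sqrt(mean(rowSums(
    sweep(joint, 2, colMeans(joint))^2)))
  if (data_scale == 0) data_scale <- 1
  sigma0 <- params$initial_width_um %||% data_scale
  sigma_floor <- params$final_width_um %||% (sigma0 / 100)
  sigma_floor <- min(sigma_floor, sigma0)

  damp <- params$rotation_damping
  if (!is.null(damp)) {
    release <- damp$release_width_um %||% (2 * mean_nn_spacing(X))
    release <- max(release, sigma_floor)
  }

  R <- diag(d)
  tr <- colMeans(X) - colMeans(Y)   # coarse start: match centroids
  sigma <- sigma0
  q_old <- Inf
  converged <- FALSE
  iters <- 0L
  floor_iters <- 0L

  for (it in seq_len(params$max_iterations)) {
    iters <- it
    TY <- Y %*% t(R) + matrix(tr, M, d, byrow = TRUE)
    cst <- (2 * pi * sigma^2)^(d / 2) * w / (1 - w + 1e-12) * M / N
    es <- .cpd_estep(TY, X, sigma, cst)
    q <- es$neg_loglik
    P1 <- es$P1
    Pt1 <- es$Pt1
    Np <- sum(P1)
    if (Np < 1e-12) break
    mu_x <- as.numeric(crossprod(X, Pt1)) / Np
    mu_y <- as.numeric(crossprod(Y, P1)) / Np
    # A = sum_{m,n} P[m,n] (X[n]-mu_x)(Y[m]-mu_y)^T from the statistics
    PXc <- es$PX - outer(P1, mu_x)
    A <- crossprod(PXc, sweep(Y, 2, mu_y))
    sv <- svd(A)
    C <- diag(d); C[d, d] <- sign(det(sv$u %*% t(sv$v)))
    R_new <- sv$u %*% C %*% t(sv$v)

    if (!is.null(damp)) {
      f <- if (sigma > release) {
        damp$damping_factor
      } else if (release > sigma_floor) {
        # linear release: factor -> 1 as sigma -> floor
        damp$damping_factor + (1 - damp$damping_factor) *
          (release - sigma) / (release - sigma_floor)
      } else 1
      R_inc <- R_new %*% t(R)
      R_new <- damp_rotation(R_inc, f) %*% R
      # re-orthonormalize against drift
      svr <- svd(R_new)
      R_new <- svr$u %*% t(svr$v)
    }
    tr_new <- mu_x - as.numeric(R_new %*% mu_y)
    # parameter change this iteration (the likelihood lags one step)
    d_ang <- rotation_angle_deg(rigid_transform(R_new %*% t(R)))
    d_tr <- sqrt(sum((tr_new - tr)^2))
    R <- R_new
    tr <- tr_new

    at_floor <- sigma <= sigma_floor * (1 + 1e-12)
    if (at_floor) floor_iters <- floor_iters + 1L
    if (at_floor && abs(q_old - q) < params$tolerance * (abs(q) + 1) &&
        (floor_iters >= 25L || (abs(d_ang) < 1e-7 && d_tr < 1e-7))) {
      converged <- TRUE
      break
    }
    q_old <- q
    sigma <- max(sigma * params$anneal, sigma_floor)
  }

  if (params$polish && is.null(damp) && nrow(Y) >= d + 1) {
    # hard-assignment Procrustes polish: match each moved source point to
    # its nearest target, gate by distance, and resolve in closed form
    TY <- Y %*% t(R) + matrix(tr, M, d, byrow = TRUE)
    nn <- RANN::nn2(X, TY, k = 1)
    gate <- nn$nn.dists[, 1] <=
      max(2.5 * stats::median(nn$nn.dists[, 1]), 1e-9)
    if (sum(gate) >= d + 1) {
      polished <- tryCatch(
        kabsch(Y[gate, , drop = FALSE], X[nn$nn.idx[gate, 1], , drop = FALSE]),
        error = function(e) NULL)
      if (!is.null(polished)) {
        R <- polished$rotation
        tr <- polished$translation
      }
    }
  }

  out <- rigid_transform(R, tr)
  attr(out, "converged") <- converged ||
    iters < params$max_iterations
  attr(out, "iterations") <- iters
  attr(out, "sigma_um") <- sigma
  if (!attr(out, "converged")) {
    warning("registration did not converge; returning best-so-far transform",
            call. = FALSE)
  }
  out
}

#' Rotation-damped rigid registration
#'
#' Variant of [cpd_rigid()] that biases against rotations by directly
#' reducing the size of the rotation computed at each M-step until the
#' annealing width has dropped to a release width, after which full
#' rotations are gradually reintroduced. Translations are never damped.
#' The effect is to permit only rotations that match points to nearby
#' points, avoiding large-rotation local optima.
#'
#' @inheritParams cpd_rigid
#' @param damping_factor Multiplier in (0, 1] applied to the M-step rotation
#'   increment while the width is above `release_width_um`.
#' @param release_width_um Gaussian width below which damping relaxes
#'   linearly back to 1; `NULL` means twice the mean nearest-neighbour
#'   spacing of the target cloud.
#' @return A `rigid_transform`, as [cpd_rigid()].
#' @export
cpd_rigid_damped <- function(source, target, params = cpd_params(),
                             damping_factor = 0.1,
                             release_width_um = NULL) {
  params$rotation_damping <- list(damping_factor = damping_factor,
                                  release_width_um = release_width_um)
  cpd_rigid(source, target, params)
}
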