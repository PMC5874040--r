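# Shared fixtures: small grids and synthetic bundles, built once per run.
# Problem sizes are scaled down (coarser voxels, short fast phase) so the
# suite stays fast; the statistical structure matches the generator
# defaults.

small_grid <- function(fast_count = 16L, voxel = 0.65) {
  acquisition_grid(voxel_size_um = voxel,
                   shape_voxels = c(96L, 48L, 48L),
                   fast_count = as.integer(fast_count))
}

# memoized bundles so expensive simulations run once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

reference_bundle <- function() {
  cached("ref", {
    g <- small_grid()
    simulate_embryo(synthetic_embryo_spec(
      seed = 101L, grid = g, temporal_offset_min = 0, theta0_deg = 20,
      reporter_timepoints = fast_timepoints(g)))
  })
}

test_bundle_30deg <- function() {
  cached("test30", {
    g <- small_grid()
    simulate_embryo(synthetic_embryo_spec(
      seed = 202L, grid = g, temporal_offset_min = -10,
      total_rotation_deg = 30, length_scale = 1.03, width_scale = 0.99,
      reporter_timepoints = max(fast_timepoints(g))))
  })
}

fast_config <- function(...) {
  align_config(seed = 5L, ...)
}

# dense point sample on an ellipsoid surface (for hull oracles)
ellipsoid_surface <- function(n, semi = c(25, 12.5, 12.5), seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  sweep(u / sqrt(rowSums(u^2)), 2, semi, "*")
}

# closed-form solid-ellipsoid moments (unit density), ascending
ellipsoid_moments <- function(semi) {
  m <- 4 / 3 * pi * prod(semi)
  sort(m / 5 * c(semi[2]^2 + semi[3]^2,
                 semi[1]^2 + semi[3]^2,
                 semi[1]^2 + semi[2]^2))
}

# Monte-Carlo voxel-fill oracle for hull moments: rejection-sample points
# in the hull's bounding box, keep those inside the hull (all face-plane
# tests), and average.
mc_hull_moments <- function(points, n = 2e5, seed = 1) {
  set.seed(seed)
  hull <- convex_hull_3d(points)
  P <- as.matrix(points)
  faces <- hull$faces
  a <- P[faces[, 1], , drop = FALSE]
  nrm <- t(vapply(seq_len(nrow(faces)), function(k) {
    v1 <- P[faces[k, 2], ] - P[faces[k, 1], ]
    v2 <- P[faces[k, 3], ] - P[faces[k, 1], ]
    c(v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1])
  }, numeric(3)))
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  X <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inside <- rep(TRUE, n)
  for (k in seq_len(nrow(faces))) {
    inside <- inside &
      (sweep(X, 2, a[k, ]) %*% nrm[k, ])[, 1] <= 1e-12
    }
  Xi <- X[inside, , drop = FALSE]
  vol <- prod(hi - lo) * nrow(Xi) / n
  ctr <- colMeans(Xi)
  Xc <- sweep(Xi, 2, ctr)
  C <- crossprod(Xc) / nrow(Xi) * vol
  I <- sum(diag(C)) * diag(3) - C
  list(volume = vol, centroid = ctr,
       moments = sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values))
}

# exhaustive threshold-sweep oracle for plateau detection
brute_force_plateaus <- function(series, increment = 0.05, min_run = 15) {
  n <- nrow(series)
  pc <- c(NA, abs(100 * diff(series$count) / pmax(series$count[-n], 1e-12)))
  res <- list()
  for (w in list(low = c(120, 220), high = c(220, 350))) {
    in_win <- series$count > w[1] & series$count <= w[2]
    found <- NULL
    for (thr in seq(0, 100, by = increment)) {
      qual <- which(in_win & !is.na(pc) & pc <= thr + 1e-12)
      if (length(qual) == 0) next
      runs <- split(qual, cumsum(c(1, diff(qual) != 1)))
      lens <- lengths(runs)
      if (max(lens) > min_run) {
        run <- runs[[which.max(lens)]]
        found <- list(time = mean(series$time_min[run]), thr = thr,
                      n = length(run))
        break
      }
    }
    res[[length(res) + 1]] <- found
  }
  res[!vapply(res, is.null, logical(1))]
}

expect_plateaus_match_brute_force <- function(series) {
  got <- detect_plateaus(series)
  want <- brute_force_plateaus(series)
  testthat::expect_equal(nrow(got), length(want))
  for (i in seq_along(want)) {
    testthat::expect_equal(got$plateau_time_min[i], want[[i]]$time)
    testthat::expect_equal(got$threshold_used[i], want[[i]]$thr)
    testthat::expect_equal(got$n_members[i], want[[i]]$n)
  }
}

random_rotation_3d <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
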