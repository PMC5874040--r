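make_cloud <- function(n, d = 2, seed = 1, scale = 10) {
  set.seed(seed)
  matrix(runif(n * d, -scale, scale), ncol = d)
}

test_that("cpd_rigid recovers known rotations and translations", {
  X <- make_cloud(200, 2, seed = 2)
  tgt <- sweep(X %*% t(rot2(10)), 2, c(3, -2), "+")
  tr <- cpd_rigid(X, tgt)
  expect_equal(rotation_angle_deg(tr), 10, tolerance = 0.1)
  expect_equal(tr$translation, c(3, -2), tolerance = 0.05)

  same <- cpd_rigid(X, X)
  expect_lt(abs(rotation_angle_deg(same)), 1e-6)
  expect_lt(max(abs(same$translation)), 1e-6)

  X3 <- make_cloud(300, 3, seed = 3)
  tgt3 <- sweep(X3 %*% t(rot3(7, c(0, 0, 1))), 2, c(1, 2, -1), "+")
  tr3 <- cpd_rigid(X3, tgt3)
  expect_equal(rotation_angle_deg(tr3), 7, tolerance = 0.1)
  expect_lt(max(abs(apply_transform(tr3, X3) - tgt3)), 0.05)
})

test_that("cpd_rigid is robust to uniform outliers", {
  set.seed(9)
  X <- make_cloud(200, 2, seed = 4)
  tgt <- X %*% t(rot2(8))
  out <- matrix(runif(2 * 20, -15, 15), ncol = 2)   # 10% outliers
  tr <- cpd_rigid(X, rbind(tgt, out),
                  cpd_params(outlier_weight = 0.1))
  expect_lt(abs(rotation_angle_deg(tr) - 8), 1)
})

test_that("cpd_rigid agrees with the kabsch oracle on noiseless rigid pairs", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(3 * 150, 0, 8), ncol = 3)
    R <- rot3(runif(1, -15, 15), rnorm(3))
    t <- rnorm(3, 0, 3)
    Y <- sweep(X %*% t(R), 2, t, "+")
    est <- cpd_rigid(X, Y)
    oracle <- kabsch(X, Y)
    dR <- est$rotation %*% t(oracle$rotation)
    expect_lt(abs(rotation_angle_deg(rigid_transform(dR))), 0.1)
    expect_lt(sqrt(sum((est$translation - oracle$translation)^2)), 0.05)
  }
})

test_that("registration is equivariant under a common rigid conjugation", {
  X <- make_cloud(150, 2, seed = 5)
  Y <- X %*% t(rot2(6))
  base <- rotation_angle_deg(cpd_rigid(X, Y))
  G <- rot2(47)
  g <- c(4, -7)
  conj <- rotation_angle_deg(cpd_rigid(sweep(X %*% t(G), 2, g, "+"),
                                       sweep(Y %*% t(G), 2, g, "+")))
  expect_equal(conj, base, tolerance = 0.2)
})

test_that("deterministic: identical inputs give identical transforms", {
  X <- make_cloud(100, 2, seed = 6)
  Y <- X %*% t(rot2(4))
  t1 <- cpd_rigid(X, Y)
  t2 <- cpd_rigid(X, Y)
  expect_identical(t1$rotation, t2$rotation)
  expect_identical(t1$translation, t2$translation)
})

test_that("damped variant matches plain CPD for small true rotations", {
  X <- make_cloud(200, 2, seed = 7)
  Y <- X %*% t(rot2(1.5))
  plain <- rotation_angle_deg(cpd_rigid(X, Y))
  damped <- rotation_angle_deg(cpd_rigid_damped(X, Y))
  expect_equal(damped, plain, tolerance = 0.2)
})

test_that("damped variant recovers pure translations without spurious rotation", {
  X <- make_cloud(300, 3, seed = 8)
  Y <- sweep(X, 2, c(5, 0, 0), "+")
  tr <- cpd_rigid_damped(X, Y)
  expect_lt(abs(rotation_angle_deg(tr)), 0.5)
  expect_equal(tr$translation, c(5, 0, 0), tolerance = 0.1)
})

# A two-optimum fixture: a cloud with approximate 3-fold structure plus a
# marker making the identity the global optimum. Undamped annealing falls
# into the ~60 degree local optimum on this construction; damping holds the
# rotation near the identity basin.
bimodal_fixture <- function() {
  set.seed(13)
  ang <- runif(400, 0, 2 * pi)
  r <- runif(400, 7, 10)
  base <- cbind(r * cos(3 * ang) * cos(ang), r * cos(3 * ang) * sin(ang))
  marker <- cbind(runif(60, 11, 13), runif(60, -1, 1))
  rbind(base, marker)
}

test_that("rotation damping avoids a large-rotation local optimum", {
  X <- bimodal_fixture()
  # target: same shape, tiny true rotation
  Y <- X %*% t(rot2(2))
  # brute-force likelihood scan confirms a secondary optimum far from 0
  sse_at <- function(a) {
    Xr <- X %*% t(rot2(a))
    sum(RANN::nn2(Y, Xr, k = 1)$nn.dists^2)
  }
  angles <- seq(-180, 180, by = 5)
  sse <- vapply(angles, sse_at, numeric(1))
  local_opts <- angles[which(sse < stats::quantile(sse, 0.2))]
  expect_true(any(abs(local_opts) > 45))  # far-from-identity basin exists

  damped <- cpd_rigid_damped(X, Y, cpd_params(anneal = 0.9),
                             damping_factor = 0.05)
  expect_lt(abs(rotation_angle_deg(damped)), 10)
})

test_that("returned rotations are exactly orthogonal with unit determinant", {
  X <- make_cloud(100, 3, seed = 10)
  Y <- X %*% t(rot3(12, c(1, 0, 1)))
  for (tr in list(cpd_rigid(X, Y), cpd_rigid_damped(X, Y))) {
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-9)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
})

test_that("dimension mismatches and empty clouds are errors", {
  expect_error(cpd_rigid(matrix(0, 0, 2), make_cloud(10)), "empty")
  expect_error(cpd_rigid(make_cloud(10, 2), make_cloud(10, 3)),
               "dimension mismatch")
})
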