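tiny_grid <- acquisition_grid(voxel_size_um = 0.1625,
                              shape_voxels = c(20L, 20L, 20L))

vol_from_idx <- function(idx, grid = tiny_grid) {
  mask <- array(FALSE, grid$shape_voxels)
  mask[idx] <- TRUE
  label_volume(mask, grid, "reporter_gfp", 1L)
}

# brute-force all-pairs overlap oracle
brute_overlap <- function(test, ref, radius_um = 1) {
  pt <- mask_coords_um(test); pr <- mask_coords_um(ref)
  d <- as.matrix(stats::dist(rbind(pt, pr)))[seq_len(nrow(pt)),
                                             nrow(pt) + seq_len(nrow(pr)),
                                             drop = FALSE]
  c(mean(apply(d, 1, min) <= radius_um + 1e-9),
    mean(apply(d, 2, min) <= radius_um + 1e-9))
}

test_that("overlap fraction matches the brute-force all-pairs oracle exactly", {
  a <- vol_from_idx(cbind(3:7, 3:7, 3:7))
  expect_equal(unname(overlap_fraction(a, a)), c(1, 1))

  # two single voxels 10 um apart (different grid so they fit)
  g2 <- acquisition_grid(voxel_size_um = 1, shape_voxels = c(15L, 5L, 5L))
  v1 <- label_volume(array(c(TRUE, rep(FALSE, 374)), c(15, 5, 5)), g2)
  m2 <- array(FALSE, c(15, 5, 5)); m2[11, 1, 1] <- TRUE
  v2 <- label_volume(m2, g2)
  expect_equal(unname(overlap_fraction(v1, v2)), c(0, 0))

  # two 5^3 cubes offset 4 voxels (0.65 um) along x
  set.seed(2)
  c1 <- vol_from_idx(as.matrix(expand.grid(3:7, 3:7, 3:7)))
  c2 <- vol_from_idx(as.matrix(expand.grid(7:11, 3:7, 3:7)))
  expect_equal(unname(overlap_fraction(c1, c2)), brute_overlap(c1, c2))
  # random sparse masks, exact agreement
  r1 <- vol_from_idx(cbind(sample(20, 30, TRUE), sample(20, 30, TRUE),
                           sample(20, 30, TRUE)))
  r2 <- vol_from_idx(cbind(sample(20, 25, TRUE), sample(20, 25, TRUE),
                           sample(20, 25, TRUE)))
  expect_equal(unname(overlap_fraction(r1, r2)), brute_overlap(r1, r2))

  # radius limits: huge radius -> 1; tiny radius -> exact intersection
  expect_equal(unname(overlap_fraction(c1, c2, radius_um = 100)), c(1, 1))
  inter <- sum(c1$mask & c2$mask)
  expect_equal(unname(overlap_fraction(c1, c2, radius_um = 1e-9)),
               c(inter / sum(c1$mask), inter / sum(c2$mask)))

  # empty mask: fraction 0 with QC note
  e <- vol_from_idx(matrix(integer(0), 0, 3))
  ov <- overlap_fraction(e, c1)
  expect_equal(as.numeric(ov), c(0, 0))
  expect_false(is.null(attr(ov, "qc")))
  expect_error(overlap_fraction(v1, c1), "different grids")
})

circle_trace <- function(n = 72, r = 6, center = c(0, 0, 0), R = diag(3)) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-1]
  sweep(cbind(0, r * cos(a), r * sin(a)) %*% t(R), 2, center, "+")
}

test_that("plane fits recover circles and their tilts", {
  tr <- circle_trace()
  line <- list(point_um = c(0, 0, 0), split_direction = c(0, 0, 1))
  fit <- fit_nr_plane(tr, line)
  expect_equal(abs(fit$out), c(1, 0, 0), tolerance = 1e-6)
  expect_gt(fit$out[1], 0)  # hemisphere convention: +x
  expect_equal(fit$centroid_um, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(abs(sum(fit$out * fit$side_to_side)), 1e-9)
  expect_lt(abs(sum(fit$out * fit$forward)), 1e-9)

  # 10-degree tilt about y: out vectors 10 degrees apart
  R <- rot3(10, "y")
  fit2 <- fit_nr_plane(circle_trace(R = R), line)
  ang <- rad2deg(acos(sum(fit$out * fit2$out)))
  expect_equal(ang, 10, tolerance = 0.5)
})

test_that("plane fitting is rotation-equivariant", {
  set.seed(9)
  tr <- circle_trace(60, 5)
  line <- list(point_um = c(0, 0, 0), split_direction = c(0, 0, 1))
  base <- fit_nr_plane(tr, line)
  R <- rot3(37, c(1, 2, 0.5))
  rot_line <- list(point_um = c(0, 0, 0),
                   split_direction = as.numeric(R %*% c(0, 0, 1)))
  rot_fit <- fit_nr_plane(tr %*% t(R), rot_line,
                          hemisphere = as.numeric(R %*% c(1, 0, 0)))
  expect_equal(rot_fit$out, as.numeric(R %*% base$out), tolerance = 1e-6)
  expect_equal(rot_fit$side_to_side, as.numeric(R %*% base$side_to_side),
               tolerance = 1e-6)
})

test_that("vector-decomposition fit resists non-planar cell-body stubs", {
  # circle with two short out-of-plane hooks near the ventral arm ends
  # (mimicking the cell-body regions, which exit the ring plane in
  # opposite senses on the two sides)
  tr <- circle_trace(72, 6)
  stub <- function(base, dir, n = 6) {
    sweep(outer(seq(0.4, 2.0, length.out = n), dir), 2, base, "+")
  }
  tr_stub <- rbind(tr, stub(c(0, 5.9, -0.8), c(1, 0, 0)),
                   stub(c(0, -5.9, -0.8), c(-1, 0, 0)))
  line <- list(point_um = c(0, 0, 0), split_direction = c(0, 0, 1))
  fit <- fit_nr_plane(tr_stub, line)
  ang_fit <- rad2deg(acos(min(abs(fit$out[1]), 1)))
  expect_lt(ang_fit, 2)
  # ordinary least-squares plane (smallest principal component) tilts more
  ctr <- colMeans(tr_stub)
  ls_normal <- svd(sweep(tr_stub, 2, ctr))$v[, 3]
  ang_ls <- rad2deg(acos(min(abs(ls_normal[1]), 1)))
  expect_gt(ang_ls, ang_fit)
})

test_that("plane fit validates arm splits and trace geometry", {
  tr <- circle_trace()
  bad_line <- list(point_um = c(0, 0, 100), split_direction = c(0, 0, 1))
  expect_error(fit_nr_plane(tr, bad_line), "arm")
  expect_error(neurite_trace(tr[1:5, ]), "at least 10")
  jumpy <- rbind(tr, c(100, 0, 0))
  expect_error(neurite_trace(jumpy), "closer than 5")
})

test_that("centroid and plane-angle deviations match direct computation", {
  expect_error(centroid_deviation(matrix(0, 1, 3)), ">= 2")
  same <- matrix(1, 4, 3)
  expect_equal(centroid_deviation(same)$deviation_um, rep(0, 4))
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(centroid_deviation(two)$deviation_um, c(1, 1))
  set.seed(10)
  P <- matrix(rnorm(30), 10, 3)
  got <- centroid_deviation(P)
  want <- sqrt(rowSums(sweep(P, 2, colMeans(P))^2))
  expect_equal(got$deviation_um, want)
  # permutation invariance (as a set)
  perm <- sample(10)
  expect_equal(sort(centroid_deviation(P[perm, ])$deviation_um),
               sort(got$deviation_um))

  eq <- matrix(rep(c(0, 0, 1), 3), 3, 3, byrow = TRUE)
  expect_equal(plane_angle_deviation(eq)$angle_deg, rep(0, 3))
  pair <- rbind(as.numeric(rot3(5, "y") %*% c(1, 0, 0)),
                as.numeric(rot3(-5, "y") %*% c(1, 0, 0)))
  expect_equal(plane_angle_deviation(pair)$angle_deg, c(5, 5),
               tolerance = 1e-9)
  V <- matrix(rnorm(15), 5, 3)
  V <- V * sign(V[, 1])   # hemisphere-consistent
  gotv <- plane_angle_deviation(V)
  m <- unit(colSums(V / sqrt(rowSums(V^2))))
  wantv <- rad2deg(acos(pmin(1, (V / sqrt(rowSums(V^2))) %*% m)))
  expect_equal(gotv$angle_deg, as.numeric(wantv))
  expect_error(plane_angle_deviation(rbind(c(1, 0, 0), c(-1, 0, 0))),
               "zero-norm")
})
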