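test_that("perpendicular axes follow the projected posterior-to-anterior vector", {
  grid <- acquisition_grid(voxel_size_um = 1, shape_voxels = c(60L, 30L, 30L))
  ctr <- grid_extent_um(grid) / 2
  blob <- function(at) voxelize_points(matrix(at + ctr, 1), grid,
                                       radius_um = 2)$mask
  vol <- label_volume(blob(c(20, 5, 0)) | blob(c(-20, -5, 0)), grid)
  ax <- perpendicular_axes(vol, c(1, 0, 0), ctr)
  expect_equal(ax$p2, c(0, 1, 0), tolerance = 1e-6)
  expect_equal(ax$p3, c(0, 0, 1), tolerance = 1e-6)

  # posterior-to-anterior vector parallel to P1: ambiguous
  on_axis <- label_volume(blob(c(20, 0, 0)) | blob(c(-20, 0, 0)), grid)
  expect_error(perpendicular_axes(on_axis, c(1, 0, 0), ctr),
               "ambiguous|parallel")
  one_side <- label_volume(blob(c(20, 5, 0)), grid)
  expect_error(perpendicular_axes(one_side, c(1, 0, 0), ctr), "one side")
})

test_that("anterior orientation picks the side with more fiducial signal", {
  grid <- acquisition_grid(voxel_size_um = 1, shape_voxels = c(60L, 30L, 30L))
  ctr <- grid_extent_um(grid) / 2
  ant <- voxelize_points(sweep(matrix(c(15, 0, 0, 18, 2, 1), 2, 3,
                                      byrow = TRUE), 2, ctr, "+"),
                         grid, radius_um = 2)
  expect_equal(anterior_orientation(ant, c(1, 0, 0), ctr), 1)
  expect_equal(anterior_orientation(ant, c(-1, 0, 0), ctr), -1)
  # mirror-symmetric mask: tie
  sym <- voxelize_points(sweep(matrix(c(15, 0, 0, -15, 0, 0), 2, 3,
                                      byrow = TRUE), 2, ctr, "+"),
                         grid, radius_um = 2)
  expect_error(anterior_orientation(sym, c(1, 0, 0), ctr), "ambiguous")
})

test_that("coarse alignment returns the inverse of the applied P2 rotation", {
  f_ref <- embryo_frame(c(1, 0, 0), c(0, 1, 0))
  expect_equal(coarse_align(f_ref, f_ref), 0)
  p2_rot <- as.numeric(rot3(30, "x") %*% c(0, 1, 0))
  f_test <- embryo_frame(c(1, 0, 0), p2_rot)
  expect_equal(coarse_align(f_test, f_ref), -30, tolerance = 1e-9)
  # random frames: applying the returned rotation aligns P2 with P2_ref
  set.seed(5)
  for (i in 1:5) {
    p1 <- unit(rnorm(3))
    a <- embryo_frame(p1, rnorm(3))
    b <- embryo_frame(p1, rnorm(3))
    ang <- coarse_align(a, b)
    p2_new <- as.numeric(rot3(ang, p1) %*% a$axes[, 2])
    expect_gt(sum(p2_new * b$axes[, 2]), 1 - 1e-9)
  }
})

test_that("per-timepoint refinement caps large rotations and flags them", {
  set.seed(6)
  X <- matrix(runif(450, -8, 8), ncol = 3)
  Y <- X %*% t(rot3(20, "x"))
  tr <- refine_per_timepoint(X, Y, cpd_params(), cap_deg = 10)
  expect_true(attr(tr, "qc_capped"))
  expect_lte(abs(rotation_angle_deg(tr)), 10 + 1e-6)

  small <- sweep(X %*% t(rot3(2, "x")), 2, c(3, 0, 0), "+")
  tr2 <- refine_per_timepoint(X, small, cpd_params(), cap_deg = 10)
  expect_false(attr(tr2, "qc_capped"))
  expect_equal(rotation_angle_deg(tr2), 2, tolerance = 1)
  ctr_err <- apply_transform(tr2, colMeans(X)) - colMeans(small)
  expect_lt(sqrt(sum(ctr_err^2)), 0.5)
})

test_that("a 60-degree misalignment without coarse alignment is flagged", {
  b <- reference_bundle()
  est <- estimate_frame(b)
  pts <- sample_fiducial_points(b$fiducial[[1]], 800, 4)
  proj <- project_p2p3(pts, est$frame)
  rotated <- proj %*% t(rot2(60))
  expect_warning(ang <- refine_early(rotated, proj, cpd_params()),
                 "alignment failure")
  expect_true(attr(ang, "qc_fail"))
  expect_gt(abs(as.numeric(ang)), 40)
  # with coarse alignment applied (identity case), the residual is tiny
  ang0 <- refine_early(proj, proj, cpd_params())
  expect_false(attr(ang0, "qc_fail"))
  expect_lt(abs(as.numeric(ang0)), 0.5)
})

test_that("self-alignment of the reference is the identity everywhere", {
  # short movie, all voxels used: residuals then reflect the algorithm, not
  # subsampling noise
  ref <- cached("ref_short", {
    g <- small_grid(fast_count = 6L)
    simulate_embryo(synthetic_embryo_spec(
      seed = 101L, grid = g, temporal_offset_min = 0, theta0_deg = 20))
  })
  res <- cached("self_align", {
    align_embryo(ref, ref, fast_config(n_sample = 100000L))
  })
  expect_equal(res$temporal$offset_min, 0)
  expect_equal(res$scale$r_l, 1, tolerance = 1e-9)
  expect_equal(res$scale$r_s, 1, tolerance = 1e-9)
  expect_equal(res$coarse_p2_rotation_deg, 0, tolerance = 1e-9)
  expect_lt(abs(res$early_refinement_deg), 0.5)
  expect_lt(max(abs(res$refinement_table$refine_angle_deg)), 0.5)
  expect_lt(max(res$refinement_table$refine_shift_um), 0.2)
  # mapped points stay put at every matched timepoint
  pts <- sweep(matrix(rnorm(30, 0, 5), 10, 3), 2,
               ref$ground_truth$center_um, "+")
  for (tp in res$pairs$t_test[c(1, nrow(res$pairs))]) {
    err <- sqrt(rowSums((map_points(res, pts, tp, "full") - pts)^2))
    expect_lt(max(err), 0.2)
  }
})

test_that("missing fiducial masks are reported by timepoint", {
  ref <- reference_bundle()
  broken <- ref
  drop <- names(broken$fiducial)[3:5]
  broken$fiducial[drop] <- NULL
  expect_error(align_embryo(broken, ref, fast_config()),
               paste(drop, collapse = ", "))
})

test_that("stage toggles skip their corrections", {
  ref <- reference_bundle()
  res <- cached("self_align_min", {
    align_embryo(ref, ref, fast_config(
      n_sample = 800L, temporal = FALSE, scaling = FALSE,
      rotation_tracking = FALSE, early_refinement = FALSE,
      final_refinement = FALSE))
  })
  expect_equal(res$temporal$offset_min, 0)
  expect_equal(res$scale$r_l, 1)
  expect_null(res$track_test)
  expect_equal(res$early_refinement_deg, 0)
  expect_true(all(res$refinement_table$refine_angle_deg == 0))
  g <- glance(res)
  expect_equal(g$mean_refine_shift_um, 0)
})
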