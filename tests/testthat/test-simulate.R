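test_that("count-curve parameters are validated against the plateau windows", {
  expect_error(count_curve_params(levels = c(100, 330)), "120, 220")
  expect_error(count_curve_params(levels = c(190, 400)), "220, 350")
  expect_error(count_curve_params(low_window_min = c(60, 80)), "durations")
  expect_error(count_curve_params(low_window_min = c(60, 140),
                                  high_window_min = c(120, 170)),
               "overlap")
})

test_that("simulated count curves are seeded, monotone templates plus noise", {
  g <- small_grid()
  p <- count_curve_params(noise_sd = 0)
  a <- simulate_count_curve(p, seed = 3, grid = g)
  b <- simulate_count_curve(p, seed = 3, grid = g)
  expect_identical(a, b)
  # zero noise: exactly the rounded template, monotone nondecreasing
  tmpl <- count_template(p, end_time_min = max(a$time_min) + 60)
  expect_equal(a$count, pmax(1, round(tmpl(a$time_min))))
  expect_true(all(diff(a$count) >= 0))
  # different seeds differ once noise is on
  p2 <- count_curve_params(noise_sd = 2)
  expect_false(identical(simulate_count_curve(p2, 1, g)$count,
                         simulate_count_curve(p2, 2, g)$count))
})

test_that("constructed plateaus are recovered from the simulated curve", {
  g <- acquisition_grid(voxel_size_um = 0.65, shape_voxels = c(96L, 48L, 48L),
                        fast_count = 2L)
  p <- count_curve_params(levels = c(194, 330), noise_sd = 0)
  s <- simulate_count_curve(p, seed = 1, grid = g)
  raw <- count_series(s$time_min[1:20], s$count[1:20])
  got <- detect_plateaus(interpolate_counts(raw, 5L))
  expect_setequal(got$window, c("low", "high"))
  # mean count over members sits at the constructed plateau level
  si <- interpolate_counts(raw, 5L)
  for (i in seq_len(nrow(got))) {
    members <- got$member_times_min[[i]]
    lvl <- mean(si$count[si$time_min %in% members])
    expect_equal(lvl, p$levels[[match(got$window[i], c("low", "high"))]],
                 tolerance = 0.01)
  }
})

test_that("synthetic bundles are bit-identical under the same spec and seed", {
  g <- small_grid(fast_count = 4L)
  sp <- synthetic_embryo_spec(seed = 11L, grid = g, total_rotation_deg = 10)
  b1 <- simulate_embryo(sp)
  b2 <- simulate_embryo(sp)
  expect_identical(b1$counts, b2$counts)
  expect_identical(tibble::as_tibble(b1$nuclei), tibble::as_tibble(b2$nuclei))
  expect_identical(b1$fiducial[[1]]$mask, b2$fiducial[[1]]$mask)
  expect_identical(b1$ground_truth, b2$ground_truth)
})

test_that("ground-truth rotation bookkeeping is exact", {
  g <- small_grid(fast_count = 8L)
  b <- simulate_embryo(synthetic_embryo_spec(seed = 12L, grid = g,
                                             total_rotation_deg = 30))
  gt <- b$ground_truth
  expect_equal(sum(gt$step_angles_deg), 30, tolerance = 1e-9)
  expect_equal(gt$cumulative_deg, cumsum(gt$step_angles_deg))
  expect_equal(gt$total_rotation_deg, 30, tolerance = 1e-9)
  # counterclockwise preference: one sign throughout by default
  expect_true(all(gt$step_angles_deg > 0))

  b0 <- simulate_embryo(synthetic_embryo_spec(seed = 13L, grid = g,
                                              total_rotation_deg = 0))
  expect_equal(b0$ground_truth$cumulative_deg,
               rep(0, g$fast_count - 1))
  # zero rotation and zero jitter: fiducial masks differ only by count growth
  b0j <- simulate_embryo(synthetic_embryo_spec(
    seed = 13L, grid = g, total_rotation_deg = 0, nucleus_jitter_um = 0,
    fiducial_n_range = c(20L, 20L)))
  expect_identical(b0j$fiducial[[1]]$mask, b0j$fiducial[[5]]$mask)
})

test_that("fiducial cluster is anterior-biased in the +P1 half", {
  b <- reference_bundle()
  ctr <- b$ground_truth$center_um
  for (nm in names(b$fiducial)[c(1, length(b$fiducial))]) {
    pts <- mask_coords_um(b$fiducial[[nm]])
    frac_anterior <- mean(pts[, 1] > ctr[1])
    expect_gte(frac_anterior, 0.7)
  }
})

test_that("generated ring voxels lie within one voxel of the true plane", {
  g <- small_grid(fast_count = 4L)
  b <- simulate_embryo(synthetic_embryo_spec(
    seed = 14L, grid = g, total_rotation_deg = 5,
    reporter_timepoints = fast_timepoints(g)[4]))
  gt <- b$ground_truth
  vol <- b$reporter[[1]]
  pts <- mask_coords_um(vol)
  n <- as.numeric(rot3(gt$theta0_deg + gt$cumulative_deg[3], "x") %*%
                    gt$ring_normal_canonical)
  ctr <- true_ring_centroid(b, vol$timepoint_index)
  d_plane <- abs(sweep(pts, 2, ctr) %*% n)
  # exclude the two cell-body blobs, then require ring voxels planar
  R <- rot3(gt$theta0_deg + gt$cumulative_deg[3], "x")
  bodies <- sweep(gt$body_centers_canonical %*% t(R), 2, gt$center_um, "+")
  d_body <- pmin(
    sqrt(rowSums(sweep(pts, 2, bodies[1, ])^2)),
    sqrt(rowSums(sweep(pts, 2, bodies[2, ])^2)))
  on_ring <- d_body > 1.5 + g$voxel_size_um * sqrt(3)
  expect_gt(sum(on_ring), 50)
  expect_lt(max(d_plane[on_ring]), g$voxel_size_um)
})

test_that("analytic ellipsoid moments give the expected width scale factor", {
  semi_ref <- c(25, 12.5, 12.5)
  semi_test <- c(25, 12.5 * 1.02, 12.5 * 1.02)
  fake <- function(semi) list(list(principal_moments = ellipsoid_moments(semi)))
  sf <- scale_factors(fake(semi_ref), fake(semi_test))
  expect_equal(sf$r_s, 1 / 1.02, tolerance = 1e-9)
  expect_equal(sf$r_l, 1, tolerance = 1e-9)
})
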