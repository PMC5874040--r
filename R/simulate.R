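#' Parameters of the synthetic nuclear-count curve
#'
#' The template is a monotone nondecreasing curve over the movie with two
#' flat plateaus, corresponding to the 200-cell stage and the ball stage
#' of embryogenesis, placed inside the count windows (120, 220) and
#' (220, 350) used by plateau detection.
#'
#' @param levels Plateau count levels, `c(low, high)`.
#' @param low_window_min,high_window_min Start/end times (reference clock,
#'   minutes) of the two plateaus.
#' @param start_count,end_count Counts at the start of imaging and at the
#'   end of the movie.
#' @param noise_sd SD of the integer-rounded observation noise (nuclei).
#' @param min_run Plateau-detection run length the durations must support.
#' @param step_min Interpolated step the durations are validated against.
#' @return A list of class `count_curve_params`.
#' @export
count_curve_params <- function(levels = c(190, 330),
                               low_window_min = c(60, 100),
                               high_window_min = c(130, 170),
                               start_count = 20,
                               end_count = 348,
                               noise_sd = 2,
                               min_run = 15L,
                               step_min = 2) {
  if (!(levels[1] > 120 && levels[1] < 220)) {
    stop("low plateau level must lie inside (120, 220)", call. = FALSE)
  }
  if (!(levels[2] > 220 && levels[2] < 350)) {
    stop("high plateau level must lie inside (220, 350)", call. = FALSE)
  }
  durations <- c(diff(low_window_min), diff(high_window_min))
  if (any(durations <= min_run * step_min)) {
    stop(sprintf("plateau durations must exceed %g min (%d interpolated points)",
                 min_run * step_min, min_run), call. = FALSE)
  }
  if (high_window_min[1] <= low_window_min[2]) {
    stop("plateaus must not overlap", call. = FALSE)
  }
  structure(list(levels = levels, low_window_min = low_window_min,
                 high_window_min = high_window_min,
                 start_count = start_count, end_count = end_count,
                 noise_sd = noise_sd),
            class = "count_curve_params")
}

#' Deterministic count-curve template
#' @param params A [count_curve_params()].
#' @param end_time_min Time of the movie end (reference clock).
#' @return A function of time (minutes) returning the noiseless count.
#' @export
count_template <- function(params, end_time_min = 440) {
  kx <- c(0, params$low_window_min, params$high_window_min,
          max(end_time_min, params$high_window_min[2] + 1))
  ky <- c(params$start_count, params$levels[1], params$levels[1],
          params$levels[2], params$levels[2], params$end_count)
  f <- stats::splinefun(kx, ky, method = "monoH.FC")
  function(t) f(pmin(pmax(t, 0), max(kx)))
}

#' Simulate an observed nuclear-count curve
#'
#' Evaluates the two-plateau template at the acquisition times (shifted by
#' a temporal offset) and adds integer-rounded observation noise.
#'
#' @param params A [count_curve_params()].
#' @param seed Integer seed.
#' @param grid An [acquisition_grid()] providing acquisition times.
#' @param offset_min Ground-truth temporal offset: the test clock plus this
#'   value lands on the reference clock.
#' @return A raw [count_series()] over all timepoints of the grid.
#' @export
simulate_count_curve <- function(params, seed = 1L,
                                 grid = acquisition_grid(),
                                 offset_min = 0) {
  stopifnot(inherits(params, "count_curve_params"))
  times <- grid_times_min(grid)
  tmpl <- count_template(params, end_time_min = max(times) + 60)
  counts <- with_seed(seed, {
    pmax(1, round(tmpl(times + offset_min) +
                    stats::rnorm(length(times), 0, params$noise_sd)))
  })
  count_series(times, counts)
}

# run code with a local, seeded RNG; session RNG state is untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, globalenv())
  } else if (exists(".Random.seed", globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# uniform points inside an axis-aligned ellipsoid
runif_ellipsoid <- function(n, semi_axes) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * stats::runif(n)^(1 / 3)
  sweep(u, 2, semi_axes, "*")
}

# random sequential addition of hard spheres inside an ellipsoid
rsa_nuclei <- function(n, semi_axes, radius_um, max_attempts = 200000L) {
  out <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  min_d2 <- (2 * radius_um)^2
  while (placed < n && attempts < max_attempts) {
    batch <- runif_ellipsoid(min(200L, max(50L, n)), semi_axes)
    for (i in seq_len(nrow(batch))) {
      attempts <- attempts + 1L
      if (placed > 0) {
        d2 <- rowSums((out[seq_len(placed), , drop = FALSE] -
                         matrix(batch[i, ], placed, 3, byrow = TRUE))^2)
        if (min(d2) < min_d2) next
      }
      placed <- placed + 1L
      out[placed, ] <- batch[i, ]
      if (placed == n) break
    }
  }
  if (placed < n) {
    stop("could not place all nuclei without overlap; reduce count or radius",
         call. = FALSE)
  }
  out
}

# stereotyped fiducial-nucleus template in canonical embryo coordinates
# (long axis = x, anterior = +x). Fixed across embryos, emulating the
# reproducible anterior-biased expression pattern of the fiducial reporter:
# up to 40 anterior nuclei (all in the +x half, mild +y bias) and 4
# posterior-ventral nuclei whose offset from the axis fixes the P2 direction.
fiducial_template <- function(long_semi = 25, short_semi = 12.5,
                              n_max_anterior = 40L, n_posterior = 4L) {
  with_seed(104729L, {
    ant <- matrix(NA_real_, 0, 3)
    while (nrow(ant) < n_max_anterior) {
      cand <- runif_ellipsoid(200, c(long_semi, short_semi, short_semi) * 0.85)
      cand <- cand[cand[, 1] > 0.12 * long_semi, , drop = FALSE]
      cand[, 2] <- cand[, 2] * 0.8 + 0.18 * short_semi
      ant <- rbind(ant, cand)
    }
    ant <- ant[seq_len(n_max_anterior), , drop = FALSE]
    # spread the 4 posterior nuclei around a ventral posterior point
    post <- matrix(stats::rnorm(n_posterior * 3, 0, 1.2), n_posterior, 3) +
      matrix(c(-0.68 * long_semi, -0.45 * short_semi, 0),
             n_posterior, 3, byrow = TRUE)
    list(anterior = ant, posterior = post)
  })
}

#' Specification of a synthetic embryo movie
#'
#' Defines one synthetic embryo: an ellipsoidal volume (default semi-axes
#' 25 and 12.5 micrometers) filled with non-overlapping nuclei whose count
#' follows a two-plateau curve, an anterior-biased fiducial-nucleus
#' cluster plus a 4-nucleus posterior-ventral cluster, bulk rotation about
#' the long axis during the fast imaging phase (total drawn from
#' N(34.8, 47.5) degrees counterclockwise, per-step magnitudes from
#' N(1.7, 1.4) degrees rescaled to the total), inter-embryo size
#' differences of a few percent, and a temporal offset. A synthetic nerve
#' ring (circle perpendicular to the long axis near 2/3 embryo length,
#' plus cell-body blobs) is drawn in the reporter channel.
#'
#' @param seed Integer seed; all randomness in the embryo derives from it.
#' @param grid An [acquisition_grid()]; the frame must be larger than the
#'   embryo.
#' @param long_semi_axis_um,short_semi_axis_um Canonical semi-axes.
#' @param length_scale_jitter,width_scale_jitter Maximal fractional size
#'   deviation; the embryo's scale is drawn uniformly from `1 +/- jitter`
#'   (defaults 0.029 and 0.013, the average adjustments observed across
#'   real embryos; maxima were 0.093 and 0.048).
#' @param length_scale,width_scale Explicit scales overriding the draw.
#' @param temporal_offset_min Ground-truth offset (added to this embryo's
#'   clock to land on the reference clock).
#' @param total_rotation_deg Total bulk rotation; `NULL` draws from
#'   N(34.8, 47.5), counterclockwise positive.
#' @param per_step_mean_deg,per_step_sd_deg Per-step rotation magnitude
#'   distribution before rescaling (defaults 1.7 and 1.4).
#' @param count_curve A [count_curve_params()].
#' @param theta0_deg Initial rotational position about the long axis;
#'   `NULL` draws uniformly (embryos mount at arbitrary roll angles).
#' @param fiducial_n_range Anterior fiducial nuclei at start/end of the
#'   movie (clamped to 4-40).
#' @param nucleus_radius_um Hard-sphere nucleus radius (default 1.5).
#' @param nucleus_jitter_um Per-frame jitter of fiducial nucleus centers.
#' @param twitch_time_min Twitch onset on the reference clock; `NULL` uses
#'   the last fast frame of the reference clock.
#' @param nuclei_timepoints Timepoints for which nuclei tables are built
#'   (default 1..min(30, last), covering the axis-averaging window).
#' @param reporter_timepoints Fast timepoints with a reporter volume
#'   (default: last fast frame only).
#' @return A list of class `synthetic_embryo_spec`.
#' @export
synthetic_embryo_spec <- function(seed = 1L,
                                  grid = acquisition_grid(),
                                  long_semi_axis_um = 25,
                                  short_semi_axis_um = 12.5,
                                  length_scale_jitter = 0.029,
                                  width_scale_jitter = 0.013,
                                  length_scale = NULL,
                                  width_scale = NULL,
                                  temporal_offset_min = 0,
                                  total_rotation_deg = NULL,
                                  per_step_mean_deg = 1.7,
                                  per_step_sd_deg = 1.4,
                                  count_curve = count_curve_params(),
                                  theta0_deg = NULL,
                                  fiducial_n_range = c(8L, 40L),
                                  nucleus_radius_um = 1.5,
                                  nucleus_jitter_um = 0.1,
                                  twitch_time_min = NULL,
                                  nuclei_timepoints = NULL,
                                  reporter_timepoints = NULL) {
  stopifnot(long_semi_axis_um > 0, short_semi_axis_um > 0,
            length_scale_jitter >= 0, width_scale_jitter >= 0,
            nucleus_radius_um > 0)
  fiducial_n_range <- pmin(pmax(as.integer(fiducial_n_range), 4L), 40L)
  ext <- grid_extent_um(grid)
  if (ext[1] < 2.3 * long_semi_axis_um ||
      any(ext[2:3] < 2.3 * short_semi_axis_um)) {
    stop("grid frame is too small for the embryo", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_embryo_spec")
}

#' Simulate a synthetic embryo movie bundle with ground truth
#'
#' Generates the full per-embryo bundle the alignment pipeline consumes —
#' nuclei tables, nuclear-count curve, fiducial label volumes for every
#' fast timepoint and reporter volumes for selected timepoints — together
#' with the ground truth (offset, scales, rotation history, axes, ring
#' geometry) needed to score recovery. Identical spec and seed give
#' bit-identical bundles.
#'
#' @param spec A [synthetic_embryo_spec()].
#' @return A list of class `embryo_bundle` with elements `grid`, `counts`
#'   (raw [count_series()]), `nuclei` ([nuclei_series()]), `fiducial`
#'   (list of [label_volume()] keyed by fast timepoint), `reporter`
#'   (list keyed by timepoint), `twitch_time_min`, `embryo_id`, and
#'   `ground_truth` (see below).
#'
#'   `ground_truth` holds `offset_min`, `length_scale`/`width_scale` (vs
#'   the canonical embryo), `theta0_deg`, `step_angles_deg` and
#'   `cumulative_deg` (per fast step), `p1` (unit long axis), `p2_initial`
#'   (P2 at the first fast frame), `center_um`, `ring_center_canonical`,
#'   `ring_normal_canonical`, `ring_radius_um`.
#' @export
simulate_embryo <- function(spec) {
  stopifnot(inherits(spec, "synthetic_embryo_spec"))
  grid <- spec$grid
  with_seed(spec$seed, {
    s_l <- spec$length_scale %||%
      stats::runif(1, 1 - spec$length_scale_jitter, 1 + spec$length_scale_jitter)
    s_w <- spec$width_scale %||%
      stats::runif(1, 1 - spec$width_scale_jitter, 1 + spec$width_scale_jitter)
    total_rot <- spec$total_rotation_deg %||% stats::rnorm(1, 34.8, 47.5)
    theta0 <- spec$theta0_deg %||% stats::runif(1, -180, 180)

    n_steps <- grid$fast_count - 1L
    if (n_steps > 0) {
      mags <- abs(stats::rnorm(n_steps, spec$per_step_mean_deg,
                               spec$per_step_sd_deg))
      mags[mags < 1e-6] <- 1e-6
      step_angles <- if (abs(total_rot) < 1e-12) {
        rep(0, n_steps)
      } else {
        sign(total_rot) * mags * (abs(total_rot) / sum(mags))
      }
    } else {
      step_angles <- numeric(0)
    }
    cumulative <- cumsum(step_angles)

    times <- grid_times_min(grid)
    twitch_ref <- spec$twitch_time_min %||% max(times)
    tmpl <- count_template(spec$count_curve, end_time_min = max(times) + 60)
    counts_obs <- pmax(1, round(tmpl(times + spec$temporal_offset_min) +
                                  stats::rnorm(length(times), 0,
                                               spec$count_curve$noise_sd)))
    counts <- count_series(times, counts_obs)

    center <- grid_extent_um(grid) / 2
    semi <- c(spec$long_semi_axis_um * s_l,
              spec$short_semi_axis_um * s_w,
              spec$short_semi_axis_um * s_w)
    fast <- fast_timepoints(grid)
    rot_at <- function(t) {
      # cumulative bulk rotation at timepoint t (zero before the fast phase)
      j <- match(t, fast)
      phi <- if (is.na(j) || j <= 1) 0 else cumulative[j - 1]
      theta0 + phi
    }

    # pan-nuclear nuclei tables (counts + convex-hull geometry)
    nuc_tp <- spec$nuclei_timepoints %||% seq_len(min(30L, length(times)))
    rec <- lapply(nuc_tp, function(t) {
      pts <- rsa_nuclei(counts_obs[t], semi, spec$nucleus_radius_um)
      pts <- pts %*% t(rot3(rot_at(t), "x"))
      pts <- sweep(pts, 2, center, "+")
      tibble::tibble(t = t, x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
    })
    nuclei <- nuclei_series(dplyr::bind_rows(rec), grid)

    # fiducial masks per fast timepoint
    ftmpl <- fiducial_template(spec$long_semi_axis_um,
                               spec$short_semi_axis_um)
    stage <- function(tau) min(max(tau / twitch_ref, 0), 1)
    n_lo <- spec$fiducial_n_range[1]; n_hi <- spec$fiducial_n_range[2]
    fiducial <- list()
    for (t in fast) {
      tau <- times[t] + spec$temporal_offset_min
      n_ant <- round(n_lo + (n_hi - n_lo) * stage(tau))
      pts <- sweep(rbind(ftmpl$anterior[seq_len(n_ant), , drop = FALSE],
                         ftmpl$posterior), 2, c(s_l, s_w, s_w), "*")
      if (spec$nucleus_jitter_um > 0) {
        pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                         spec$nucleus_jitter_um),
                            nrow(pts), 3)
      }
      pts <- sweep(pts %*% t(rot3(rot_at(t), "x")), 2, center, "+")
      fiducial[[as.character(t)]] <-
        voxelize_points(pts, grid, "fiducial_gfp", t,
                        radius_um = spec$nucleus_radius_um)
    }

    # reporter: ring perpendicular to the long axis near 2/3 embryo length
    ring_center_canon <- c(spec$long_semi_axis_um * s_l / 3, 0, 0)
    ring_radius <- 0.45 * spec$short_semi_axis_um * s_w
    rep_tp <- spec$reporter_timepoints %||% fast[length(fast)]
    alpha <- seq(0, 2 * pi, length.out = 720L)[-1]
    ring_canon <- cbind(ring_center_canon[1],
                        ring_radius * cos(alpha),
                        ring_radius * sin(alpha))
    body_canon <- rbind(ring_center_canon + c(0, -ring_radius, 1.2),
                        ring_center_canon + c(0, -ring_radius, -1.2))
    reporter <- list()
    for (t in rep_tp) {
      R <- rot3(rot_at(t), "x")
      ring_img <- sweep(ring_canon %*% t(R), 2, center, "+")
      body_img <- sweep(body_canon %*% t(R), 2, center, "+")
      ring_vol <- voxelize_points(ring_img, grid, "reporter_gfp", t,
                                  radius_um = 0.99 * grid$voxel_size_um)
      body_vol <- voxelize_points(body_img, grid, "reporter_gfp", t,
                                  radius_um = 1.5)
      reporter[[as.character(t)]] <-
        label_volume(ring_vol$mask | body_vol$mask, grid, "reporter_gfp", t)
    }

    truth <- list(offset_min = spec$temporal_offset_min,
                  length_scale = s_l, width_scale = s_w,
                  theta0_deg = theta0,
                  total_rotation_deg = if (n_steps > 0) sum(step_angles) else 0,
                  step_angles_deg = step_angles,
                  cumulative_deg = cumulative,
                  p1 = c(1, 0, 0),
                  p2_initial = as.numeric(rot3(theta0, "x") %*% c(0, 1, 0)),
                  center_um = center,
                  ring_center_canonical = ring_center_canon,
                  ring_normal_canonical = c(1, 0, 0),
                  ring_radius_um = ring_radius,
                  body_centers_canonical = body_canon,
                  twitch_time_ref_min = twitch_ref)

    structure(list(grid = grid, counts = counts, nuclei = nuclei,
                   fiducial = fiducial, reporter = reporter,
                   twitch_time_min = twitch_ref - spec$temporal_offset_min,
                   embryo_id = sprintf("synthetic-%d", spec$seed),
                   ground_truth = truth, spec = spec),
              class = "embryo_bundle")
  })
}

#' @export
print.embryo_bundle <- function(x, ...) {
  cat(sprintf("<embryo_bundle> %s: %d nuclei rows, %d fiducial volumes, %d reporter volumes\n",
              x$embryo_id, nrow(x$nuclei), length(x$fiducial),
              length(x$reporter)))
  invisible(x)
}

#' Ground-truth ring centroid in image coordinates
#' @param bundle A synthetic `embryo_bundle`.
#' @param timepoint Timepoint index.
#' @return 3-vector in micrometers.
#' @export
true_ring_centroid <- function(bundle, timepoint) {
  gt <- bundle$ground_truth
  grid <- bundle$grid
  fast <- fast_timepoints(grid)
  j <- match(timepoint, fast)
  phi <- if (is.na(j) || j <= 1) 0 else gt$cumulative_deg[j - 1]
  as.numeric(rot3(gt$theta0_deg + phi, "x") %*% gt$ring_center_canonical) +
    gt$center_um
}

#' Synthetic nerve-ring trace polyline in image coordinates
#' @param bundle A synthetic `embryo_bundle`.
#' @param timepoint Timepoint index.
#' @param n_points Points along the ring.
#' @return Matrix (n x 3) tracing the ring.
#' @export
true_ring_trace <- function(bundle, timepoint, n_points = 72L) {
  gt <- bundle$ground_truth
  fast <- fast_timepoints(bundle$grid)
  j <- match(timepoint, fast)
  phi <- if (is.na(j) || j <= 1) 0 else gt$cumulative_deg[j - 1]
  alpha <- seq(0, 2 * pi, length.out = n_points + 1L)[-1]
  ring <- cbind(gt$ring_center_canonical[1],
                gt$ring_radius_um * cos(alpha),
                gt$ring_radius_um * sin(alpha))
  sweep(ring %*% t(rot3(gt$theta0_deg + phi, "x")), 2, gt$center_um, "+")
}
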