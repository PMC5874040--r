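raw_series <- function(counts, step = 10) {
  count_series(seq(0, by = step, length.out = length(counts)), counts)
}

test_that("count_series validates its invariants", {
  expect_error(count_series(c(0, 10), c(5, 4, 3)), "equal length")
  expect_error(count_series(c(10, 0), c(5, 4)), "strictly increasing")
  expect_error(count_series(c(0, 10), c(5, -1)), "nonnegative")
  expect_error(count_series(c(0, 10), c(5.5, 6)), "integers")
  # interpolated series may carry fractional counts
  expect_s3_class(count_series(c(0, 2), c(5.5, 6), interpolation_factor = 5L),
                  "count_series")
})

test_that("interpolation reproduces samples, preserves monotonicity and lines", {
  s <- raw_series(c(10L, 12L, 30L, 31L, 90L, 95L))
  out <- interpolate_counts(s, 5L)
  expect_equal(nrow(out), (nrow(s) - 1) * 5 + 1)
  # original samples reproduced exactly
  expect_equal(out$count[out$time_min %in% s$time_min], s$count)
  # monotone data -> monotone interpolant, checked densely
  expect_true(all(diff(out$count) >= -1e-12))
  # factor 1 is the identity
  expect_equal(interpolate_counts(s, 1L), s)
  # collinear points stay on the line
  lin <- raw_series(seq(10L, 100L, by = 10L))
  il <- interpolate_counts(lin, 4L)
  expect_equal(il$count, 10 + 90 * (il$time_min - il$time_min[1]) /
                 diff(range(il$time_min)), tolerance = 1e-9)
})

test_that("temporal offset is zero for self-alignment and recovers known shifts", {
  tm <- count_template(count_curve_params())
  ref <- count_series(seq(0, 190, by = 10), round(tm(seq(0, 190, by = 10))))
  ri <- interpolate_counts(ref, 5L)
  self <- temporal_offset(ri, ri)
  expect_equal(self$offset_min, 0)

  # test curve lags by 4 min (2 interpolated steps): offset is -4
  lag <- count_series(seq(0, 190, by = 10),
                      round(tm(seq(0, 190, by = 10) - 4)))
  off <- temporal_offset(interpolate_counts(lag, 5L), ri)
  expect_equal(off$offset_min, -4)

  # antisymmetry on fully-overlapping synthetic pairs
  lead <- count_series(seq(0, 190, by = 10),
                       round(tm(seq(0, 190, by = 10) + 4)))
  off_ba <- temporal_offset(ri, interpolate_counts(lead, 5L))
  off_ab <- temporal_offset(interpolate_counts(lead, 5L), ri)
  expect_equal(off_ab$offset_min, -off_ba$offset_min)
})

test_that("normalization by overlap beats raw SSE at curve edges", {
  # Constructed counter-example: when per-point residuals are nearly
  # offset-independent (a shallow, almost shift-invariant ramp with
  # observation noise), the raw summed square error rewards shedding
  # overlap points and drifts to a large offset, while the per-point
  # normalized criterion stays near the truth.
  t_raw <- seq(0, 190, by = 10)
  slope <- 0.04
  scan_offsets <- function(tst, ref) {
    step <- 2
    offsets <- (-30:30) * step
    scan <- vapply(offsets, function(delta) {
      i_ref <- round((tst$time_min + delta - ref$time_min[1]) / step) + 1
      ok <- i_ref >= 1 & i_ref <= nrow(ref)
      if (sum(ok) < 0.25 * nrow(ref)) return(c(NA, NA))
      sse <- sum((tst$count[ok] - ref$count[i_ref[ok]])^2)
      c(sse, sse / sum(ok))
    }, numeric(2))
    list(raw = offsets[which.min(scan[1, ])],
         norm = offsets[which.min(scan[2, ])])
  }
  ref <- interpolate_counts(count_series(t_raw, round(150 + slope * t_raw)),
                            5L)
  # oracle equality holds for any noise realization
  for (seed in 1:5) {
    set.seed(seed)
    tst <- interpolate_counts(count_series(
      t_raw, pmax(0, round(150 + slope * (t_raw - 4) + rnorm(20, 0, 3)))), 5L)
    bf <- scan_offsets(tst, ref)
    expect_equal(temporal_offset(tst, ref)$offset_min, bf$norm)
  }
  # the fixture instance exhibiting the raw-criterion failure
  set.seed(2)
  tst <- interpolate_counts(count_series(
    t_raw, pmax(0, round(150 + slope * (t_raw - 4) + rnorm(20, 0, 3)))), 5L)
  bf <- scan_offsets(tst, ref)
  expect_gte(abs(bf$raw), 40)          # raw drifts to a large offset
  expect_lte(abs(bf$norm - (-4)), 12)  # normalized stays near the truth
})

test_that("plateau detection matches an exhaustive brute-force search", {
  tm <- count_template(count_curve_params())
  t_raw <- seq(0, 190, by = 10)
  noiseless <- interpolate_counts(count_series(t_raw, round(tm(t_raw))), 5L)
  set.seed(8)
  noisy <- interpolate_counts(
    count_series(t_raw, pmax(1, round(tm(t_raw) + rnorm(20, 0, 3)))), 5L)
  for (series in list(noiseless, noisy)) {
    expect_plateaus_match_brute_force(series)
  }
})

test_that("constructed plateaus are recovered at threshold zero", {
  # 20 interpolated points flat at 194 inside the low window, steep rest
  times <- seq(0, by = 2, length.out = 60)
  counts <- c(seq(60, 180, length.out = 20), rep(194, 20),
              seq(230, 340, length.out = 20))
  s <- count_series(times, counts, interpolation_factor = 5L)
  got <- detect_plateaus(s)
  low <- got[got$window == "low", ]
  expect_equal(nrow(low), 1L)
  expect_equal(low$threshold_used, 0)
  # members: the flat run excluding its first point (change measured from
  # the previous point, which was still rising)
  expect_equal(low$plateau_time_min, mean(times[22:40]))

  # counts never entering the windows -> empty result
  flat <- count_series(times, rep(50, 60), interpolation_factor = 5L)
  expect_equal(nrow(detect_plateaus(flat)), 0L)
})

test_that("twitch statistics shrink under perfect offsets", {
  expect_error(twitch_stats(400, 0), ">= 2")
  tw <- c(400, 420, 395, 410)
  # offsets exactly centering each embryo: corrected SD 0, r = -1
  off <- -(tw - mean(tw))
  st <- twitch_stats(tw, off)
  expect_equal(st$sd_corrected_min, 0)
  expect_equal(st$r_offset_twitch, -1)
  expect_gt(st$sd_raw_min, 0)

  # simulated cohort: large offset spread, small residual noise
  set.seed(21)
  true_offsets <- rnorm(30, 0, 19)
  twitch <- 400 - true_offsets + rnorm(30, 0, 3)
  st2 <- twitch_stats(twitch, true_offsets)
  expect_lt(st2$sd_corrected_min, st2$sd_raw_min)
})
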