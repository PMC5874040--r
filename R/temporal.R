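#' Nuclear-count time series
#'
#' A tibble with columns `time_min` (strictly increasing) and `count`
#' (nonnegative), carrying the interpolation factor as an attribute. Raw
#' (uninterpolated, factor 1) counts must be integers, as they come from a
#' nuclear segmenter.
#'
#' @param times_min Strictly increasing numeric times in minutes.
#' @param counts Nonnegative counts, same length.
#' @param interpolation_factor Integer >= 1; 1 marks a raw series.
#' @return A tibble of class `count_series`.
#' @export
count_series <- function(times_min, counts, interpolation_factor = 1L) {
  if (length(times_min) != length(counts)) {
    stop("times and counts must have equal length", call. = FALSE)
  }
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (interpolation_factor == 1L &&
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("raw (uninterpolated) counts must be integers", call. = FALSE)
  }
  structure(tibble::tibble(time_min = as.numeric(times_min),
                           count = as.numeric(counts)),
            interpolation_factor = as.integer(interpolation_factor),
            class = c("count_series", class(tibble::tibble())))
}

#' Interpolate a count curve with monotone piecewise-cubic Hermite polynomials
#'
#' Adds `factor - 1` equally spaced estimates between consecutive frames
#' using a monotonicity-preserving piecewise-cubic Hermite interpolant
#' (Fritsch-Carlson), improving the resolution of temporal matching. The
#' original samples are reproduced exactly.
#'
#' @param series A [count_series()].
#' @param factor Integer density multiplier (default 5, i.e. four added
#'   estimates per frame interval).
#' @return An interpolated [count_series()].
#' @export
interpolate_counts <- function(series, factor = 5L) {
  stopifnot(inherits(series, "count_series"), factor >= 1)
  if (nrow(series) < 2) stop("need at least 2 points", call. = FALSE)
  if (factor == 1L) return(series)
  x <- series$time_min
  new_x <- unique(unlist(lapply(seq_len(length(x) - 1), function(i) {
    seq(x[i], x[i + 1], length.out = factor + 1)[-(factor + 1)]
  })))
  new_x <- c(new_x, x[length(x)])
  f <- stats::splinefun(x, series$count, method = "monoH.FC")
  count_series(new_x, pmax(f(new_x), 0),
               attr(series, "interpolation_factor") * as.integer(factor))
}

#' Least-squares temporal offset between count curves
#'
#' Finds the linear time offset (a multiple of the interpolated step) that
#' shifts the test embryo's clock onto the reference clock by minimizing
#' the summed squared difference of nuclear counts across corresponding
#' time points, normalized by the number of overlapping time points.
#' Without the normalization, shifting by the maximal offset usually
#' minimizes the raw squared error; candidate offsets leaving fewer than
#' `min_overlap_frac` of the reference window are excluded.
#'
#' Sign convention: the offset is added to the test clock to land on the
#' reference clock, so a test embryo whose curve lags the reference by
#' `d` minutes gets offset `-d`.
#'
#' @param test,ref Interpolated [count_series()] on the same time step.
#' @param max_offset_min Largest candidate |offset| in minutes (default 60,
#'   the staging uncertainty at mounting).
#' @param min_overlap_frac Minimum overlap as a fraction of the reference
#'   window (default 0.25).
#' @return An object of class `temporal_offset`: list with `offset_min`,
#'   `normalized_sse` and `overlap_points`.
#' @export
temporal_offset <- function(test, ref, max_offset_min = 60,
                            min_overlap_frac = 0.25) {
  stopifnot(inherits(test, "count_series"), inherits(ref, "count_series"))
  step_t <- diff(test$time_min)
  step_r <- diff(ref$time_min)
  step <- stats::median(step_r)
  if (max(abs(c(step_t, step_r) - step)) > 1e-6 * step) {
    stop("both series must be interpolated on the same uniform step",
         call. = FALSE)
  }
  k_max <- floor(max_offset_min / step)
  min_overlap <- max(1, ceiling(min_overlap_frac * nrow(ref)))
  best <- NULL
  for (k in -k_max:k_max) {
    delta <- k * step
    # pair test count at time s with reference count at time s + delta
    i_ref <- round((test$time_min + delta - ref$time_min[1]) / step) + 1L
    ok <- i_ref >= 1L & i_ref <= nrow(ref)
    n_ov <- sum(ok)
    if (n_ov < min_overlap) next
    sse <- sum((test$count[ok] - ref$count[i_ref[ok]])^2) / n_ov
    if (is.null(best) || sse < best$normalized_sse - 1e-12 ||
        (abs(sse - best$normalized_sse) <= 1e-12 &&
           abs(delta) < abs(best$offset_min))) {
      best <- list(offset_min = delta, normalized_sse = sse,
                   overlap_points = n_ov)
    }
  }
  if (is.null(best)) {
    stop("no candidate offset leaves sufficient overlap", call. = FALSE)
  }
  structure(best, class = "temporal_offset")
}

#' @export
print.temporal_offset <- function(x, ...) {
  cat(sprintf("<temporal_offset> %+.1f min (normalized SSE %.3f over %d points)\n",
              x$offset_min, x$normalized_sse, x$overlap_points))
  invisible(x)
}

#' @describeIn temporal_offset tidy one-row summary.
#' @param x A `temporal_offset`.
#' @param ... Unused.
#' @export
tidy.temporal_offset <- function(x, ...) {
  tibble::tibble(offset_min = x$offset_min,
                 normalized_sse = x$normalized_sse,
                 overlap_points = x$overlap_points)
}

#' Detect cell-count plateaus
#'
#' Finds the two near-constant stretches of the (interpolated) nuclear
#' count curve that correspond to the 200-cell stage and the ball stage.
#' Within each count window (120-220 and 220-350 nuclei), the absolute
#' percentage change of count from the previous time point is compared to
#' a threshold that starts at 0% and is raised in small increments until a
#' connected run of more than `min_run` time points qualifies; that run is
#' the plateau and its time is the mean of its members' times.
#'
#' @param series An interpolated [count_series()].
#' @param increment Threshold increment per step, in percentage points.
#' @param min_run Run length that must be exceeded (default 15 points).
#' @return A tibble with one row per detected plateau: `window`
#'   (`"low"`/`"high"`), `plateau_time_min`, `threshold_used`, `n_members`
#'   and list-column `member_times_min`. Windows without a plateau are
#'   omitted; an empty tibble is not an error.
#' @export
detect_plateaus <- function(series, increment = 0.05, min_run = 15L) {
  stopifnot(inherits(series, "count_series"))
  n <- nrow(series)
  pc <- c(NA_real_, abs(100 * diff(series$count) /
                          pmax(series$count[-n], 1e-12)))
  windows <- list(low = c(120, 220), high = c(220, 350))
  out <- list()
  for (wname in names(windows)) {
    w <- windows[[wname]]
    in_win <- series$count > w[1] & series$count <= w[2]
    cand <- which(in_win & !is.na(pc))
    if (length(cand) == 0) next
    max_thr <- max(pc[cand])
    run <- NULL
    thr <- 0
    repeat {
      qual <- in_win & !is.na(pc) & pc <= thr + 1e-12
      r <- rle(qual)
      ends <- cumsum(r$lengths)
      good <- which(r$values & r$lengths > min_run)
      if (length(good)) {
        g <- good[which.max(r$lengths[good])]
        run <- (ends[g] - r$lengths[g] + 1L):ends[g]
        break
      }
      if (thr > max_thr) break
      thr <- thr + increment
    }
    if (is.null(run)) next
    out[[wname]] <- tibble::tibble(
      window = wname,
      plateau_time_min = mean(series$time_min[run]),
      threshold_used = thr,
      n_members = length(run),
      member_times_min = list(series$time_min[run]))
  }
  if (length(out) == 0) {
    return(tibble::tibble(window = character(), plateau_time_min = numeric(),
                          threshold_used = numeric(), n_members = integer(),
                          member_times_min = list()))
  }
  dplyr::bind_rows(out)
}

#' Twitch-time dispersion before and after temporal offsets
#'
#' The onset of muscle twitching is a sharp developmental endpoint; if the
#' count-curve offsets capture true developmental asynchrony, applying
#' them should shrink the spread of twitch times across embryos.
#'
#' @param twitch_times_min Per-embryo twitch onset times (raw clocks).
#' @param offsets Per-embryo offsets in minutes, or a list of
#'   [temporal_offset()] objects.
#' @param plateau_times_min Optional per-embryo plateau times, for the
#'   plateau/twitch correlation.
#' @return A one-row tibble: `n`, `sd_raw_min`, `sd_corrected_min`,
#'   `r_offset_twitch` and (if plateau times given) `r_plateau_twitch`.
#' @export
twitch_stats <- function(twitch_times_min, offsets,
                         plateau_times_min = NULL) {
  if (is.list(offsets) && !is.numeric(offsets)) {
    offsets <- vapply(offsets, function(o) o$offset_min, numeric(1))
  }
  n <- length(twitch_times_min)
  if (n < 2 || length(offsets) != n) {
    stop("need >= 2 embryos with matching twitch times and offsets",
         call. = FALSE)
  }
  corrected <- twitch_times_min + offsets
  out <- tibble::tibble(
    n = n,
    sd_raw_min = stats::sd(twitch_times_min),
    sd_corrected_min = stats::sd(corrected),
    r_offset_twitch = stats::cor(offsets, twitch_times_min))
  if (!is.null(plateau_times_min)) {
    out$r_plateau_twitch <- stats::cor(plateau_times_min, twitch_times_min)
  }
  out
}
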