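#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   autoplot theme_minimal facet_wrap geom_hline
NULL

#' Plot a nuclear-count curve
#' @param object A [count_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.count_series <- function(object, ...) {
  ggplot(object, aes(.data$time_min, .data$count)) +
    geom_line(color = "grey40") +
    geom_point(size = 0.8) +
    labs(x = "time (min)", y = "nuclei",
         title = "Nuclear count over development") +
    theme_minimal()
}

#' Plot a bulk-rotation track
#' @param object A [rotation_track()] tibble.
#' @param ... Unused.
#' @return A ggplot of per-step and cumulative rotation.
#' @exportS3Method ggplot2::autoplot
autoplot.rotation_track <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("angle_deg", "cumulative_deg"),
                              names_to = "series", values_to = "deg")
  long$series <- factor(long$series, c("angle_deg", "cumulative_deg"),
                        c("per step", "cumulative"))
  ggplot(long, aes(.data$step, .data$deg)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_line() +
    geom_point(size = 0.7) +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "fast-imaging step",
         y = "rotation about long axis (deg, CCW)") +
    theme_minimal()
}

#' Plot count-curve alignment of a test embryo onto the reference
#'
#' @param test,ref [count_series()] (interpolated or raw).
#' @param offset A [temporal_offset()] (or offset in minutes).
#' @return A ggplot overlaying the reference curve with the raw and
#'   offset-corrected test curves.
#' @export
plot_count_alignment <- function(test, ref, offset) {
  off <- if (inherits(offset, "temporal_offset")) offset$offset_min else offset
  df <- dplyr::bind_rows(
    tibble::tibble(time_min = ref$time_min, count = ref$count,
                   curve = "reference"),
    tibble::tibble(time_min = test$time_min, count = test$count,
                   curve = "test (raw)"),
    tibble::tibble(time_min = test$time_min + off, count = test$count,
                   curve = "test (offset applied)"))
  ggplot(df, aes(.data$time_min, .data$count, color = .data$curve)) +
    geom_line() +
    labs(x = "reference clock (min)", y = "nuclei",
         title = sprintf("Temporal alignment (offset %+.1f min)", off)) +
    theme_minimal()
}

#' Plot overlap fractions across alignment stages
#' @param overlap_table Output of [overlap_by_stage()] (possibly several
#'   embryos bound together).
#' @return A ggplot.
#' @export
plot_overlap_stages <- function(overlap_table) {
  ggplot(overlap_table,
         aes(.data$stage, .data$overlap, fill = .data$channel)) +
    geom_col(position = "dodge") +
    labs(x = "alignment stage", y = "mean overlap within 1 um",
         title = "Alignment quality by stage") +
    theme_minimal()
}
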