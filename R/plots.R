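# Diagnostic figures for validity analyses (requires ggplot2).

#' Scatter of video vs reference step counts with an OLS fit
#'
#' @param video_counts,reference_counts Paired per-bout step counts.
#' @param label Optional panel title.
#' @return A ggplot object.
#' @export
plot_step_count_scatter <- function(video_counts, reference_counts,
                                    label = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(reference = reference_counts, video = video_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = video)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "reference step count", y = "video step count",
                  title = label) +
    ggplot2::theme_minimal()
}

#' R-squared and slope versus step-count cutoff
#'
#' @param sweep Output of [cutoff_sweep()].
#' @return A ggplot object.
#' @export
plot_cutoff_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  long <- rbind(
    data.frame(cutoff = sweep$cutoff, value = sweep$r_squared,
               what = "R-squared"),
    data.frame(cutoff = sweep$cutoff, value = sweep$slope, what = "slope")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = cutoff, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "maximum reference steps per bout", y = NULL) +
    ggplot2::theme_minimal()
}
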