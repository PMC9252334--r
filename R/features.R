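# Per-bout spatiotemporal gait features from heel-strike events.
#
# Camera-space distances carry no real-world units, so spatial measures are
# normalized by the participant's apparent hip width in each frame, which
# cancels the perspective scale.  With metric depth data two additional
# features (gait speed, step length) become available.

#' Per-frame hip width
#'
#' Euclidean distance between the left and right hip keypoints in each
#' frame, on the (smoothed) trajectories.  Pixels for 2D input, meters for
#' 3D.  This is the per-frame normalizer that cancels the camera-distance
#' scale in 2D spatial features.
#'
#' @param seq A [pose_sequence()] with both hips tracked.
#' @return Numeric vector of length `n_frames(seq)` (NA where a hip is
#'   missing).
#' @export
hip_width <- function(seq) {
  lh <- joint_track(seq, "left_hip")
  rh <- joint_track(seq, "right_hip")
  w <- sqrt(rowSums((lh - rh)^2))
  bad <- seq$missing[, "left_hip"] | seq$missing[, "right_hip"]
  if (all(bad)) stop("cannot normalize: hips untracked", call. = FALSE)
  w[bad] <- NA_real_
  w
}

cv_pct <- function(x, unbiased = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  s <- if (unbiased) stats::sd(x) else
    sqrt(mean((x - m)^2))
  100 * s / m
}

#' Compute per-bout gait features
#'
#' From a merged, time-ordered heel-strike list:
#' \itemize{
#'   \item `n_steps`: number of heel strikes;
#'   \item `cadence`: `60 * (n - 1) / (t_last - t_first)` steps/minute;
#'   \item `step_time_cv`: percent CV of intervals between valid
#'     consecutive opposite-foot strikes;
#'   \item `step_width_mean`, `step_width_cv`: each step width is the
#'     absolute lateral (image x) separation of consecutive opposite-foot
#'     strike positions, divided by the hip width at the later strike's
#'     frame (when both feet are grounded); unitless;
#'   \item 3D input adds `step_length_mean` (mean absolute depth-axis
#'     separation of consecutive opposite-foot strikes, meters) and `speed`
#'     (depth displacement between first and last strike over the elapsed
#'     time, m/s).
#' }
#' CVs use the sample (n-1) standard deviation by default.
#'
#' @param strikes A merged `heel_strikes` data frame (see [merge_feet()]).
#' @param seq The [pose_sequence()] the strikes came from.
#' @param hipw Per-frame hip width, from [hip_width()] (computed if `NULL`).
#' @param unbiased_cv Use the sample (n-1) standard deviation in CVs
#'   (default `TRUE`).
#' @return A one-row `gait_features` data frame.
#' @export
compute_features <- function(strikes, seq, hipw = NULL, unbiased_cv = TRUE) {
  n <- nrow(strikes)
  if (n < 3L) stop("insufficient steps: need at least 3 strikes",
                   call. = FALSE)
  if (is.null(hipw)) hipw <- hip_width(seq)
  t <- strikes$time_s
  span <- t[n] - t[1]
  cadence <- 60 * (n - 1) / span
  vi <- which(strikes$valid_step)
  step_times <- t[vi] - t[vi - 1L]
  lat <- strikes$x
  hw_at <- hipw[strikes$frame + 1L]
  widths <- abs(lat[vi] - lat[vi - 1L]) / hw_at[vi]
  # degenerate or missing hip width at a strike frame: that step width is
  # unnormalizable and excluded; with none left the feature is absent
  widths <- widths[is.finite(widths)]
  is3d <- seq$dims == 3L && "z" %in% names(strikes)
  out <- data.frame(
    n_steps = n,
    cadence = cadence,
    step_width_mean = if (length(widths)) mean(widths) else NA_real_,
    step_width_cv = cv_pct(widths, unbiased_cv),
    step_time_cv = cv_pct(step_times, unbiased_cv),
    n_valid_steps = length(vi),
    annotation_method = if (all(strikes$source == "manual")) "manual" else
      "auto"
  )
  if (is3d) {
    depth <- strikes$z
    out$step_length_mean <- if (length(vi)) mean(abs(depth[vi] -
                                                       depth[vi - 1L])) else
      NA_real_
    out$speed <- abs(depth[n] - depth[1]) / span
  }
  class(out) <- c("gait_features", "data.frame")
  out
}

#' Apply bout inclusion rules
#'
#' Drops bouts whose reference (ground-truth / walkway) step count exceeds
#' `max_steps` -- the regime where clustering-based detection is known to
#' undercount short, shuffling steps -- and bouts with fewer than
#' `min_steps` detected strikes.
#'
#' @param features Data frame with at least `bout_id` and `n_steps`
#'   (detected) columns.
#' @param reference_steps Named (by `bout_id`) or positionally aligned
#'   vector of reference step counts.
#' @param min_steps Minimum detected strikes to keep a bout (default 3).
#' @param max_steps Reference step-count cap (default 20; `Inf` disables).
#' @return The retained rows, with the exclusions (and reasons) in attribute
#'   `"exclusions"`.
#' @export
filter_bouts <- function(features, reference_steps, min_steps = 3,
                         max_steps = 20) {
  if (!is.null(names(reference_steps))) {
    reference_steps <- reference_steps[features$bout_id]
  }
  stopifnot(length(reference_steps) == nrow(features))
  too_many <- !is.na(reference_steps) & reference_steps > max_steps
  too_few <- features$n_steps < min_steps
  drop <- too_many | too_few
  excl <- data.frame(
    bout_id = features$bout_id[drop],
    reason = ifelse(too_many[drop], "reference steps above cap",
                    "insufficient steps")
  )
  kept <- features[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "exclusions") <- excl
  kept
}

#' Infer walking direction from apparent hip width
#'
#' The apparent (pixel) hip width grows as the walker approaches the camera
#' and shrinks as they recede, so the sign of its robust linear trend over
#' the bout gives the walking direction.  A trend smaller than the residual
#' noise floor returns `"unknown"`; a manual direction label in the bout
#' metadata should always take precedence.
#'
#' @param seq A [pose_sequence()] with hips tracked over at least 1 s.
#' @return `"toward"`, `"away"` or `"unknown"`.
#' @export
infer_direction <- function(seq) {
  hw <- hip_width(seq)
  ur <- usable_range(seq) %||% c(0L, n_frames(seq) - 1L)
  idx <- (ur[1]:ur[2]) + 1L
  hw <- hw[idx]
  ok <- is.finite(hw)
  if (sum(ok) < seq$fps) stop("hip width series too short", call. = FALSE)
  t <- (idx[ok] - 1L) / seq$fps
  hw <- hw[ok]
  # de-spike before fitting
  hws <- if (length(hw) >= 7L) stats::runmed(hw, 7L) else hw
  fit <- stats::lm(hws ~ t)
  slope <- stats::coef(fit)[2]
  swing <- abs(slope) * (max(t) - min(t))
  floor <- 2 * stats::sd(stats::resid(fit))
  if (!is.finite(slope) || swing < floor) return("unknown")
  if (slope > 0) "toward" else "away"
}
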