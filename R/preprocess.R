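# Raw keypoint tracks -> smooth, gap-free joint trajectories:
# confidence gating, linear gap interpolation, zero-phase Butterworth
# low-pass smoothing.

.default_thresholds <- c(alphapose = 0.50, detectron = 0.15, openpose = 0.65)

#' Preprocessing configuration
#'
#' @param confidence_threshold Confidence below which a keypoint is treated
#'   as missing.  `NULL` (default) resolves per estimator tag: 0.50 for
#'   AlphaPose, 0.15 for Detectron, 0.65 for OpenPose, 0.50 otherwise.
#' @param filter_order Butterworth order (default 2).
#' @param cutoff_hz Low-pass cutoff in Hz (default 8); must be below the
#'   Nyquist frequency of the sequence.
#' @param max_gap_frames Longest interior gap (frames) that is filled by
#'   interpolation; longer gaps split the track (default 15, i.e. 0.5 s at
#'   30 Hz).
#' @param joints Canonical joints the pipeline uses; only these are
#'   interpolated/smoothed and drive the usable-range trim.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(confidence_threshold = NULL, filter_order = 2,
                              cutoff_hz = 8, max_gap_frames = 15,
                              joints = .required_joints) {
  if (!is.null(confidence_threshold)) {
    stopifnot(confidence_threshold >= 0, confidence_threshold <= 1)
  }
  stopifnot(filter_order >= 1, cutoff_hz > 0, max_gap_frames >= 0)
  structure(list(confidence_threshold = confidence_threshold,
                 filter_order = as.integer(filter_order),
                 cutoff_hz = cutoff_hz,
                 max_gap_frames = as.integer(max_gap_frames),
                 joints = joints),
            class = "preprocess_config")
}

resolve_threshold <- function(cfg, estimator = NULL) {
  if (!is.null(cfg$confidence_threshold)) return(cfg$confidence_threshold)
  if (!is.null(estimator)) {
    th <- .default_thresholds[tolower(estimator)]
    if (!is.na(th)) return(unname(th))
  }
  0.50
}

#' Mask low-confidence keypoints
#'
#' Marks joint-frames whose confidence score falls below the threshold as
#' missing, so they are re-estimated by interpolation.  The fraction masked
#' per joint is attached as attribute `"masked_fraction"` (estimator
#' thresholds are chosen so that on average under 10% of timesteps per joint
#' need interpolation).
#'
#' @param seq A [pose_sequence()] with confidence scores.  3D input without
#'   confidence is returned unchanged.
#' @param cfg A [preprocess_config()].
#' @param estimator Optional estimator tag used to resolve the default
#'   threshold.
#' @return The masked `pose_sequence`.
#' @export
mask_low_confidence <- function(seq, cfg = preprocess_config(),
                                estimator = NULL) {
  if (is.null(seq$confidence)) {
    attr(seq, "masked_fraction") <- setNames(rep(0, length(seq$joint_names)),
                                             seq$joint_names)
    return(seq)
  }
  th <- resolve_threshold(cfg, estimator)
  low <- seq$confidence < th
  newly <- low & !seq$missing
  seq$missing <- seq$missing | low
  attr(seq, "masked_fraction") <- colMeans(seq$missing)
  attr(seq, "newly_masked") <- colMeans(newly)
  seq
}

#' Interpolate interior gaps in joint trajectories
#'
#' Fills interior runs of missing frames (up to `max_gap_frames` long) by
#' linear interpolation per coordinate, for the configured joints.  Leading
#' and trailing missing frames are never extrapolated: they are trimmed from
#' the usable range, reported via [usable_range()].  Gaps longer than
#' `max_gap_frames` are left missing and reported as track splits in
#' attribute `"splits"`.
#'
#' @param seq A [pose_sequence()] (typically after [mask_low_confidence()]).
#' @param cfg A [preprocess_config()].
#' @return The gap-filled `pose_sequence` with a usable range set.
#' @export
interpolate_gaps <- function(seq, cfg = preprocess_config()) {
  nf <- n_frames(seq)
  joints <- intersect(cfg$joints, seq$joint_names)
  first_ok <- 1L
  last_ok <- nf
  splits <- list()
  for (j in joints) {
    ok <- !seq$missing[, j]
    if (sum(ok) < 2L) stop("untrackable joint: ", j, call. = FALSE)
    v1 <- which(ok)[1]
    v2 <- max(which(ok))
    first_ok <- max(first_ok, v1)
    last_ok <- min(last_ok, v2)
    # interior gaps
    r <- rle(ok[v1:v2])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(!r$values)) {
      gs <- starts[g] + v1 - 1L
      ge <- ends[g] + v1 - 1L
      glen <- ge - gs + 1L
      if (glen > cfg$max_gap_frames) {
        splits[[length(splits) + 1L]] <-
          data.frame(joint = j, gap_start = gs - 1L, gap_end = ge - 1L,
                     length = glen)
        next
      }
      for (d in seq_len(seq$dims)) {
        a <- seq$coords[gs - 1L, j, d]
        b <- seq$coords[ge + 1L, j, d]
        w <- seq_len(glen) / (glen + 1)
        seq$coords[gs:ge, j, d] <- a + w * (b - a)
      }
      seq$missing[gs:ge, j] <- FALSE
      if (!is.null(seq$confidence)) seq$confidence[gs:ge, j] <- NA_real_
    }
  }
  attr(seq, "usable_range") <- c(first_ok - 1L, last_ok - 1L)
  attr(seq, "splits") <- if (length(splits)) do.call(rbind, splits) else NULL
  seq
}

#' Zero-phase Butterworth low-pass filter of a signal
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (so the net response is the squared magnitude with zero phase), with odd
#' signal-reflection padding at both ends so endpoints see no artificial
#' step.  A constant signal passes through unchanged to machine precision; a
#' sinusoid at the cutoff frequency is attenuated to one half of its
#' amplitude (half-power applied twice).
#'
#' @param x Numeric vector, gap free.
#' @param fps Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency, `0 < cutoff_hz < fps/2`.
#' @param order Filter order (default 2).
#' @return Filtered numeric vector, same length as `x`.
#' @export
butter_filtfilt <- function(x, fps, cutoff_hz = 8, order = 2) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fps / 2)
  n <- length(x)
  flt <- signal::butter(order, cutoff_hz / (fps / 2), type = "low")
  b <- flt$b
  a <- flt$a
  L <- length(b)
  min_n <- 3L * 3L * L  # 3 x filter pad length
  if (n <= min_n) stop("bout too short to filter", call. = FALSE)
  r <- max(Mod(polyroot(rev(a))))
  pad <- ceiling(log(1e-13) / log(max(r, 1e-6)))
  pad <- max(3L * L, min(as.integer(pad), n - 1L))
  one_pass <- function(v) {
    ext <- c(2 * v[1] - v[(pad + 1L):2L], v, 2 * v[length(v)] -
               v[(length(v) - 1L):(length(v) - pad)])
    m <- length(ext)
    # FIR (numerator) part
    u <- stats::filter(ext, b, method = "convolution", sides = 1)
    u <- as.numeric(u)
    for (t in seq_len(L - 1L)) {
      xt <- ext[pmax(t - seq_len(L) + 1L, 1L)]
      u[t] <- sum(b * xt)
    }
    # IIR (denominator) part with steady-state initialization
    y0 <- ext[1] * sum(b) / sum(a)
    y <- stats::filter(u, -a[-1], method = "recursive",
                       init = rep(y0, L - 1L))
    as.numeric(y)
  }
  y <- one_pass(x)
  y <- rev(one_pass(rev(y[(pad + 1L):(pad + n)])))
  y <- y[(pad + 1L):(pad + n)]
  y
}

#' Smooth joint trajectories
#'
#' Runs the zero-phase Butterworth low-pass filter over every maximal
#' gap-free run of each configured joint's coordinates.  Runs shorter than
#' the filter's padding requirement are left unfiltered and reported in
#' attribute `"unfiltered_runs"`; if no run of a configured joint can be
#' filtered the bout is rejected.
#'
#' @param seq A gap-filled [pose_sequence()] (see [interpolate_gaps()]).
#' @param cfg A [preprocess_config()].
#' @return The smoothed `pose_sequence`.
#' @export
smooth_trajectories <- function(seq, cfg = preprocess_config()) {
  stopifnot(cfg$cutoff_hz < seq$fps / 2)
  joints <- intersect(cfg$joints, seq$joint_names)
  L <- cfg$filter_order + 1L
  min_n <- 3L * 3L * L
  skipped <- list()
  noise <- list()
  any_filtered <- FALSE
  for (j in joints) {
    ok <- !seq$missing[, j]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      if (r$lengths[g] <= min_n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(joint = j, run_start = starts[g] - 1L,
                     run_len = r$lengths[g])
        next
      }
      idx <- starts[g]:ends[g]
      res <- 0
      for (d in seq_len(seq$dims)) {
        raw <- seq$coords[idx, j, d]
        sm <- butter_filtfilt(raw, fps = seq$fps,
                              cutoff_hz = cfg$cutoff_hz,
                              order = cfg$filter_order)
        seq$coords[idx, j, d] <- sm
        res <- res + (1.4826 * stats::mad(raw - sm, center = 0))^2
      }
      noise[[j]] <- c(noise[[j]], sqrt(res / seq$dims))
      any_filtered <- TRUE
    }
  }
  if (!any_filtered) stop("bout too short to filter", call. = FALSE)
  attr(seq, "unfiltered_runs") <- if (length(skipped))
    do.call(rbind, skipped) else NULL
  # robust per-joint estimate of the keypoint jitter removed by smoothing;
  # downstream stance detection uses it as a noise floor for its radius
  attr(seq, "noise_px") <- vapply(noise, mean, numeric(1))
  attr(seq, "smoothed") <- TRUE
  seq
}

#' Full preprocessing pass
#'
#' Confidence masking, gap interpolation and trajectory smoothing in the
#' pipeline's canonical order.
#'
#' @inheritParams mask_low_confidence
#' @return The preprocessed `pose_sequence`.
#' @export
preprocess_sequence <- function(seq, cfg = preprocess_config(),
                                estimator = NULL) {
  seq <- mask_low_confidence(seq, cfg, estimator)
  masked <- attr(seq, "masked_fraction")
  seq <- interpolate_gaps(seq, cfg)
  ur <- attr(seq, "usable_range")
  spl <- attr(seq, "splits")
  seq <- smooth_trajectories(seq, cfg)
  attr(seq, "masked_fraction") <- masked
  attr(seq, "usable_range") <- ur
  attr(seq, "splits") <- spl
  seq
}
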