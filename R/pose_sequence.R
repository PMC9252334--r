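# Canonical joint vocabulary used internally.  Loaders translate
# estimator-specific keypoint schemes into these names; downstream code only
# ever asks for canonical names.
.required_joints <- c("left_ankle", "right_ankle", "left_hip", "right_hip")

.joint_schemes <- list(
  # COCO 17-keypoint ordering (AlphaPose, Detectron)
  coco17 = c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle"
  ),
  # OpenPose COCO 18-keypoint ordering
  coco18 = c(
    "nose", "neck", "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder", "left_elbow", "left_wrist", "right_hip", "right_knee",
    "right_ankle", "left_hip", "left_knee", "left_ankle", "right_eye",
    "left_eye", "right_ear", "left_ear"
  ),
  # OpenPose BODY_25 ordering
  body25 = c(
    "nose", "neck", "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder", "left_elbow", "left_wrist", "mid_hip", "right_hip",
    "right_knee", "right_ankle", "left_hip", "left_knee", "left_ankle",
    "right_eye", "left_eye", "right_ear", "left_ear", "left_big_toe",
    "left_small_toe", "left_heel", "right_big_toe", "right_small_toe",
    "right_heel"
  ),
  # Minimal scheme emitted by the built-in simulator
  synthetic4 = c("left_hip", "right_hip", "left_ankle", "right_ankle")
)

#' Keypoint ordering of a named joint scheme
#'
#' Returns the canonical joint names, in keypoint order, for one of the
#' supported pose-estimator output schemes.
#'
#' @param name One of `"coco17"`, `"coco18"`, `"body25"`, `"synthetic4"`.
#' @return Character vector of canonical joint names.
#' @export
joint_scheme <- function(name) {
  if (!name %in% names(.joint_schemes)) {
    stop("unsupported joint scheme: ", name, call. = FALSE)
  }
  .joint_schemes[[name]]
}

#' Construct a pose sequence
#'
#' A `pose_sequence` is the pipeline's universal carrier: a frames x joints x
#' coords array of keypoint positions with per-frame confidence scores and a
#' missingness mask.  Frames are 0-based; frame `i` occurs at time `i / fps`
#' seconds.  Coordinates follow the image convention for 2D input (x
#' rightward, y downward, pixels) and, for 3D input, x lateral / y vertical /
#' z depth in meters.
#'
#' @param coords Numeric array `frames x joints x D` (`D` of 2 or 3) with
#'   joint names on the second dimension.
#' @param fps Frame rate in frames per second (> 0).
#' @param confidence Optional `frames x joints` matrix in `[0, 1]`; may be
#'   `NULL` for 3D input lacking confidence scores.
#' @param missing Optional logical `frames x joints` mask; defaults to
#'   non-finite coordinates.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, fps, confidence = NULL, missing = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  jn <- dimnames(coords)[[2]]
  if (is.null(jn)) stop("coords must carry joint names", call. = FALSE)
  absent <- setdiff(.required_joints, jn)
  if (length(absent)) {
    stop("joint scheme must resolve ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  nf <- dim(coords)[1]
  nj <- dim(coords)[2]
  if (!is.null(confidence)) {
    stopifnot(is.matrix(confidence), nrow(confidence) == nf,
              ncol(confidence) == nj)
  }
  if (is.null(missing)) {
    missing <- apply(coords, c(1, 2), function(v) any(!is.finite(v)))
  }
  stopifnot(is.matrix(missing) || nf == 0L, all(dim(missing) == c(nf, nj)))
  dimnames(missing) <- list(NULL, jn)
  if (!is.null(confidence)) dimnames(confidence) <- list(NULL, jn)
  structure(
    list(coords = coords, confidence = confidence, missing = missing,
         fps = fps, joint_names = jn, dims = dim(coords)[3]),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames x %d joints x %dD @ %g fps\n",
              n_frames(x), length(x$joint_names), x$dims, x$fps))
  cat(sprintf("  missing: %.1f%% of joint-frames\n", 100 * mean(x$missing)))
  ur <- usable_range(x)
  if (!is.null(ur)) cat(sprintf("  usable frames: %d..%d\n", ur[1], ur[2]))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Usable frame range of a pose sequence
#'
#' After gap interpolation ([interpolate_gaps()]) the leading/trailing
#' untracked frames are trimmed; this returns the 0-based inclusive frame
#' range that survived, or `NULL` if the sequence has not been trimmed.
#'
#' @param seq A `pose_sequence`.
#' @return Integer vector `c(first, last)` (0-based, inclusive) or `NULL`.
#' @export
usable_range <- function(seq) attr(seq, "usable_range")

#' Per-frame trajectory of one joint
#'
#' @param seq A `pose_sequence`.
#' @param joint Canonical joint name.
#' @return Numeric matrix `frames x D`.
#' @export
joint_track <- function(seq, joint) {
  if (!joint %in% seq$joint_names) {
    stop("unknown joint: ", joint, call. = FALSE)
  }
  m <- seq$coords[, joint, , drop = FALSE]
  dim(m) <- c(dim(seq$coords)[1], seq$dims)
  m
}

#' Bout metadata
#'
#' Describes one walking bout within a pose sequence: a half-open frame range
#' `[frame_start, frame_end)`, walking direction relative to the camera, the
#' pose-estimator tag (used to pick confidence thresholds), treatment state
#' and subject id.
#'
#' @param bout_id Bout identifier string.
#' @param frame_start,frame_end 0-based frame range, start inclusive, end
#'   exclusive.
#' @param direction `"toward"`, `"away"` or `"unknown"`.
#' @param estimator Free-form source tag, e.g. `"alphapose"`.
#' @param treatment_state `"ON"`, `"OFF"` or `"unknown"`.
#' @param subject_id Subject identifier string.
#' @return An object of class `bout_meta`.
#' @export
bout_meta <- function(bout_id, frame_start, frame_end,
                      direction = c("unknown", "toward", "away"),
                      estimator = "unknown",
                      treatment_state = c("unknown", "ON", "OFF"),
                      subject_id = "s1") {
  direction <- match.arg(direction)
  treatment_state <- match.arg(treatment_state)
  frame_start <- as.integer(frame_start)
  frame_end <- as.integer(frame_end)
  if (frame_start >= frame_end) {
    stop("frame_start must be < frame_end", call. = FALSE)
  }
  structure(
    list(bout_id = as.character(bout_id), frame_start = frame_start,
         frame_end = frame_end, direction = direction, estimator = estimator,
         treatment_state = treatment_state, subject_id = subject_id),
    class = "bout_meta"
  )
}
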