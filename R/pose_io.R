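# Readers/writers for the three exchange formats the pipeline touches:
#  * per-frame JSON emitted by 2D pose estimators,
#  * long-format keypoint CSV (frame, joint, x, y[, z], confidence) -- the
#    canonical exchange format, also emitted by the simulator,
#  * heel-strike annotation CSV (bout_id, frame, foot).

#' Read a directory of per-frame pose-estimator JSON files
#'
#' Ingests the JSON dialect of 2D pose estimators: one file per frame, each
#' holding a `people` list whose entries carry a flat
#' `[x1, y1, c1, x2, y2, c2, ...]` keypoint array (under `pose_keypoints_2d`
#' or `pose_keypoints`).  When several people are detected in a frame, the
#' detection with the highest mean keypoint confidence is kept.  Frames are
#' ordered by the numeric index embedded in each filename; gaps in the index
#' sequence are filled with all-missing frames (with a warning).
#'
#' @param path Directory containing `*.json` files.
#' @param joint_scheme_name Keypoint ordering of the files; see
#'   [joint_scheme()].
#' @param fps Frame rate to record on the sequence (default 30).
#' @return A [pose_sequence()].
#' @export
read_pose_json_dir <- function(path, joint_scheme_name, fps = 30) {
  jn <- joint_scheme(joint_scheme_name)
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no frames: no JSON files in ", path, call. = FALSE)
  idx <- vapply(basename(files), function(f) {
    m <- regmatches(f, regexpr("[0-9]+", f))
    if (!length(m)) NA_real_ else as.numeric(m)
  }, numeric(1))
  if (anyNA(idx)) stop("cannot parse frame index from filename", call. = FALSE)
  ord <- order(idx)
  files <- files[ord]
  idx <- as.integer(idx[ord])
  if (anyDuplicated(idx)) stop("duplicated frame indices", call. = FALSE)
  idx <- idx - idx[1]
  nf <- idx[length(idx)] + 1L
  if (nf > length(files)) {
    warning("frame-index gaps: inserting ", nf - length(files),
            " all-missing frame(s)", call. = FALSE)
  }
  nj <- length(jn)
  coords <- array(NA_real_, c(nf, nj, 2), dimnames = list(NULL, jn, c("x", "y")))
  conf <- matrix(0, nf, nj, dimnames = list(NULL, jn))
  for (k in seq_along(files)) {
    doc <- jsonlite::fromJSON(files[k], simplifyVector = TRUE)
    ppl <- doc$people
    kp <- NULL
    if (!is.null(ppl) && NROW(ppl) > 0) {
      get_kp <- function(i) {
        v <- if (is.data.frame(ppl)) {
          ppl$pose_keypoints_2d[[i]] %||% ppl$pose_keypoints[[i]]
        } else {
          ppl[[i]]$pose_keypoints_2d %||% ppl[[i]]$pose_keypoints
        }
        as.numeric(v)
      }
      np <- if (is.data.frame(ppl)) nrow(ppl) else length(ppl)
      cand <- lapply(seq_len(np), get_kp)
      cand <- Filter(function(v) length(v) == 3L * nj, cand)
      if (length(cand)) {
        scores <- vapply(cand, function(v) mean(v[seq(3, length(v), 3)]),
                         numeric(1))
        kp <- cand[[which.max(scores)]]
      }
    }
    if (!is.null(kp)) {
      r <- idx[k] + 1L
      kp <- matrix(kp, ncol = 3, byrow = TRUE)
      coords[r, , 1] <- kp[, 1]
      coords[r, , 2] <- kp[, 2]
      conf[r, ] <- kp[, 3]
    }
  }
  missing <- !is.finite(coords[, , 1, drop = FALSE][, , 1]) | conf <= 0
  dim(missing) <- c(nf, nj)
  pose_sequence(coords, fps = fps, confidence = conf, missing = missing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write the long-format keypoint CSV
#'
#' The canonical exchange format: one row per observed (frame, joint) with
#' columns `frame, joint, x, y[, z], confidence`.  Unobserved joint-frames
#' simply have no row and come back flagged in the missingness mask; the
#' write/read round trip is lossless for every finite value and the reader is
#' invariant to row order.
#'
#' @param path CSV file path.
#' @param fps Frame rate to record on the sequence (default 30).
#' @param n_frames Optional total frame count; defaults to `max(frame) + 1`.
#' @return A [pose_sequence()].
#' @export
read_pose_csv <- function(path, fps = 30, n_frames = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "x", "y")
  if (!all(need %in% names(df))) {
    stop("pose CSV must have columns frame, joint, x, y", call. = FALSE)
  }
  for (col in intersect(c("frame", "x", "y", "z", "confidence"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at row ", bad[1],
             call. = FALSE)
      }
      df[[col]] <- conv
    }
  }
  if (anyDuplicated(df[c("frame", "joint")])) {
    stop("duplicated (frame, joint) rows in pose CSV", call. = FALSE)
  }
  has_z <- "z" %in% names(df) && any(is.finite(df$z))
  d <- if (has_z) 3L else 2L
  jn <- unique(df$joint)
  # canonical joints first, in a stable order
  jn <- c(intersect(.joint_schemes$synthetic4, jn),
          setdiff(sort(jn), .joint_schemes$synthetic4))
  nf <- if (is.null(n_frames)) as.integer(max(df$frame)) + 1L else
    as.integer(n_frames)
  nj <- length(jn)
  ax <- c("x", "y", if (has_z) "z")
  coords <- array(NA_real_, c(nf, nj, d), dimnames = list(NULL, jn, ax))
  conf <- matrix(0, nf, nj, dimnames = list(NULL, jn))
  ji <- match(df$joint, jn)
  fi <- as.integer(df$frame) + 1L
  if (any(fi < 1L | fi > nf)) stop("frame index out of range", call. = FALSE)
  coords[cbind(fi, ji, 1L)] <- df$x
  coords[cbind(fi, ji, 2L)] <- df$y
  if (has_z) coords[cbind(fi, ji, 3L)] <- df$z
  if ("confidence" %in% names(df)) {
    conf[cbind(fi, ji)] <- df$confidence
  } else {
    conf[cbind(fi, ji)] <- 1
  }
  missing <- matrix(TRUE, nf, nj)
  missing[cbind(fi, ji)] <- FALSE
  missing <- missing | !is.finite(coords[, , 1, drop = FALSE][, , 1])
  pose_sequence(coords, fps = fps, confidence = conf, missing = missing)
}

#' @rdname read_pose_csv
#' @param seq A [pose_sequence()] to write.
#' @export
write_pose_csv <- function(seq, path) {
  nf <- n_frames(seq)
  jn <- seq$joint_names
  keep <- !seq$missing
  fi <- row(keep)[keep]
  ji <- col(keep)[keep]
  df <- data.frame(
    frame = fi - 1L,
    joint = jn[ji],
    x = seq$coords[cbind(fi, ji, 1L)],
    y = seq$coords[cbind(fi, ji, 2L)]
  )
  if (seq$dims == 3L) df$z <- seq$coords[cbind(fi, ji, 3L)]
  df$confidence <- if (is.null(seq$confidence)) 1 else
    seq$confidence[cbind(fi, ji)]
  df <- df[order(df$frame, match(df$joint, jn)), ]
  # 17 significant digits round-trip doubles exactly
  for (col in intersect(c("x", "y", "z", "confidence"), names(df))) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heel-strike annotation CSV
#'
#' Manual heel-strike annotations as a CSV with columns
#' `bout_id, frame, foot` (`foot` in `left`/`right`).  Frames are sorted
#' ascending within each foot; when bout metadata is supplied every frame is
#' validated against the bout's frame range.
#'
#' @param path CSV file path.
#' @param bout Optional [bout_meta()] to validate frame ranges against.
#' @return An `annotation_set`: data frame with columns
#'   `bout_id, frame, foot`.
#' @export
read_annotations <- function(path, bout = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bout_id", "frame", "foot")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns bout_id, frame, foot",
         call. = FALSE)
  }
  annotation_set(df$frame, df$foot, bout_id = df$bout_id, bout = bout)
}

#' Construct an annotation set
#'
#' @param frame Integer vector of annotated heel-strike frames (0-based).
#' @param foot Character vector, `"left"` or `"right"`.
#' @param bout_id Bout identifier(s).
#' @param bout Optional [bout_meta()] for range validation.
#' @return Data frame of class `annotation_set`.
#' @export
annotation_set <- function(frame, foot, bout_id = "b1", bout = NULL) {
  foot <- as.character(foot)
  bad <- setdiff(unique(foot), c("left", "right"))
  if (length(bad)) {
    stop("foot must be 'left' or 'right', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(bout_id = as.character(bout_id),
                   frame = as.integer(frame), foot = foot,
                   stringsAsFactors = FALSE)
  df <- df[order(df$bout_id, df$foot, df$frame), ]
  rownames(df) <- NULL
  for (b in unique(df$bout_id)) {
    for (ft in c("left", "right")) {
      f <- df$frame[df$bout_id == b & df$foot == ft]
      if (anyDuplicated(f)) {
        stop("duplicate annotation frames for foot ", ft, " in bout ", b,
             call. = FALSE)
      }
    }
  }
  if (!is.null(bout)) {
    out <- df$frame < bout$frame_start | df$frame >= bout$frame_end
    if (any(out)) {
      stop("annotation frame ", df$frame[which(out)[1]],
           " outside range of bout ", bout$bout_id, call. = FALSE)
    }
  }
  class(df) <- c("annotation_set", "data.frame")
  df
}
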