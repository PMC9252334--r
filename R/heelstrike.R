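# Stance detection and heel-strike events.
#
# A stance is a spatiotemporal cluster of ankle samples: the ankle keypoint
# stays (nearly) stationary on the ground for a sustained stretch of frames.
# ST-DBSCAN finds such clusters by requiring neighbours to be close in both
# space (eps_spatial) and time (eps_temporal); the heel strike is the first
# timestep of each detected stance.

#' ST-DBSCAN parameters
#'
#' @param eps_spatial Spatial neighbourhood radius.  In pixels (or meters for
#'   3D input); when `NULL` (default) it is resolved per bout as
#'   `eps_hip_frac` times the median apparent hip width, which ties the
#'   stationarity tolerance to image scale.  In hip-width multiples when
#'   `normalize_by_hip_width = TRUE`.
#' @param eps_hip_frac Fraction of the bout's median hip width used to
#'   auto-resolve `eps_spatial` (default 0.06; validated on the synthetic
#'   recovery suite, where it separates consecutive normal-gait stances at
#'   all walkway depths while merging far-field shuffling steps).
#' @param eps_temporal Temporal neighbourhood radius in seconds
#'   (default 0.13, i.e. +/- 3 frames at 30 Hz).  Must be shorter than the time the swinging ankle's
#'   projection spends near the landing position, or pre-landing swing
#'   samples join the stance and bias the detected strike early.
#' @param min_pts Minimum number of neighbours (the point itself included)
#'   for a core point (default 4).
#' @param normalize_by_hip_width If `TRUE`, coordinates are divided by the
#'   per-frame hip width before clustering, making `eps_spatial` a hip-width
#'   multiple and the tolerance depth-adaptive.  Off by default: clustering
#'   in raw camera space preserves the far-field behaviour of frontal video,
#'   where distant short steps merge into one cluster.
#' @param min_stance_s Minimum stance duration in seconds (default 0.3);
#'   detected clusters shorter than this are discarded as jitter or slow
#'   swing phases.
#' @param noise_eps_mult When `eps_spatial` is auto-resolved, the radius is
#'   floored at this multiple of the estimated residual keypoint jitter
#'   (see [smooth_trajectories()]), so stationary samples reach core
#'   density under observation noise (default 2).
#' @param min_stride_s Two stances of one foot cannot begin closer than a
#'   physiological stride; of a same-foot pair starting within this many
#'   seconds, the shorter is discarded as an artifact (default 0.65, below
#'   the stride time of even a fast shuffle).
#' @return An `stdbscan_params` list.
#' @export
stdbscan_params <- function(eps_spatial = NULL, eps_hip_frac = 0.06,
                            eps_temporal = 0.13, min_pts = 4,
                            normalize_by_hip_width = FALSE,
                            min_stance_s = 0.3, noise_eps_mult = 2.0,
                            min_stride_s = 0.65) {
  stopifnot(is.null(eps_spatial) || eps_spatial > 0,
            eps_hip_frac > 0, eps_temporal > 0, min_pts >= 2,
            noise_eps_mult >= 0, min_stride_s >= 0)
  structure(list(eps_spatial = eps_spatial, eps_hip_frac = eps_hip_frac,
                 eps_temporal = eps_temporal, min_pts = as.integer(min_pts),
                 normalize_by_hip_width = isTRUE(normalize_by_hip_width),
                 min_stance_s = min_stance_s,
                 noise_eps_mult = noise_eps_mult,
                 min_stride_s = min_stride_s),
            class = "stdbscan_params")
}

#' Spatiotemporal DBSCAN
#'
#' Density-based clustering in which a point's neighbourhood consists of the
#' points within `eps_spatial` (Euclidean, over the coordinate columns) AND
#' within `eps_temporal` in time.  Core points (at least `min_pts`
#' neighbours, themselves included) are expanded into clusters exactly as in
#' classical DBSCAN; points never density-reachable are labelled noise.
#' Expansion visits points in time order and cluster ids are assigned in
#' order of discovery, so labels are deterministic for a fixed input order.
#'
#' @param times Numeric vector of timestamps (seconds), non-decreasing.
#' @param coords Numeric matrix `n x D` (`D` in 1..3) of coordinates.
#' @param eps_spatial,eps_temporal Neighbourhood radii (> 0).
#' @param min_pts Core-point threshold (>= 2), point itself included.
#' @return Integer vector of cluster labels (`1, 2, ...` in discovery order;
#'   `-1` = noise).  Empty input gives an empty vector.
#' @export
st_dbscan <- function(times, coords, eps_spatial, eps_temporal, min_pts) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, eps_spatial > 0, eps_temporal > 0,
            min_pts >= 2)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  eps2 <- eps_spatial^2
  neighbors <- function(i) {
    lo <- findInterval(times[i] - eps_temporal, times, left.open = TRUE) + 1L
    hi <- findInterval(times[i] + eps_temporal, times)
    cand <- lo:hi
    d2 <- rowSums((coords[cand, , drop = FALSE] -
                     rep(coords[i, ], each = length(cand)))^2)
    cand[d2 <= eps2]
  }
  labels <- integer(n)  # 0 = unclassified, -1 = noise, >0 = cluster id
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- neighbors(i)
    if (length(nb) < min_pts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- nb[nb != i]
    while (length(seeds)) {
      q <- seeds[1L]
      seeds <- seeds[-1L]
      if (labels[q] == -1L) labels[q] <- cl  # border point
      if (labels[q] != 0L) next
      labels[q] <- cl
      nbq <- neighbors(q)
      if (length(nbq) >= min_pts) {
        seeds <- c(seeds, nbq[labels[nbq] == 0L | labels[nbq] == -1L])
      }
    }
  }
  labels
}

resolve_eps_spatial <- function(seq, params, frames, joint = NULL) {
  if (!is.null(params$eps_spatial)) return(params$eps_spatial)
  hw <- hip_width(seq)
  med <- stats::median(hw[frames + 1L], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop("cannot resolve eps_spatial: hip width unavailable", call. = FALSE)
  }
  eps <- params$eps_hip_frac * med
  # the radius must exceed the residual keypoint jitter or stationary
  # samples fail to reach core density
  np <- attr(seq, "noise_px")
  if (!is.null(np) && !is.null(joint) && joint %in% names(np) &&
      is.finite(np[[joint]])) {
    eps <- max(eps, params$noise_eps_mult * np[[joint]])
  }
  eps
}

#' Detect stances of one foot
#'
#' Runs [st_dbscan()] on the (time, coordinates) samples of one ankle over
#' the bout's usable range, then turns clusters into stances: clusters
#' shorter than the minimum stance duration are discarded as jitter,
#' overlapping same-foot clusters are merged, and a stance whose first frame
#' coincides with the first observable frame is dropped (its onset -- the
#' heel strike -- happened before the observation window and cannot be
#' timed).
#'
#' @param seq A preprocessed [pose_sequence()] (smoothed, usable range set).
#' @param foot `"left"` or `"right"`.
#' @param params An [stdbscan_params()].
#' @param bout Optional [bout_meta()] restricting the frame range.
#' @param drop_boundary Drop a stance that begins within the temporal
#'   radius of the start of the observation window (default `TRUE`): its
#'   onset -- the heel strike -- may predate the window and cannot be
#'   timed.
#' @return Data frame of stances ordered by `frame_first`, with columns
#'   `foot, frame_first, frame_last, n, x, y[, z]` (positions are cluster
#'   medians) and the member frames in attribute `"members"`.
#' @export
detect_stances <- function(seq, foot = c("left", "right"),
                           params = stdbscan_params(), bout = NULL,
                           drop_boundary = TRUE) {
  foot <- match.arg(foot)
  joint <- paste0(foot, "_ankle")
  ur <- usable_range(seq)
  if (is.null(ur)) ur <- c(0L, n_frames(seq) - 1L)
  if (!is.null(bout)) {
    ur <- c(max(ur[1], bout$frame_start), min(ur[2], bout$frame_end - 1L))
  }
  frames <- ur[1]:ur[2]
  ok <- !seq$missing[frames + 1L, joint]
  frames <- frames[ok]
  if (length(frames) < params$min_pts) {
    stop("no stance data: ankle untrackable for foot ", foot, call. = FALSE)
  }
  track <- joint_track(seq, joint)[frames + 1L, , drop = FALSE]
  if (params$normalize_by_hip_width) {
    hw <- hip_width(seq)[frames + 1L]
    if (any(!is.finite(hw) | hw <= 0)) {
      stop("cannot normalize: hip width unavailable", call. = FALSE)
    }
    track <- track / hw
    eps_s <- if (is.null(params$eps_spatial)) params$eps_hip_frac else
      params$eps_spatial
  } else {
    eps_s <- resolve_eps_spatial(seq, params, frames, joint)
  }
  tt <- frames / seq$fps
  labels <- st_dbscan(tt, track, eps_spatial = eps_s,
                      eps_temporal = params$eps_temporal,
                      min_pts = params$min_pts)
  min_stance <- params$min_stance_s %||% 0.3
  ids <- sort(unique(labels[labels > 0L]))
  cl_median <- function(mf) {
    apply(track[match(mf, frames), , drop = FALSE], 2, stats::median)
  }
  st <- lapply(ids, function(id) {
    mf <- frames[labels == id]
    list(frames = mf, first = min(mf), last = max(mf), pos = cl_median(mf))
  })
  if (length(st) > 1L) {
    # Merge same-foot clusters that overlap, or that are nearly contiguous
    # in time AND co-located in space: the latter are fragments of one
    # physical stance split by observation noise.
    gap_max <- round(0.2 * seq$fps)
    st <- st[order(vapply(st, `[[`, integer(1), "first"))]
    merged <- list(st[[1]])
    for (s in st[-1]) {
      lastm <- merged[[length(merged)]]
      touching <- s$first <= lastm$last
      rejoin <- (s$first - lastm$last) <= gap_max &&
        sqrt(sum((s$pos - lastm$pos)^2)) <= eps_s
      if (touching || rejoin) {
        lastm$frames <- sort(union(lastm$frames, s$frames))
        lastm$first <- min(lastm$first, s$first)
        lastm$last <- max(lastm$last, s$last)
        lastm$pos <- cl_median(lastm$frames)
        merged[[length(merged)]] <- lastm
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    st <- merged
  }
  bmargin <- max(2L, ceiling(params$eps_temporal * seq$fps))
  keep <- vapply(st, function(s) {
    dur <- (s$last - s$first + 1L) / seq$fps
    dur >= min_stance && !(drop_boundary && s$first <= ur[1] + bmargin)
  }, logical(1))
  st <- st[keep]
  # Two stances of the same foot cannot begin less than a physiological
  # stride apart; when they do, the shorter one is an artifact (typically
  # the projected swing arc briefly stalling in image space) and is dropped.
  if (length(st) > 1L) {
    repeat {
      starts <- vapply(st, `[[`, integer(1), "first")
      gaps <- diff(starts) / seq$fps
      bad <- which(gaps < params$min_stride_s)
      if (!length(bad)) break
      i <- bad[1L]
      drop_i <- if (length(st[[i]]$frames) <= length(st[[i + 1L]]$frames))
        i else i + 1L
      st <- st[-drop_i]
      if (length(st) < 2L) break
    }
  }
  raw_track <- joint_track(seq, joint)
  pos <- t(vapply(st, function(s) {
    apply(raw_track[s$frames + 1L, , drop = FALSE], 2, stats::median)
  }, numeric(seq$dims)))
  ax <- c("x", "y", "z")[seq_len(seq$dims)]
  out <- data.frame(
    foot = rep(foot, length(st)),
    frame_first = vapply(st, `[[`, integer(1), "first"),
    frame_last = vapply(st, `[[`, integer(1), "last"),
    n = vapply(st, function(s) length(s$frames), integer(1))
  )
  if (length(st)) {
    out[ax] <- as.data.frame(pos)
  } else {
    for (a in ax) out[[a]] <- numeric(0)
  }
  out <- out[order(out$frame_first), ]
  rownames(out) <- NULL
  attr(out, "members") <- lapply(st, `[[`, "frames")
  attr(out, "eps_spatial") <- eps_s
  out
}

.event_frame <- function(frames, time_s, foot, pos, source, interpolated) {
  ax <- c("x", "y", "z")[seq_len(ncol(pos))]
  df <- data.frame(frame = as.integer(frames), time_s = time_s,
                   foot = foot, source = source,
                   interpolated = interpolated)
  df[ax] <- as.data.frame(pos)
  class(df) <- c("heel_strikes", "data.frame")
  df
}

#' Heel strikes from detected stances
#'
#' One event per stance: the heel strike is the first timestep of the
#' stance; the event position is the smoothed ankle position at that frame.
#'
#' @param stances Output of [detect_stances()].
#' @param seq The same preprocessed [pose_sequence()].
#' @return A `heel_strikes` data frame with columns
#'   `frame, time_s, foot, source, interpolated, x, y[, z]`.
#' @export
heel_strikes_auto <- function(stances, seq) {
  fr <- stances$frame_first
  joint <- paste0(unique(stances$foot), "_ankle")
  ax <- c("x", "y", "z")[seq_len(seq$dims)]
  if (!nrow(stances)) {
    return(.event_frame(integer(0), numeric(0), character(0),
                        matrix(numeric(0), 0, seq$dims), character(0),
                        logical(0)))
  }
  pos <- joint_track(seq, joint)[fr + 1L, , drop = FALSE]
  .event_frame(fr, fr / seq$fps, stances$foot, pos, "auto", FALSE)
}

#' Heel strikes from manual annotations
#'
#' Manual annotation times the strike from the video; the strike position is
#' read off the smoothed joint trajectory at the annotated frame.  Events
#' whose frame falls in an untrackable gap (no spatial data at all) are
#' dropped with a warning; events at interpolated frames are kept and
#' flagged.
#'
#' @param annotations An [annotation_set()].
#' @param seq A preprocessed [pose_sequence()].
#' @return A `heel_strikes` data frame (`source = "manual"`).
#' @export
heel_strikes_manual <- function(annotations, seq) {
  fr <- annotations$frame
  foot <- annotations$foot
  joint <- paste0(foot, "_ankle")
  ji <- match(joint, seq$joint_names)
  ur <- usable_range(seq) %||% c(0L, n_frames(seq) - 1L)
  gap <- seq$missing[cbind(fr + 1L, ji)] | fr < ur[1] | fr > ur[2]
  if (any(gap)) {
    warning(sum(gap), " annotation(s) dropped: no spatial data at the ",
            "annotated frame", call. = FALSE)
  }
  fr <- fr[!gap]
  foot <- foot[!gap]
  ji <- ji[!gap]
  interp <- if (!is.null(seq$confidence) && length(fr)) {
    is.na(seq$confidence[cbind(fr + 1L, ji)])
  } else {
    rep(FALSE, length(fr))
  }
  pos <- matrix(NA_real_, length(fr), seq$dims)
  for (d in seq_len(seq$dims)) pos[, d] <- seq$coords[cbind(fr + 1L, ji, d)]
  ord <- order(fr)
  .event_frame(fr[ord], fr[ord] / seq$fps, foot[ord], pos[ord, , drop = FALSE],
               "manual", interp[ord])
}

#' Merge per-foot heel-strike lists into one step sequence
#'
#' Events are merged and sorted by time.  A step is the interval between two
#' consecutive events; it is valid only when the two events come from
#' opposite feet at distinct frames.  Consecutive same-foot events (a missed
#' opposite-foot strike) and same-frame left/right ties (tie broken
#' left-first) are flagged, and the steps they bound are excluded from
#' step-level features.
#'
#' @param left_events,right_events `heel_strikes` data frames, each sorted.
#' @return A `heel_strikes` data frame sorted by time with a logical column
#'   `valid_step`: `TRUE` for events that validly terminate a step.
#' @export
merge_feet <- function(left_events, right_events) {
  ev <- rbind(as.data.frame(left_events), as.data.frame(right_events))
  # sort by frame; ties left-first
  ev <- ev[order(ev$frame, match(ev$foot, c("left", "right"))), ]
  rownames(ev) <- NULL
  n <- nrow(ev)
  valid <- rep(FALSE, n)
  if (n >= 2L) {
    prev_foot <- ev$foot[-n]
    prev_frame <- ev$frame[-n]
    valid[-1L] <- ev$foot[-1L] != prev_foot & ev$frame[-1L] > prev_frame
  }
  ev$valid_step <- valid
  ev$tie <- duplicated(ev$frame) | duplicated(ev$frame, fromLast = TRUE)
  class(ev) <- c("heel_strikes", "data.frame")
  ev
}
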