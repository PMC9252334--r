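# Synthetic 3D walker with pinhole-camera projection.
#
# Emulates the study geometry this pipeline targets: a participant walking
# ~6 m along a straight walkway, filmed at 30 Hz by a static tripod camera
# positioned a couple of meters before the near end of the walkway, roughly
# at hip height, looking down the walkway axis.  The generator draws a
# heel-strike schedule from truncated-normal step time / length / width
# distributions, animates ankles (stationary during stance, smooth swing
# with sinusoidal vertical clearance) and hips, projects all joints through
# a pinhole model, and adds pixel noise and confidence dropout.  The exact
# schedule and the features it implies are returned as ground truth,
# playing the role of an instrumented walkway.

rtruncnorm1 <- function(n, mean, sd, lower = NULL, upper = NULL) {
  if (sd == 0) return(rep(mean, n))
  lo <- if (is.null(lower)) max(mean - 3 * sd, 1e-6) else lower
  hi <- if (is.null(upper)) mean + 3 * sd else upper
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Specification of one simulated walking bout
#'
#' Defaults encode the target recording setup: a 6 m walkway filmed at
#' 30 Hz and 640x480 by a camera 2 m before the walkway's near end, 1.2 m
#' high, pitched 5 degrees down, ~600 px focal length.  Step parameters
#' default to an unimpaired adult walking pattern.
#'
#' @param walkway_length_m Walkway length (default 6).
#' @param fps Frame rate (default 30).
#' @param image_size `c(width, height)` in pixels (default 640x480).
#' @param direction `"toward"` or `"away"` (relative to the camera).
#' @param step_length_m,step_time_s,step_width_m Lists with `mean`, `sd`
#'   and optional `lower`/`upper` truncation bounds (defaults truncate at
#'   +/- 3 sd and positivity).
#' @param hip_width_m Inter-hip distance (default 0.30).
#' @param camera List: `height_m` (1.2), `pitch_deg` (5, downward),
#'   `focal_px` (600), `principal_point` (image center), `offset_m`
#'   (camera-to-walkway-start distance along the axis, 2).
#' @param noise_px_sd Gaussian pixel noise on projected keypoints
#'   (default 0).
#' @param confidence_model List: `base` score (0.9) and `dropout_prob`
#'   (0); dropped joint-frames get a confidence drawn uniformly below 0.45
#'   so default thresholds mask them.
#' @param depth_output If `TRUE`, emit metric 3D coordinates (x lateral,
#'   y vertical, z depth) instead of projecting to pixels.
#' @param stance_fraction Fraction of each foot's stride spent in stance
#'   (default 0.6).
#' @param clearance_m Peak vertical excursion of the ankle keypoint
#'   during swing (default 0.15, typical of unimpaired gait where the heel
#'   rises steeply after toe-off; shuffling gait barely clears the ground,
#'   so the shuffling preset lowers this to 0.04).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   bouts (R's default Mersenne-Twister generator).
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(walkway_length_m = 6, fps = 30,
                      image_size = c(640, 480),
                      direction = c("away", "toward"),
                      step_length_m = list(mean = 0.55, sd = 0.05),
                      step_time_s = list(mean = 0.55, sd = 0.05),
                      step_width_m = list(mean = 0.10, sd = 0.02),
                      hip_width_m = 0.30,
                      camera = list(),
                      noise_px_sd = 0,
                      confidence_model = list(base = 0.9, dropout_prob = 0),
                      depth_output = FALSE,
                      stance_fraction = 0.6,
                      clearance_m = 0.15,
                      seed = NULL) {
  direction <- match.arg(direction)
  cam <- utils::modifyList(
    list(height_m = 1.2, pitch_deg = 5, focal_px = 600,
         principal_point = image_size / 2, offset_m = 2),
    camera)
  conf <- utils::modifyList(list(base = 0.9, dropout_prob = 0),
                            confidence_model)
  stopifnot(walkway_length_m > 0, fps > 0,
            step_length_m$mean > 0, step_time_s$mean > 0,
            step_width_m$mean > 0, hip_width_m > 0,
            cam$offset_m > 0, stance_fraction > 0, stance_fraction < 1)
  structure(list(
    walkway_length_m = walkway_length_m, fps = fps, image_size = image_size,
    direction = direction, step_length_m = step_length_m,
    step_time_s = step_time_s, step_width_m = step_width_m,
    hip_width_m = hip_width_m, camera = cam, noise_px_sd = noise_px_sd,
    confidence_model = conf, depth_output = isTRUE(depth_output),
    stance_fraction = stance_fraction, clearance_m = clearance_m,
    seed = seed), class = "walk_spec")
}

.draw_steps <- function(par, n) {
  rtruncnorm1(n, par$mean, par$sd, par$lower %||% NULL, par$upper %||% NULL)
}

# piecewise ankle track: stationary at strike positions during stance,
# cosine-eased swing with sinusoidal vertical clearance otherwise
.ankle_track <- function(t_grid, strike_t, strike_s, strike_lat,
                         stance_fraction, clearance) {
  ns <- length(strike_t)
  s <- numeric(length(t_grid))
  lat <- numeric(length(t_grid))
  h <- numeric(length(t_grid))
  s[] <- strike_s[1]
  lat[] <- strike_lat[1]
  for (j in seq_len(ns)) {
    if (j < ns) {
      stride <- strike_t[j + 1] - strike_t[j]
      lift <- strike_t[j] + stance_fraction * stride
      in_stance <- t_grid >= strike_t[j] & t_grid < lift
      in_swing <- t_grid >= lift & t_grid < strike_t[j + 1]
      s[in_stance] <- strike_s[j]
      lat[in_stance] <- strike_lat[j]
      if (any(in_swing)) {
        phase <- (t_grid[in_swing] - lift) / (strike_t[j + 1] - lift)
        ease <- (1 - cos(pi * phase)) / 2
        s[in_swing] <- strike_s[j] + ease * (strike_s[j + 1] - strike_s[j])
        lat[in_swing] <- strike_lat[j] +
          ease * (strike_lat[j + 1] - strike_lat[j])
        h[in_swing] <- clearance * sin(pi * phase)
      }
    } else {
      after <- t_grid >= strike_t[j]
      s[after] <- strike_s[j]
      lat[after] <- strike_lat[j]
    }
  }
  list(s = s, lat = lat, h = h)
}

.project <- function(X, Y, Z, cam) {
  th <- cam$pitch_deg * pi / 180
  yrel <- Y - cam$height_m
  xc <- X
  yc <- -yrel * cos(th) - Z * sin(th)
  zc <- -yrel * sin(th) + Z * cos(th)
  if (any(zc <= 0.1)) stop("walker behind (or at) the camera", call. = FALSE)
  list(u = cam$principal_point[1] + cam$focal_px * xc / zc,
       v = cam$principal_point[2] + cam$focal_px * yc / zc,
       zc = zc)
}

#' Simulate one walking bout
#'
#' Generates the heel-strike schedule, animates the walker with a short
#' lead-in and lead-out beyond the walkway (so the bout starts and ends
#' mid-gait, as real cropped bouts do), projects the joints and packages
#' the result.  The returned sequence covers exactly the bout frames; a
#' stance already in progress at frame 0 belongs to a pre-bout strike and
#' is intentionally present so detectors must cope with it.
#'
#' @param spec A [walk_spec()].
#' @param bout_id,subject_id Identifiers stored in the bout metadata.
#' @param treatment_state `"ON"`, `"OFF"` or `"unknown"`.
#' @return A list of class `simulated_walk` with elements `seq`
#'   ([pose_sequence()]), `gt` (ground truth: `$strikes` schedule,
#'   `$features` true feature row), `bout` ([bout_meta()]) and
#'   `annotations` (the true schedule as an [annotation_set()], i.e. an
#'   oracle manual annotator).
#' @export
simulate_walk <- function(spec = walk_spec(), bout_id = "b1",
                          subject_id = "s1",
                          treatment_state = "unknown") {
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  L <- spec$walkway_length_m
  # lead-in/out long enough that both feet have pre- and post-bout strikes,
  # so the bout starts and ends mid-gait for either foot
  pre <- 2.5 * spec$step_length_m$mean + 0.5
  post <- 2 * spec$step_length_m$mean + 0.4
  # draw until the post-roll is covered
  nmax <- ceiling((L + pre + post) /
                    max(spec$step_length_m$mean - 3 * spec$step_length_m$sd,
                        0.04)) + 4L
  len <- .draw_steps(spec$step_length_m, nmax)
  tim <- .draw_steps(spec$step_time_s, nmax)
  wid <- .draw_steps(spec$step_width_m, nmax)
  s <- cumsum(len) - pre
  tt <- cumsum(tim)
  idx_end <- which(s > L + post - 0.05)
  keep <- seq_len(if (length(idx_end)) idx_end[1] else nmax)
  s <- s[keep]
  tt <- tt[keep]
  wid <- wid[keep]
  foot <- rep(c("left", "right"), length.out = length(s))
  lat <- ifelse(foot == "left", -wid / 2, wid / 2)

  in_bout <- which(s >= 0 & s <= L)
  if (length(in_bout) < 3L) stop("walkway too short for 3 strikes",
                                 call. = FALSE)
  t0 <- tt[in_bout[1]] - 0.3
  t1 <- tt[in_bout[length(in_bout)]] + 0.4
  nf <- floor((t1 - t0) * spec$fps) + 1L
  tg <- t0 + (seq_len(nf) - 1L) / spec$fps

  # ankle world tracks (s = forward along walkway, lat = lateral, h = height)
  ank <- list()
  for (ft in c("left", "right")) {
    j <- which(foot == ft)
    ank[[ft]] <- .ankle_track(tg, tt[j], s[j], lat[j],
                              spec$stance_fraction, spec$clearance_m)
  }
  # pelvis forward position: through the midpoints of successive strikes
  mid_s <- (s[-1] + s[-length(s)]) / 2
  pelvis_s <- stats::approx(tt[-1], mid_s, xout = tg, rule = 2)$y

  ankle_h0 <- 0.05
  hip_h <- 0.90
  world <- list(
    left_hip = list(s = pelvis_s, lat = rep(-spec$hip_width_m / 2, nf),
                    h = rep(hip_h, nf)),
    right_hip = list(s = pelvis_s, lat = rep(spec$hip_width_m / 2, nf),
                     h = rep(hip_h, nf)),
    left_ankle = list(s = ank$left$s, lat = ank$left$lat,
                      h = ankle_h0 + ank$left$h),
    right_ankle = list(s = ank$right$s, lat = ank$right$lat,
                       h = ankle_h0 + ank$right$h)
  )
  to_depth <- function(sv) {
    if (spec$direction == "away") spec$camera$offset_m + sv else
      spec$camera$offset_m + L - sv
  }
  jn <- names(world)
  d <- if (spec$depth_output) 3L else 2L
  coords <- array(NA_real_, c(nf, length(jn), d),
                  dimnames = list(NULL, jn, c("x", "y", "z")[seq_len(d)]))
  for (k in seq_along(jn)) {
    w <- world[[k]]
    Z <- to_depth(w$s)
    if (spec$depth_output) {
      coords[, k, 1] <- w$lat
      coords[, k, 2] <- w$h
      coords[, k, 3] <- Z
      if (spec$noise_px_sd > 0) {
        mns <- spec$noise_px_sd * Z / spec$camera$focal_px
        for (dd in 1:3) coords[, k, dd] <- coords[, k, dd] +
            stats::rnorm(nf, 0, mns)
      }
    } else {
      pr <- .project(w$lat, w$h, Z, spec$camera)
      coords[, k, 1] <- pr$u + stats::rnorm(nf, 0, spec$noise_px_sd)
      coords[, k, 2] <- pr$v + stats::rnorm(nf, 0, spec$noise_px_sd)
    }
  }
  conf <- matrix(pmin(pmax(spec$confidence_model$base +
                             stats::rnorm(nf * length(jn), 0, 0.02),
                           0.6), 1), nf, length(jn),
                 dimnames = list(NULL, jn))
  if (spec$confidence_model$dropout_prob > 0) {
    drop <- matrix(stats::runif(nf * length(jn)) <
                     spec$confidence_model$dropout_prob, nf, length(jn))
    conf[drop] <- stats::runif(sum(drop), 0, 0.45)
  }
  seq <- pose_sequence(coords, fps = spec$fps, confidence = conf,
                       missing = matrix(FALSE, nf, length(jn),
                                        dimnames = list(NULL, jn)))

  # ground truth: in-bout strikes on the bout's clock
  gt_t <- tt[in_bout] - t0
  gt_strikes <- data.frame(
    time_s = gt_t,
    frame = as.integer(round(gt_t * spec$fps)),
    foot = foot[in_bout],
    forward_m = s[in_bout],
    lateral_m = lat[in_bout],
    depth_m = to_depth(s[in_bout])
  )
  gt <- structure(list(strikes = gt_strikes, hip_width_m = spec$hip_width_m,
                       spec = spec), class = "ground_truth")
  gt$features <- true_features(gt)
  ann <- annotation_set(gt_strikes$frame, gt_strikes$foot, bout_id = bout_id)
  bout <- bout_meta(bout_id, 0L, nf, direction = spec$direction,
                    estimator = "synthetic",
                    treatment_state = treatment_state,
                    subject_id = subject_id)
  structure(list(seq = seq, gt = gt, bout = bout, annotations = ann),
            class = "simulated_walk")
}

#' True gait features from a ground-truth schedule
#'
#' Computes the reference feature set from the exact strike schedule with
#' the same formulas the video path uses, in metric units, plus the
#' hip-width-normalized step-width ratio (rank correlations are invariant
#' to this monotone rescaling of the metric width).
#'
#' @param gt A `ground_truth` object from [simulate_walk()].
#' @param unbiased_cv Use the sample (n-1) standard deviation in CVs.
#' @return One-row data frame: `n_steps, cadence, step_width_mean` (m),
#'   `step_width_ratio_mean`, `step_width_cv, step_time_cv,
#'   step_length_mean` (m), `speed` (m/s).
#' @export
true_features <- function(gt, unbiased_cv = TRUE) {
  st <- gt$strikes
  n <- nrow(st)
  if (n < 3L) stop("insufficient steps: need at least 3 strikes",
                   call. = FALSE)
  t <- st$time_s
  span <- t[n] - t[1]
  valid <- which(st$foot[-1] != st$foot[-n]) + 1L
  step_times <- t[valid] - t[valid - 1L]
  widths_m <- abs(st$lateral_m[valid] - st$lateral_m[valid - 1L])
  lengths_m <- abs(st$forward_m[valid] - st$forward_m[valid - 1L])
  data.frame(
    n_steps = n,
    cadence = 60 * (n - 1) / span,
    step_width_mean = mean(widths_m),
    step_width_ratio_mean = mean(widths_m) / gt$hip_width_m,
    step_width_cv = cv_pct(widths_m, unbiased_cv),
    step_time_cv = cv_pct(step_times, unbiased_cv),
    step_length_mean = mean(lengths_m),
    speed = abs(st$forward_m[n] - st$forward_m[1]) / span
  )
}

# Cohort presets.  Each bout's step-parameter MEANS are drawn from a
# population distribution (between-subject variability); the within-bout
# step-to-step sd is separate.  The shuffling population matches the
# short-step regime in which frontal-view clustering undercounts: per-walk
# mean step length 10.8 +/- 5.4 cm, range 4.8-19.2 cm, with the minimal
# foot clearance that defines a shuffle.
.presets <- list(
  normal = list(
    population = list(
      step_length_m = list(mean = 0.55, sd = 0.08, lower = 0.35, upper = 0.75),
      step_time_s = list(mean = 0.55, sd = 0.06, lower = 0.40, upper = 0.75),
      step_width_m = list(mean = 0.10, sd = 0.025, lower = 0.05, upper = 0.18)),
    within_sd = list(step_length_m = 0.03, step_time_s = 0.03,
                     step_width_m = 0.02),
    clearance_m = 0.15),
  shuffling = list(
    population = list(
      step_length_m = list(mean = 0.108, sd = 0.054, lower = 0.048,
                           upper = 0.192),
      step_time_s = list(mean = 0.45, sd = 0.05, lower = 0.35, upper = 0.60),
      step_width_m = list(mean = 0.12, sd = 0.02, lower = 0.06, upper = 0.18)),
    within_sd = list(step_length_m = 0.015, step_time_s = 0.03,
                     step_width_m = 0.02),
    clearance_m = 0.04)
)

.draw_bout_pars <- function(preset) {
  pop <- preset$population
  out <- list()
  for (nm in names(pop)) {
    p <- pop[[nm]]
    m <- rtruncnorm1(1, p$mean, p$sd, p$lower, p$upper)
    out[[nm]] <- list(mean = m, sd = preset$within_sd[[nm]])
  }
  out$clearance_m <- preset$clearance_m
  out
}

#' Generate a cohort of simulated bouts
#'
#' @param n_bouts Number of bouts (for `on_off_paired`, number of pairs).
#' @param preset `"normal"` (unimpaired steps), `"shuffling"` (very short
#'   steps: length 10.8 +/- 5.4 cm truncated to 4.8-19.2 cm, the regime
#'   where frontal-view clustering undercounts), `"mixed"` (alternating),
#'   or `"on_off_paired"` (paired bouts per synthetic subject with an
#'   additive treatment effect on step length and step time).
#' @param seed Integer seed for the whole cohort.
#' @param noise_px_sd,dropout_prob Observation noise settings applied to
#'   every bout.
#' @param treatment_effect For `on_off_paired`: list with `step_length_m`
#'   and `step_time_s` additive ON-state improvements (longer, quicker
#'   steps); zero effects give a null cohort.
#' @param dir Optional directory: writes the canonical keypoint CSV per
#'   bout plus `ground_truth.csv`, `bouts.csv` and `annotations.csv`.
#' @param ... Further [walk_spec()] overrides applied to every bout.
#' @return List of class `gait_cohort`: `walks` (list of
#'   `simulated_walk`), `truth` (per-bout true features + metadata), and
#'   `bouts` (metadata table).
#' @export
make_cohort <- function(n_bouts, preset = c("normal", "shuffling", "mixed",
                                            "on_off_paired"),
                        seed = 1, noise_px_sd = 0, dropout_prob = 0,
                        treatment_effect = list(step_length_m = 0.10,
                                                step_time_s = 0.05),
                        dir = NULL, ...) {
  preset <- match.arg(preset)
  set.seed(seed)
  total <- if (preset == "on_off_paired") 2L * n_bouts else n_bouts
  bout_seeds <- sample.int(.Machine$integer.max - 1L, total)
  overrides <- list(...)
  walks <- vector("list", total)
  rows <- vector("list", total)
  on_pars <- list()
  for (i in seq_len(total)) {
    kind <- switch(preset,
                   normal = "normal",
                   shuffling = "shuffling",
                   mixed = if (i %% 2L == 1L) "normal" else "shuffling",
                   on_off_paired = "normal")
    state <- "unknown"
    subject <- sprintf("s%03d", if (preset == "on_off_paired")
      ceiling(i / 2) else i)
    if (preset == "on_off_paired") {
      state <- if (i %% 2L == 1L) "ON" else "OFF"
      if (state == "ON") {
        pars <- .draw_bout_pars(.presets[[kind]])
        on_pars[[subject]] <- pars
      } else {
        pars <- on_pars[[subject]]
        pars$step_length_m$mean <- max(
          pars$step_length_m$mean - treatment_effect$step_length_m, 0.05)
        pars$step_time_s$mean <-
          pars$step_time_s$mean + treatment_effect$step_time_s
      }
    } else {
      pars <- .draw_bout_pars(.presets[[kind]])
    }
    clr <- pars$clearance_m
    pars$clearance_m <- NULL
    args <- utils::modifyList(
      c(pars, list(clearance_m = clr,
                   direction = if (i %% 2L == 1L) "toward" else "away",
                   noise_px_sd = noise_px_sd,
                   confidence_model = list(base = 0.9,
                                           dropout_prob = dropout_prob),
                   seed = bout_seeds[i])),
      overrides)
    spec <- do.call(walk_spec, args)
    bid <- sprintf("b%03d", i)
    w <- simulate_walk(spec, bout_id = bid, subject_id = subject,
                       treatment_state = state)
    walks[[i]] <- w
    rows[[i]] <- cbind(
      data.frame(bout_id = bid, subject_id = subject, preset = kind,
                 direction = spec$direction, treatment_state = state),
      w$gt$features)
  }
  truth <- do.call(rbind, rows)
  bouts <- truth[c("bout_id", "subject_id", "preset", "direction",
                   "treatment_state")]
  out <- structure(list(walks = walks, truth = truth, bouts = bouts),
                   class = "gait_cohort")
  if (!is.null(dir)) export_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk in the canonical formats
#'
#' One long-format keypoint CSV per bout (readable by [read_pose_csv()]),
#' plus `ground_truth.csv`, `bouts.csv` and `annotations.csv`.
#'
#' @param cohort A `gait_cohort` from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- list()
  for (w in cohort$walks) {
    write_pose_csv(w$seq, file.path(dir, paste0(w$bout$bout_id, "_pose.csv")))
    a <- as.data.frame(w$annotations)
    a$bout_id <- w$bout$bout_id
    ann[[length(ann) + 1L]] <- a
  }
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$bouts, file.path(dir, "bouts.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ann), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
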