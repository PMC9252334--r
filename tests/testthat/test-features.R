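strike_frame <- function(frames, foot, x, fps = 30, z = NULL) {
  df <- data.frame(frame = frames, time_s = frames / fps, foot = foot,
                   source = "manual", interpolated = FALSE, x = x,
                   y = 0)
  if (!is.null(z)) df$z <- z
  n <- nrow(df)
  df$valid_step <- c(FALSE, df$foot[-1] != df$foot[-n] &
                       df$frame[-1] > df$frame[-n])
  df$tie <- FALSE
  class(df) <- c("heel_strikes", "data.frame")
  df
}

test_that("hip width is the per-frame inter-hip distance", {
  seq <- toy_sequence(cbind(rep(0, 5), rep(0, 5)), hip_sep = 20)
  expect_equal(hip_width(seq), rep(20, 5))
  # isometry: rigid in-plane rotation leaves widths unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- seq
  for (j in seq$joint_names) {
    rot$coords[, j, ] <- seq$coords[, j, ] %*% t(R)
  }
  expect_equal(hip_width(rot), hip_width(seq), tolerance = 1e-12)
})

test_that("features match the hand-computed example", {
  # strikes every 0.5 s, lateral positions 100,112,98,114 px, hip width 20
  st <- strike_frame(c(0, 15, 30, 45), c("left", "right", "left", "right"),
                     c(100, 112, 98, 114))
  seq <- toy_sequence(cbind(rep(0, 46), rep(0, 46)), hip_sep = 20)
  f <- compute_features(st, seq)
  expect_equal(f$n_steps, 4L)
  expect_equal(f$cadence, 120)
  expect_equal(f$step_time_cv, 0)
  # widths 12/20, 14/20, 16/20 = .6 .7 .8; sample sd 0.1
  expect_equal(f$step_width_mean, 0.7)
  expect_equal(f$step_width_cv, 100 * 0.1 / 0.7, tolerance = 1e-9)
  expect_equal(f$n_valid_steps, 3L)
})

test_that("3D strikes add step length and speed", {
  st <- strike_frame(c(0, 15, 30, 45), c("left", "right", "left", "right"),
                     c(0, 0.1, 0, 0.1), z = c(0, 0.55, 1.10, 1.65))
  nf <- 46
  jn <- c("left_hip", "right_hip", "left_ankle", "right_ankle")
  coords <- array(0, c(nf, 4, 3), dimnames = list(NULL, jn, NULL))
  coords[, "left_hip", 1] <- -0.15
  coords[, "right_hip", 1] <- 0.15
  seq <- pose_sequence(coords, fps = 30,
                       missing = matrix(FALSE, nf, 4,
                                        dimnames = list(NULL, jn)))
  f <- compute_features(st, seq)
  expect_equal(f$step_length_mean, 0.55)
  expect_equal(f$speed, 1.65 / 1.5)
})

test_that("feature invariants: counts, rescaling, CV scale freedom", {
  st <- strike_frame(c(0, 16, 33, 47, 65),
                     c("left", "right", "left", "right", "left"),
                     c(100, 111, 99, 113, 101))
  seq <- toy_sequence(cbind(rep(0, 66), rep(0, 66)), hip_sep = 20)
  f <- compute_features(st, seq)
  # cadence x span / 60 + 1 = n exactly
  span <- (65 - 0) / 30
  expect_equal(f$cadence * span / 60 + 1, f$n_steps)
  # uniform image rescaling cancels out of hip-normalized widths
  k <- 3.7
  st2 <- st
  st2$x <- st2$x * k
  seq2 <- seq
  seq2$coords <- seq2$coords * k
  f2 <- compute_features(st2, seq2)
  expect_equal(f2$step_width_mean, f$step_width_mean, tolerance = 1e-12)
  expect_equal(f2$step_width_cv, f$step_width_cv, tolerance = 1e-9)
  # step-time CV is invariant to a uniform time dilation
  st3 <- st
  st3$time_s <- st3$time_s * 2.5
  f3 <- compute_features(st3, seq)
  expect_equal(f3$step_time_cv, f$step_time_cv, tolerance = 1e-9)
})

test_that("degenerate inputs are refused or flagged", {
  seq <- toy_sequence(cbind(rep(0, 40), rep(0, 40)), hip_sep = 20)
  st <- strike_frame(c(0, 15), c("left", "right"), c(100, 112))
  expect_error(compute_features(st, seq), "insufficient steps")
  # coincident hips: widths unnormalizable, flagged absent
  seq0 <- toy_sequence(cbind(rep(0, 46), rep(0, 46)), hip_sep = 0)
  st4 <- strike_frame(c(0, 15, 30, 45), c("left", "right", "left", "right"),
                      c(100, 112, 98, 114))
  f <- compute_features(st4, seq0)
  expect_true(is.na(f$step_width_mean))
  expect_true(is.na(f$step_width_cv))
})

test_that("bout filtering applies both rules and reports exclusions", {
  feats <- data.frame(bout_id = c("a", "b", "c", "d"),
                      n_steps = c(12, 19, 25, 2))
  ref <- setNames(c(12, 19, 25, 10), feats$bout_id)
  kept <- filter_bouts(feats, ref, min_steps = 3, max_steps = 20)
  expect_equal(kept$bout_id, c("a", "b"))
  excl <- attr(kept, "exclusions")
  expect_setequal(excl$bout_id, c("c", "d"))
  # cap = Inf disables the reference rule
  kept2 <- filter_bouts(feats, ref, max_steps = Inf)
  expect_equal(kept2$bout_id, c("a", "b", "c"))
  # oracle: exclusion count equals brute-force rule application
  set.seed(81)
  for (i in 1:10) {
    n <- 30
    fx <- data.frame(bout_id = as.character(seq_len(n)),
                     n_steps = sample(1:30, n, replace = TRUE))
    rx <- sample(1:40, n, replace = TRUE)
    kx <- filter_bouts(fx, rx)
    expect_equal(nrow(kx), sum(rx <= 20 & fx$n_steps >= 3))
  }
})

test_that("walking direction is inferred from the hip-width trend", {
  n <- 90
  grow <- toy_sequence(cbind(rep(0, n), rep(0, n)))
  grow$coords[, "left_hip", 1] <- 100 - seq_len(n) * 0.5
  grow$coords[, "right_hip", 1] <- 100 + seq_len(n) * 0.5
  expect_equal(infer_direction(grow), "toward")
  shrink <- grow
  shrink$coords[, "left_hip", 1] <- 100 - (n - seq_len(n)) * 0.5
  shrink$coords[, "right_hip", 1] <- 100 + (n - seq_len(n)) * 0.5
  expect_equal(infer_direction(shrink), "away")
  # flat + noisy: below the trend floor
  set.seed(91)
  flat <- grow
  flat$coords[, "left_hip", 1] <- 90 + rnorm(n, 0, 2)
  flat$coords[, "right_hip", 1] <- 110 + rnorm(n, 0, 2)
  expect_equal(infer_direction(flat), "unknown")
})

test_that("direction inference is reliable on noisy simulated bouts", {
  ok <- 0
  n <- 40
  for (i in seq_len(n)) {
    dirn <- if (i %% 2 == 0) "away" else "toward"
    w <- simulate_walk(walk_spec(seed = 3000 + i, direction = dirn,
                                 noise_px_sd = 2))
    pp <- preprocess_sequence(w$seq)
    if (infer_direction(pp) == dirn) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})
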