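test_that("st_dbscan handles degenerate densities", {
  # identical points within the radii form one cluster, no noise
  tt <- seq(0, 0.3, length.out = 10)
  pts <- matrix(rep(c(5, 5), each = 10), 10)
  lab <- st_dbscan(tt, pts, eps_spatial = 1, eps_temporal = 1, min_pts = 4)
  expect_equal(lab, rep(1L, 10))
  # isolated point is noise
  expect_equal(st_dbscan(0, matrix(c(1, 1), 1), 1, 1, 2), -1L)
  # empty input
  expect_equal(st_dbscan(numeric(0), matrix(numeric(0), 0, 2), 1, 1, 2),
               integer(0))
  # two spatially distant groups overlapping in time split apart
  tt2 <- rep(seq(0, 0.7, by = 0.1), 2)
  pts2 <- rbind(matrix(rep(c(0, 0), each = 8), 8),
                matrix(rep(c(100, 0), each = 8), 8))
  o <- order(tt2)
  lab2 <- st_dbscan(tt2[o], pts2[o, ], eps_spatial = 5, eps_temporal = 1,
                    min_pts = 4)
  expect_equal(length(unique(lab2)), 2L)
  expect_true(all(lab2 > 0))
  expect_identical(lab2, oracle_stdbscan(tt2[o], pts2[o, ], 5, 1, 4))
})

test_that("st_dbscan is deterministic and time-sorted input is required", {
  set.seed(51)
  tt <- sort(runif(60, 0, 5))
  pts <- matrix(runif(120), 60)
  l1 <- st_dbscan(tt, pts, 0.2, 0.3, 4)
  l2 <- st_dbscan(tt, pts, 0.2, 0.3, 4)
  expect_identical(l1, l2)
  expect_error(st_dbscan(rev(tt), pts, 0.2, 0.3, 4), "sorted")
})

test_that("stances are detected on plateaus and not on moving tracks", {
  track <- plateau_track(c(100, 160, 220, 280))
  seq <- toy_sequence(track)
  params <- stdbscan_params(eps_spatial = 5, eps_temporal = 0.13,
                            min_pts = 4, min_stance_s = 0.3)
  st <- detect_stances(seq, "left", params, drop_boundary = FALSE)
  expect_equal(nrow(st), 4L)
  # plateau boundaries: plateaus of 12 frames separated by 9 transitions
  expect_equal(st$frame_first, c(0, 21, 42, 63))
  expect_equal(st$frame_last - st$frame_first + 1L, rep(12L, 4))
  # first stance is dropped when the window starts mid-stance
  st2 <- detect_stances(seq, "left", params, drop_boundary = TRUE)
  expect_equal(st2$frame_first, c(21, 42, 63))
  # continuously moving ankle: no stances
  mov <- toy_sequence(cbind(seq(0, 600, length.out = 90),
                            rep(400, 90)))
  expect_equal(nrow(detect_stances(mov, "left", params,
                                   drop_boundary = FALSE)), 0L)
})

test_that("plateaus inside the radii merge into one stance", {
  # two plateaus 3 px apart (< eps): the unresolved short-step regime
  track <- plateau_track(c(100, 103), plateau_frames = 12, trans_frames = 2)
  seq <- toy_sequence(track)
  params <- stdbscan_params(eps_spatial = 5, eps_temporal = 0.13,
                            min_pts = 4, min_stance_s = 0.3)
  st <- detect_stances(seq, "left", params, drop_boundary = FALSE)
  expect_equal(nrow(st), 1L)
  ev <- heel_strikes_auto(st, seq)
  expect_equal(nrow(ev), 1L)  # one event, not two
})

test_that("auto heel strikes are the first stance timesteps", {
  track <- plateau_track(c(100, 160, 220))
  seq <- toy_sequence(track)
  st <- detect_stances(seq, "left",
                       stdbscan_params(eps_spatial = 5, eps_temporal = 0.13,
                                       min_pts = 4, min_stance_s = 0.3),
                       drop_boundary = FALSE)
  ev <- heel_strikes_auto(st, seq)
  expect_equal(ev$frame, st$frame_first)
  expect_equal(ev$time_s, st$frame_first / 30)
  expect_true(all(ev$source == "auto"))
  empty <- heel_strikes_auto(st[0, ], seq)
  expect_equal(nrow(empty), 0L)
})

test_that("manual heel strikes read positions off the trajectory", {
  track <- plateau_track(c(100, 160, 220))
  seq <- toy_sequence(track)
  ann <- annotation_set(c(5, 26), c("left", "left"))
  ev <- heel_strikes_manual(ann, seq)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$x, unname(seq$coords[c(6, 27), "left_ankle", 1]))
  expect_true(all(ev$source == "manual"))
  # an annotation inside an untrackable gap is dropped with a warning
  seq$missing[27, "left_ankle"] <- TRUE
  expect_warning(ev2 <- heel_strikes_manual(ann, seq), "no spatial data")
  expect_equal(nrow(ev2), 1L)
})

test_that("merge_feet orders events and validates steps", {
  mk <- function(frames, foot) {
    data.frame(frame = as.integer(frames), time_s = frames / 30,
               foot = rep(foot, length(frames)),
               source = rep("auto", length(frames)),
               interpolated = rep(FALSE, length(frames)),
               x = frames + 0.5, y = rep(0, length(frames)))
  }
  m <- merge_feet(mk(c(10, 40), "left"), mk(25, "right"))
  expect_equal(m$frame, c(10, 25, 40))
  expect_equal(sum(m$valid_step), 2L)
  # consecutive same-foot events invalidate the step between them
  m2 <- merge_feet(mk(c(10, 40), "left"), mk(integer(0), "right"))
  expect_equal(sum(m2$valid_step), 0L)
  # same-frame tie: left first, flagged
  m3 <- merge_feet(mk(10, "left"), mk(10, "right"))
  expect_equal(m3$foot, c("left", "right"))
  expect_true(all(m3$tie))
  expect_equal(sum(m3$valid_step), 0L)
  # property: random interleavings come back sorted and complete
  set.seed(61)
  for (i in 1:20) {
    lf <- sort(sample(200, sample(3:8, 1)))
    rf <- sort(sample(200, sample(3:8, 1)))
    mm <- merge_feet(mk(lf, "left"), mk(rf, "right"))
    expect_equal(nrow(mm), length(lf) + length(rf))
    expect_true(!is.unsorted(mm$frame))
    expect_setequal(mm$frame, c(lf, rf))
  }
})

test_that("strike count never exceeds stance count", {
  set.seed(71)
  for (i in 1:5) {
    lv <- cumsum(c(100, runif(4, 40, 80)))
    seq <- toy_sequence(plateau_track(lv))
    st <- detect_stances(seq, "left",
                         stdbscan_params(eps_spatial = 5,
                                         eps_temporal = 0.13, min_pts = 4,
                                         min_stance_s = 0.3),
                         drop_boundary = FALSE)
    ev <- heel_strikes_auto(st, seq)
    expect_lte(nrow(ev), nrow(st))
    expect_equal(ev$frame, st$frame_first)
  }
})
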