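test_that("a constant-position trajectory has no bouts", {
  tr <- Trajectory(times = seq(0, 10, 0.2), x = rep(5, 51), y = rep(1, 51))
  b <- segmentBouts(tr)
  expect_equal(nrow(b), 0)
  # all-invalid trajectory: empty table, not an error
  tr2 <- Trajectory(times = 0:9, x = rep(NA_real_, 10),
                    y = rep(NA_real_, 10), valid = rep(FALSE, 10))
  expect_equal(nrow(segmentBouts(tr2)), 0)
})

test_that("a planted 10-bout trajectory is recovered exactly", {
  fx <- plantedBoutTrajectory(nBouts = 10, boutFrames = 3, speed = 20,
                              gap = 4)
  b <- segmentBouts(fx$traj)
  expect_equal(nrow(b), 10)
  expect_equal(b$distance, fx$dists, tolerance = 0.02)
  # dwell times equal planted gaps within one frame interval
  expect_true(all(abs(dwellTimes(b) - fx$gap) <= 0.2 + 1e-9))
})

test_that("bouts separated by less than minDwell merge into one", {
  dt <- 0.2
  tts <- seq(0, 8, dt)
  xs <- rep(0, length(tts))
  # bout 1: three moving frames; 0.6 s gap; bout 2: three moving frames
  xs[7:9] <- c(4, 8, 12)
  xs[10:12] <- 12
  xs[13:15] <- c(16, 20, 24)
  xs[16:length(xs)] <- 24
  tr <- Trajectory(times = tts, x = xs, y = rep(1, length(tts)))
  merged <- segmentBouts(tr, minDwell = 1.0)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$distance, 24, tolerance = 1e-9)
  split <- segmentBouts(tr, minDwell = 0.1)
  expect_equal(nrow(split), 2)
  expect_equal(sum(split$distance), 24, tolerance = 1e-9)
})

test_that("segmentation tolerates short gaps and splits on long ones", {
  fx <- plantedBoutTrajectory(nBouts = 6)
  tr <- fx$traj
  v <- isValid(tr)
  # knock out one frame inside the third bout: bridged
  i3 <- which(frameTimes(tr) > fx$starts[3] & frameTimes(tr) < fx$ends[3])[1]
  v[i3] <- FALSE
  tr2 <- Trajectory(times = frameTimes(tr), x = tr@x, y = tr@y, valid = v)
  expect_equal(nrow(segmentBouts(tr2)), 6)
  # knock out 5 consecutive frames inside a bout: split or dropped
  v2 <- isValid(tr)
  i4 <- which(frameTimes(tr) >= fx$starts[4] - 0.4 &
                frameTimes(tr) <= fx$ends[4] + 0.4)
  v2[i4] <- FALSE
  tr3 <- Trajectory(times = frameTimes(tr), x = tr@x, y = tr@y, valid = v2)
  expect_lt(nrow(segmentBouts(tr3)), 7)
})

test_that("total bout distance never exceeds trajectory path length", {
  for (s in 1:4) {
    p <- boutProcessParams(dwellMedian = 2, seed = s)
    tr <- simulateTrajectory(p, duration = 600, laneLength = 65)
    b <- segmentBouts(tr)
    expect_lte(sum(b$distance), pathLength(tr) + 1e-9)
  }
})

test_that("segmentation is idempotent on the reconstructed piecewise path", {
  p <- boutProcessParams(dwellMedian = 4, dwellShape = 0.4, seed = 9)
  tr <- simulateTrajectory(p, duration = 900, laneLength = 65)
  b1 <- segmentBouts(tr)
  # rebuild a trajectory that moves only during the detected bouts
  tt <- frameTimes(tr)
  x2 <- tr@x
  for (i in seq_len(nrow(b1))) {
    if (i < nrow(b1)) {
      hold <- tt > b1$end[i] & tt < b1$start[i + 1]
      x2[hold] <- x2[which(tt <= b1$end[i])[sum(tt <= b1$end[i])]]
    }
  }
  tr2 <- Trajectory(times = tt, x = x2, y = tr@y)
  b2 <- segmentBouts(tr2)
  expect_equal(nrow(b2), nrow(b1))
  # boundary intervals may shift by at most one frame after flattening
  expect_true(all(abs(b2$start - b1$start) <= 0.2 + 1e-9))
  expect_equal(b2$distance, b1$distance, tolerance = 0.05)
})

test_that("distribution summaries report order statistics and a true density", {
  s <- distributionSummary(c(1, 2, 3, 4, 5), bins = 5)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, c(2, 4))
  set.seed(41)
  s2 <- distributionSummary(rlnorm(500), bins = 40)
  expect_equal(sum(s2$density$density * s2$density$binwidth), 1,
               tolerance = 1e-9)
  expect_error(distributionSummary(numeric(0)), "empty")
})

test_that("planted dwell distributions with a 2x median ratio separate by MW", {
  set.seed(43)
  d1 <- rlnorm(1000, log(5), 1)
  d2 <- rlnorm(1000, log(10), 1)
  expect_lt(mannWhitney(d1, d2, mode = "normal")$p, 0.01)
})

test_that("swim velocity recovers a planted constant-speed bout", {
  fx <- plantedBoutTrajectory(nBouts = 8, boutFrames = 4, speed = 20)
  v <- swimVelocity(fx$traj)
  expect_false(v$undefined)
  expect_equal(v$median, 20, tolerance = 0.02)
  # stationary larva: flagged undefined
  still <- Trajectory(times = 0:20, x = rep(3, 21), y = rep(1, 21))
  expect_true(swimVelocity(still)$undefined)
  # invariant to reversing the time axis
  tr <- fx$traj
  rev <- Trajectory(times = max(tr@times) - base::rev(tr@times),
                    x = base::rev(tr@x), y = base::rev(tr@y))
  expect_equal(swimVelocity(rev)$median, v$median, tolerance = 1e-9)
})

test_that("laps are recovered from a triangle wave with correct amplitude/period", {
  tr <- triangleTrajectory(A = 40, speed = 20, pause = 1, nCycles = 4)
  laps <- detectLaps(tr, amplitudeMin = 10, maxIntraLapDwell = 5)
  expect_equal(nrow(laps), 8)
  expect_equal(laps$amplitude, rep(40, 8), tolerance = 0.05 * 40)
  # period = time between successive same-direction reversals (A/v + pause)*2
  expect_equal(laps$period[!is.na(laps$period)],
               rep(6, sum(!is.na(laps$period))), tolerance = 0.05 * 6)
})

test_that("monotone traversal gives one lap; stationary gives none", {
  dt <- 0.2
  tts <- seq(0, 8, dt)
  xs <- pmin(5 + 10 * tts, 45)     # ramp to the far end, then stop
  tr <- Trajectory(times = tts, x = xs, y = rep(1, length(tts)))
  laps <- detectLaps(tr, amplitudeMin = 10, maxIntraLapDwell = 10)
  expect_equal(nrow(laps), 1)
  expect_equal(laps$amplitude, 40, tolerance = 0.5)
  still <- Trajectory(times = 0:30, x = rep(5, 31), y = rep(1, 31))
  expect_equal(nrow(detectLaps(still, amplitudeMin = 10,
                               maxIntraLapDwell = 5)), 0)
})

test_that("lap clustering recovers planted cluster structure exactly", {
  # laps with gaps all above maxGap: all singletons
  mk <- function(starts, dur = 2)
    structure(data.frame(start = starts, end = starts + dur,
                         amplitude = 30, direction = 1, nBouts = 2,
                         period = NA_real_, clusterId = NA_integer_),
              class = c("lapTable", "data.frame"))
  iso <- clusterLaps(mk(c(0, 100, 200)), maxGap = 5)
  expect_equal(iso$clusterId, 1:3)
  # 3 laps with 1 s gaps: one cluster of 3
  tight <- clusterLaps(mk(c(0, 3, 6)), maxGap = 5)
  expect_equal(tight$clusterId, rep(1L, 3))
  expect_equal(attr(tight, "clusters")$duration, 8)
  # planted structure: clusters of sizes 4, 1, 3, 2, 1
  starts <- c(0, 3, 6, 9,   100,   200, 203, 206,   300, 303,   400)
  cl <- clusterLaps(mk(starts), maxGap = 5)
  expect_equal(cl$clusterId,
               rep(1:5, times = c(4, 1, 3, 2, 1)))
  expect_equal(attr(cl, "clusters")$nLaps, c(4, 1, 3, 2, 1))
})
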