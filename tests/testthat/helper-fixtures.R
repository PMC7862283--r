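# Fixtures built in code: constructed trajectories with exactly known
# bouts/laps, and brute-force statistical oracles independent of the
# package implementations.

# piecewise trajectory with planted bouts: constant-speed runs separated by
# exact stationary gaps; every quantity is frame-aligned so recovery is
# deterministic
plantedBoutTrajectory <- function(nBouts = 10, boutFrames = 3, speed = 20,
                                  gap = 4, fps = 5, x0 = 5) {
  dt <- 1 / fps
  xs <- x0; tts <- 0
  dir <- 1
  starts <- ends <- dists <- numeric(nBouts)
  for (b in seq_len(nBouts)) {
    ngap <- round(gap * fps)
    tcur <- tts[length(tts)]; xcur <- xs[length(xs)]
    tts <- c(tts, tcur + dt * seq_len(ngap))
    xs <- c(xs, rep(xcur, ngap))
    starts[b] <- tts[length(tts)]
    tcur <- tts[length(tts)]
    tts <- c(tts, tcur + dt * seq_len(boutFrames))
    xs <- c(xs, xcur + dir * speed * dt * seq_len(boutFrames))
    ends[b] <- tts[length(tts)]
    dists[b] <- speed * dt * boutFrames
    if (b %% 3 == 0) dir <- -dir
  }
  ngap <- round(gap * fps)
  tcur <- tts[length(tts)]; xcur <- xs[length(xs)]
  tts <- c(tts, tcur + dt * seq_len(ngap))
  xs <- c(xs, rep(xcur, ngap))
  list(traj = Trajectory(times = tts, x = xs, y = rep(1.5, length(tts))),
       starts = starts, ends = ends, dists = dists, gap = gap)
}

# triangle-wave trajectory: alternating constant-speed excursions of
# amplitude A with a pause at each reversal
triangleTrajectory <- function(A = 40, speed = 20, pause = 1, nCycles = 4,
                               fps = 5, x0 = 10) {
  dt <- 1 / fps
  tts <- 0; xs <- x0; dir <- 1
  for (i in seq_len(2 * nCycles)) {
    n <- round(A / speed * fps)
    tcur <- tts[length(tts)]; xcur <- xs[length(xs)]
    tts <- c(tts, tcur + dt * seq_len(n))
    xs <- c(xs, xcur + dir * speed * dt * seq_len(n))
    np <- round(pause * fps)
    tcur <- tts[length(tts)]; xcur <- xs[length(xs)]
    tts <- c(tts, tcur + dt * seq_len(np))
    xs <- c(xs, rep(xcur, np))
    dir <- -dir
  }
  Trajectory(times = tts, x = xs, y = rep(1.5, length(tts)))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments,
# written directly from the permutation definition (independent of the
# package's enumeration path: operates on raw values, recomputing ranks
# per assignment)
bruteMWExact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); N <- length(pooled)
  picks <- utils::combn(N, na)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- uOf(seq_len(na))
  Us <- apply(picks, 2, uOf)
  min(1, 2 * min(mean(Us <= obs), mean(Us >= obs)))
}

# textbook two-group log-rank from the O-E / V definition, computed with
# scalar accumulation over event times
bruteLogRank2 <- function(t1, c1, t2, c2) {
  ut <- sort(unique(c(t1[!c1], t2[!c2])))
  O1 <- sum(!c1); E1 <- 0; V <- 0
  for (tt in ut) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d <- sum(t1 == tt & !c1) + sum(t2 == tt & !c2)
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0))
  list(chisq = (O1 - E1)^2 / V)
}

# random small samples with structural ties for property tests
randomTiedSample <- function(n) sample(1:5, n, replace = TRUE)
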