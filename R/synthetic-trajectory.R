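#' Parameters of the swim-bout renewal process
#'
#' A larva's long-timescale locomotion is modelled as a renewal process:
#' immobile dwell intervals (log-normal; the lethargy readout) alternate with
#' brief swim bouts (displacement drawn from a gamma distribution, traversed
#' at constant velocity over `boutDuration`). Direction persists along the
#' lane; a bout reaching a lane end stops at the wall and the heading flips
#' for the next bout. Lap-swimming episodes arrive as a Poisson process and
#' consist of several consecutive bouts separated by short dwells.
#'
#' @param dwellMedian median dwell (immobility) interval, seconds.
#' @param dwellShape log-normal sigma (dimensionless) of dwell times.
#' @param boutDistanceMean mean per-bout displacement, mm.
#' @param boutDistanceShape gamma shape of bout distances (dimensionless).
#' @param boutDuration bout duration, seconds.
#' @param lapRate lap-episode rate, episodes per hour (0 disables laps).
#' @param lapBoutCountMean mean number of bouts per lap episode.
#' @param lapDwellMedian median dwell between bouts inside a lap episode, s.
#' @param seed default RNG seed carried with the parameter set.
#' @return validated parameter list of class `BoutProcessParams`.
#' @export
boutProcessParams <- function(dwellMedian = 5, dwellShape = 1,
                              boutDistanceMean = 5, boutDistanceShape = 25,
                              boutDuration = 0.25, lapRate = 6,
                              lapBoutCountMean = 8, lapDwellMedian = 0.5,
                              seed = 1L) {
  for (nm in c("dwellMedian", "dwellShape", "boutDistanceMean",
               "boutDistanceShape", "boutDuration", "lapBoutCountMean",
               "lapDwellMedian"))
    checkPositive(get(nm), nm)
  if (!is.numeric(lapRate) || lapRate < 0)
    stop("'lapRate' must be non-negative")
  structure(list(dwellMedian = dwellMedian, dwellShape = dwellShape,
                 boutDistanceMean = boutDistanceMean,
                 boutDistanceShape = boutDistanceShape,
                 boutDuration = boutDuration, lapRate = lapRate,
                 lapBoutCountMean = lapBoutCountMean,
                 lapDwellMedian = lapDwellMedian, seed = as.integer(seed)),
            class = "BoutProcessParams")
}

#' Genotype presets for the bout process
#'
#' Two parameter sets emulating the two-genotype design: bout distances are
#' shared (bout size does not differ between genotypes) while the mutant
#' preset
#' doubles the dwell median (bouts initiated less frequently) and halves the
#' lap-episode rate (clustered laps less frequent).
#'
#' @return named list with `sibling` and `glyt1` parameter sets.
#' @export
genotypePresets <- function() {
  list(sibling = boutProcessParams(dwellMedian = 5, lapRate = 6),
       glyt1 = boutProcessParams(dwellMedian = 10, lapRate = 3))
}

#' Simulate a lane trajectory from the bout renewal process
#'
#' Generates the event sequence (dwell, bout, dwell, ...) until `duration`
#' is reached, then samples center-of-mass positions at `fps`. The returned
#' trajectory carries a full ground-truth log: the bout table (start, end,
#' distance actually travelled, direction, lap-episode id), the dwell
#' samples, and the event-resolved position polyline, whose path length
#' equals the summed ground-truth bout distances exactly.
#'
#' @param params a [boutProcessParams()] set.
#' @param duration recording length, seconds.
#' @param laneLength lane length, mm.
#' @param fps sampling rate of the emitted trajectory, frames per second.
#' @param laneWidth lane width, mm (y is held at mid-width).
#' @param seed RNG seed; defaults to `params$seed`.
#' @param laneId lane identifier.
#' @return a [Trajectory-class] in mm with `groundTruth` filled.
#' @export
simulateTrajectory <- function(params, duration, laneLength, fps = 5,
                               laneWidth = 3, seed = params$seed,
                               laneId = "lane1") {
  if (!inherits(params, "BoutProcessParams"))
    stop("'params' must come from boutProcessParams()")
  checkPositive(duration, "duration")
  checkPositive(laneLength, "laneLength")
  checkPositive(fps, "fps")
  withSeed(seed, {
    t <- 0
    x <- laneLength / 2
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    nextLap <- if (params$lapRate > 0)
      stats::rexp(1, params$lapRate / 3600) else Inf
    lapLeft <- 0L          # bouts remaining in the current lap episode
    lapId <- 0L
    evT <- 0; evX <- x     # event polyline
    bStart <- bEnd <- bDist <- bDir <- numeric(0)
    bLap <- integer(0)
    dwells <- numeric(0)
    while (t < duration) {
      inLap <- lapLeft > 0L
      dwell <- if (inLap)
        stats::rlnorm(1, log(params$lapDwellMedian), 0.25)
      else
        stats::rlnorm(1, log(params$dwellMedian), params$dwellShape)
      if (!inLap && t + dwell > nextLap && nextLap <= duration) {
        ## lap episode interrupts the long dwell
        dwell <- max(nextLap - t, params$lapDwellMedian)
        lapLeft <- 1L + stats::rpois(1, max(params$lapBoutCountMean - 1, 0))
        lapId <- lapId + 1L
        nextLap <- nextLap + stats::rexp(1, params$lapRate / 3600)
      }
      t <- t + dwell
      if (t + params$boutDuration > duration) {
        dwells <- c(dwells, dwell)
        break
      }
      dwells <- c(dwells, dwell)
      dist <- stats::rgamma(1, shape = params$boutDistanceShape,
                            scale = params$boutDistanceMean /
                              params$boutDistanceShape)
      x1 <- x + dir * dist
      hitWall <- x1 < 0 || x1 > laneLength
      if (hitWall) x1 <- max(0, min(laneLength, x1))
      bStart <- c(bStart, t)
      bEnd <- c(bEnd, t + params$boutDuration)
      bDist <- c(bDist, abs(x1 - x))
      bDir <- c(bDir, dir)
      bLap <- c(bLap, if (inLap || lapLeft > 0L) lapId else NA_integer_)
      evT <- c(evT, t, t + params$boutDuration)
      evX <- c(evX, x, x1)
      x <- x1
      if (hitWall) dir <- -dir
      t <- t + params$boutDuration
      if (lapLeft > 0L) lapLeft <- lapLeft - 1L
    }
    boutTab <- data.frame(start = bStart, end = bEnd, distance = bDist,
                          direction = bDir, lapEpisode = bLap)
    if (duration > evT[length(evT)]) {
      evT <- c(evT, duration)
      evX <- c(evX, x)
    }
    times <- seq(0, duration, by = 1 / fps)
    pos <- stats::approx(evT, evX, xout = times, rule = 2, ties = "ordered")$y
    Trajectory(times = times, x = pos, y = rep(laneWidth / 2, length(times)),
               laneId = laneId, units = "mm",
               groundTruth = list(bouts = boutTab, dwells = dwells,
                                  events = data.frame(t = evT, x = evX),
                                  params = params, seed = seed,
                                  laneLength = laneLength, fps = fps))
  })
}
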