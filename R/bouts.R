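## Positions in mm for analysis; px trajectories need a pxPerMm calibration.
trajMm <- function(traj, pxPerMm = NULL) {
  if (traj@units == "mm") return(cbind(traj@x, traj@y))
  s <- if (!is.null(pxPerMm)) pxPerMm else traj@pxPerMm
  if (!is.finite(s) || s <= 0)
    stop("px trajectory needs a positive pxPerMm calibration")
  cbind(traj@x, traj@y) / s
}

## bridge invalid runs of <= maxGap frames by linear interpolation; longer
## runs stay NA and split bouts
bridgeGaps <- function(pos, valid, times, maxGap = 2L) {
  if (all(valid)) return(list(pos = pos, valid = valid))
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- pos
  out[!valid, ] <- NA_real_
  fill <- rep(FALSE, length(valid))
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > maxGap) next
    if (starts[i] == 1L || ends[i] == length(valid)) next
    fill[starts[i]:ends[i]] <- TRUE
  }
  if (any(fill)) {
    for (k in 1:2) {
      good <- valid & is.finite(pos[, k])
      out[fill, k] <- stats::approx(times[good], pos[good, k],
                                    xout = times[fill])$y
    }
  }
  list(pos = out, valid = valid | fill)
}

#' Segment a trajectory into swim bouts and dwell intervals
#'
#' Computes per-interval speed, smooths it with a centered moving average to
#' suppress single-frame jitter, and applies hysteresis thresholding: a bout
#' is a maximal run of intervals with speed above `speedOff` that contains
#' at least one interval above `speedOn`. Bouts separated by a gap shorter
#' than `minDwell` are merged; bouts shorter than `minBout` are discarded.
#' Invalid frames inside a candidate bout are bridged by linear
#' interpolation when the gap is at most `maxGapBridge` frames; longer gaps
#' split the bout. An all-invalid trajectory yields an empty table.
#'
#' @param traj a [Trajectory-class].
#' @param speedOn,speedOff hysteresis thresholds, mm/s (`speedOff <=
#'   speedOn`).
#' @param minBout minimum bout duration, s.
#' @param minDwell gaps shorter than this merge adjacent bouts, s.
#' @param smoothWindow centered moving-average width (odd; 1 = off).
#' @param maxGapBridge invalid-frame run length bridged by interpolation.
#' @param pxPerMm calibration override for px trajectories.
#' @return data.frame (class `boutTable`): `start`, `end`, `distance` (path
#'   length over the bout, mm), `peakSpeed` (mm/s), `precedingDwell` (s;
#'   NA for the first bout), `netDx` (signed displacement along x, mm).
#' @export
segmentBouts <- function(traj, speedOn = 2, speedOff = 1, minBout = 0.1,
                         minDwell = 0.2, smoothWindow = 3L,
                         maxGapBridge = 2L, pxPerMm = NULL) {
  if (speedOff > speedOn) stop("'speedOff' must be <= 'speedOn'")
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      distance = numeric(0), peakSpeed = numeric(0),
                      precedingDwell = numeric(0), netDx = numeric(0))
  class(empty) <- c("boutTable", "data.frame")
  if (sum(traj@valid) < 2) return(empty)
  tt <- traj@times
  br <- bridgeGaps(trajMm(traj, pxPerMm), traj@valid, tt,
                   maxGap = maxGapBridge)
  pos <- br$pos
  step <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  dt <- diff(tt)
  v <- step / dt                       # NA across unbridged gaps
  vs <- v
  if (smoothWindow > 1L) {
    k <- rep(1 / smoothWindow, smoothWindow)
    sm <- stats::filter(ifelse(is.na(v), 0, v), k, sides = 2)
    vs <- as.numeric(sm)
    vs[is.na(v)] <- NA                 # gaps still split bouts
    edge <- is.na(vs) & !is.na(v)      # filter() NAs at the ends
    vs[edge] <- v[edge]
  }
  active <- !is.na(vs) & vs > speedOff
  if (!any(active)) return(empty)
  r <- rle(active)
  iEnd <- cumsum(r$lengths)
  iStart <- iEnd - r$lengths + 1L
  segs <- which(r$values)
  keep <- vapply(segs, function(s)
    any(vs[iStart[s]:iEnd[s]] >= speedOn, na.rm = TRUE), logical(1))
  segs <- segs[keep]
  if (!length(segs)) return(empty)
  ## smoothing spreads speed into the flanking intervals, widening every
  ## run by ~1 frame per side; trim run bounds back to the raw
  ## above-threshold intervals so dwell times are not biased short
  oS <- iStart[segs]; oE <- iEnd[segs]   # full runs, for path length
  sI <- oS; eI <- oE                     # trimmed runs, for timing
  for (s in seq_along(segs)) {
    rawHit <- which(!is.na(v[sI[s]:eI[s]]) & v[sI[s]:eI[s]] > speedOff)
    if (length(rawHit)) {
      eI[s] <- sI[s] + rawHit[length(rawHit)] - 1L
      sI[s] <- sI[s] + rawHit[1] - 1L
    }
  }
  ## interval i spans [t_i, t_{i+1}]
  bStart <- tt[sI]
  bEnd <- tt[eI + 1L]
  ## merge bouts separated by less than minDwell
  if (length(segs) > 1L) {
    merged <- list(c(1L, 1L))
    for (i in 2L:length(segs)) {
      lastI <- merged[[length(merged)]]
      if (bStart[i] - bEnd[lastI[2]] < minDwell)
        merged[[length(merged)]][2] <- i
      else merged[[length(merged) + 1L]] <- c(i, i)
    }
  } else merged <- list(c(1L, 1L))
  m1 <- vapply(merged, function(mi) sI[mi[1]], integer(1))
  m2 <- vapply(merged, function(mi) eI[mi[2]], integer(1))
  f1 <- vapply(merged, function(mi) oS[mi[1]], integer(1))
  f2 <- vapply(merged, function(mi) oE[mi[2]], integer(1))
  cs <- cumsum(ifelse(is.na(step), 0, step))
  tab <- data.frame(
    start = tt[m1], end = tt[m2 + 1L],
    distance = cs[f2] - cs[f1] + ifelse(is.na(step[f1]), 0, step[f1]),
    peakSpeed = vapply(seq_along(f1), function(i)
      max(v[f1[i]:f2[i]], na.rm = TRUE), numeric(1)),
    netDx = pos[f2 + 1L, 1] - pos[f1, 1])
  tab <- tab[tab$end - tab$start >= minBout, , drop = FALSE]
  if (!nrow(tab)) return(empty)
  ## bout bounds are the outer envelope of the occupied frame intervals;
  ## motion covers on average half of each boundary interval, so the
  ## gap between envelopes underestimates the dwell by ~one frame
  dtf <- stats::median(dt)
  tab$precedingDwell <- c(NA_real_,
                          pmax(0, tab$start[-1] - tab$end[-nrow(tab)] + dtf))
  tab <- tab[, c("start", "end", "distance", "peakSpeed",
                 "precedingDwell", "netDx")]
  rownames(tab) <- NULL
  class(tab) <- c("boutTable", "data.frame")
  tab
}

#' Dwell-time samples from a bout table
#'
#' The immobile intervals between consecutive bouts (the lethargy readout);
#' the interval before the first bout is left-censored by the recording
#' start and excluded.
#'
#' @param bouts a [segmentBouts()] table.
#' @return numeric vector of dwell times, seconds.
#' @export
dwellTimes <- function(bouts) {
  d <- bouts$precedingDwell
  d[!is.na(d)]
}

#' Probability density, median and IQR of a sample
#'
#' Histogram-based probability density (`sum(density * binwidth) == 1`) with
#' sample order statistics: median and interquartile interval from
#' `quantile(type = 7)`, R's default interpolation.
#'
#' @param values non-empty numeric sample (distances, dwell times, ...).
#' @param bins number of bins or explicit break points.
#' @return list: `density` (data.frame `mid`, `binwidth`, `density`),
#'   `median`, `iqr` (length-2), `n`.
#' @export
distributionSummary <- function(values, bins = 30) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty sample")
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  list(density = data.frame(mid = h$mids, binwidth = diff(h$breaks),
                            density = h$density),
       median = unname(stats::quantile(values, 0.5, type = 7)),
       iqr = unname(stats::quantile(values, c(0.25, 0.75), type = 7)),
       n = length(values))
}

#' Median swim velocity during bouts
#'
#' Median of per-frame speeds restricted to bout intervals. A trajectory
#' with no bouts has no defined swim velocity and is flagged.
#'
#' @param traj a [Trajectory-class].
#' @param bouts optional precomputed bout table; segmented with defaults
#'   otherwise.
#' @param pxPerMm calibration override for px trajectories.
#' @param ... passed to [segmentBouts()] when `bouts` is missing.
#' @return list: `median`, `iqr`, `n` (frame speeds used), `undefined`.
#' @export
swimVelocity <- function(traj, bouts = NULL, pxPerMm = NULL, ...) {
  if (is.null(bouts)) bouts <- segmentBouts(traj, pxPerMm = pxPerMm, ...)
  if (!nrow(bouts))
    return(list(median = NA_real_, iqr = c(NA_real_, NA_real_), n = 0L,
                undefined = TRUE))
  tt <- traj@times
  pos <- trajMm(traj, pxPerMm)
  v <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2) / diff(tt)
  mid <- (tt[-length(tt)] + tt[-1]) / 2
  inBout <- rep(FALSE, length(v))
  for (i in seq_len(nrow(bouts)))
    inBout <- inBout | (mid > bouts$start[i] & mid < bouts$end[i])
  vv <- v[inBout & !is.na(v)]
  if (!length(vv))
    return(list(median = NA_real_, iqr = c(NA_real_, NA_real_), n = 0L,
                undefined = TRUE))
  list(median = stats::median(vv),
       iqr = unname(stats::quantile(vv, c(0.25, 0.75), type = 7)),
       n = length(vv), undefined = FALSE)
}
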