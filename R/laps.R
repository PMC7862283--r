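#' Detect lap-swimming excursions
#'
#' Projects the trajectory onto the lane axis (principal axis of the valid
#' positions), then scans the bout-level signed displacement sequence for
#' direction reversals. An excursion is a maximal run of same-direction
#' bouts whose intervening dwells are at most `maxIntraLapDwell`; a lap is
#' an excursion with amplitude (net displacement between its bounding
#' reversals) at least `amplitudeMin`. The period of a lap is the time to
#' the start of the next lap in the same direction.
#'
#' @param traj a [Trajectory-class] spanning a lane.
#' @param amplitudeMin minimum lap amplitude, mm.
#' @param maxIntraLapDwell dwell gap that breaks an excursion, s.
#' @param bouts optional precomputed [segmentBouts()] table.
#' @param pxPerMm calibration override for px trajectories.
#' @param ... passed to [segmentBouts()] when `bouts` is missing.
#' @return data.frame (class `lapTable`): `start`, `end`, `amplitude`,
#'   `direction` (+1/-1), `nBouts`, `period` (NA when no later
#'   same-direction lap exists), `clusterId` (NA until [clusterLaps()]).
#' @export
detectLaps <- function(traj, amplitudeMin = 10, maxIntraLapDwell = 5,
                       bouts = NULL, pxPerMm = NULL, ...) {
  if (is.null(bouts)) bouts <- segmentBouts(traj, pxPerMm = pxPerMm, ...)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      amplitude = numeric(0), direction = numeric(0),
                      nBouts = integer(0), period = numeric(0),
                      clusterId = integer(0))
  class(empty) <- c("lapTable", "data.frame")
  if (!nrow(bouts)) return(empty)
  ## project bout displacements onto the principal lane axis
  pos <- trajMm(traj, pxPerMm)
  ok <- traj@valid & is.finite(pos[, 1]) & is.finite(pos[, 2])
  ctr <- sweep(pos[ok, , drop = FALSE], 2,
               colMeans(pos[ok, , drop = FALSE]))
  axis <- if (sum(ok) > 2 && stats::var(ctr[, 2]) > 0) {
    e <- eigen(crossprod(ctr) / (sum(ok) - 1))$vectors[, 1]
    e / sqrt(sum(e^2))
  } else c(1, 0)
  ## netDx from segmentBouts is along x; recompute along the lane axis
  proj <- pos %*% axis
  tt <- traj@times
  disp <- vapply(seq_len(nrow(bouts)), function(i) {
    i1 <- which.min(abs(tt - bouts$start[i]))
    i2 <- which.min(abs(tt - bouts$end[i]))
    proj[i2] - proj[i1]
  }, numeric(1))
  sgn <- sign(disp)
  ## build excursions: reversal or long dwell starts a new one
  exc <- integer(nrow(bouts))
  cur <- 1L
  curSign <- if (sgn[1] != 0) sgn[1] else 1
  exc[1] <- cur
  for (i in seq_len(nrow(bouts))[-1]) {
    gap <- bouts$start[i] - bouts$end[i - 1]
    flip <- sgn[i] != 0 && sgn[i] != curSign
    if (flip || gap > maxIntraLapDwell) {
      cur <- cur + 1L
      if (sgn[i] != 0) curSign <- sgn[i]
    } else if (sgn[i] != 0) curSign <- sgn[i]
    exc[i] <- cur
  }
  rows <- lapply(unique(exc), function(e) {
    idx <- which(exc == e)
    amp <- abs(sum(disp[idx]))
    data.frame(start = bouts$start[min(idx)], end = bouts$end[max(idx)],
               amplitude = amp,
               direction = sign(sum(disp[idx])),
               nBouts = length(idx))
  })
  laps <- do.call(rbind, rows)
  laps <- laps[laps$amplitude >= amplitudeMin, , drop = FALSE]
  if (!nrow(laps)) return(empty)
  laps$period <- vapply(seq_len(nrow(laps)), function(i) {
    j <- which(laps$direction == laps$direction[i] &
                 laps$start > laps$start[i])
    if (!length(j)) NA_real_ else min(laps$start[j]) - laps$start[i]
  }, numeric(1))
  laps$clusterId <- NA_integer_
  rownames(laps) <- NULL
  class(laps) <- c("lapTable", "data.frame")
  laps
}

#' Cluster laps by temporal proximity
#'
#' Single-linkage in time: consecutive laps whose inter-lap gap is at most
#' `maxGap` share a cluster; isolated laps form singleton clusters. Cluster
#' duration is last lap end minus first lap start.
#'
#' @param laps a time-ordered [detectLaps()] table.
#' @param maxGap maximum inter-lap gap within a cluster, s.
#' @return the lap table with `clusterId` filled; the per-cluster summary
#'   (`clusterId`, `nLaps`, `start`, `end`, `duration`) is attached as
#'   attribute `"clusters"`.
#' @export
clusterLaps <- function(laps, maxGap = 30) {
  if (!nrow(laps)) {
    attr(laps, "clusters") <- data.frame(clusterId = integer(0),
                                         nLaps = integer(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         duration = numeric(0))
    return(laps)
  }
  if (is.unsorted(laps$start)) stop("laps must be time-ordered")
  id <- 1L
  ids <- integer(nrow(laps))
  ids[1] <- id
  for (i in seq_len(nrow(laps))[-1]) {
    if (laps$start[i] - laps$end[i - 1] > maxGap) id <- id + 1L
    ids[i] <- id
  }
  laps$clusterId <- ids
  cl <- do.call(rbind, lapply(unique(ids), function(k) {
    idx <- which(ids == k)
    data.frame(clusterId = k, nLaps = length(idx),
               start = min(laps$start[idx]), end = max(laps$end[idx]),
               duration = max(laps$end[idx]) - min(laps$start[idx]))
  }))
  attr(laps, "clusters") <- cl
  laps
}
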