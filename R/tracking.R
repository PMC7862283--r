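#' Build a background model from a window of frames
#'
#' Per-pixel statistic (median by default; robust to the larva itself, which
#' occupies few pixels at any one spot) over `window` frames starting at
#' `start`, optionally subsampled with `stride` to cut cost.
#'
#' @param frames H x W x T numeric array, or a `frameStack`.
#' @param window number of frames in the window (>= 3).
#' @param statistic `"median"` or `"mean"`.
#' @param start first frame index of the window.
#' @param stride keep every `stride`-th frame of the window.
#' @return list of class `backgroundModel`: `image` (H x W matrix),
#'   `builtFrom` (index range), `statistic`.
#' @export
buildBackground <- function(frames, window, statistic = c("median", "mean"),
                            start = 1L, stride = 1L) {
  statistic <- match.arg(statistic)
  if (inherits(frames, "frameStack")) frames <- frames$frames
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  nT <- dim(frames)[3]
  if (window < 3) stop("'window' must be >= 3")
  if (start + window - 1 > nT)
    stop(sprintf("window of %d frames at %d exceeds the %d available",
                 window, start, nT))
  idx <- seq.int(start, start + window - 1L, by = stride)
  m <- matrix(frames[, , idx], nrow = prod(dim(frames)[1:2]))
  img <- if (statistic == "median") {
    if (length(idx) == 1L) m[, 1] else apply(m, 1, stats::median)
  } else rowMeans(m)
  structure(list(image = matrix(img, dim(frames)[1], dim(frames)[2]),
                 builtFrom = range(idx), statistic = statistic),
            class = "backgroundModel")
}

#' Detect the larva in one frame by background subtraction
#'
#' Subtracts the background within the lane ROI, removes the spatially
#' uniform component (median of the difference, so a constant added to all
#' frames cancels), optionally smooths, then thresholds the absolute
#' difference. The centroid is the intensity-unweighted mean of the
#' above-threshold pixel coordinates of the largest connected component
#' (one larva per lane by design; smaller components are noise).
#'
#' @param frame H x W matrix.
#' @param bg a [buildBackground()] model.
#' @param laneRoi list with 0-based inclusive pixel bounds `x0`, `x1`,
#'   `y0`, `y1` (as produced by [laneGeometry()]).
#' @param threshold absolute-difference threshold; `NULL` uses 5x the
#'   robust noise SD (MAD) of the centered difference image.
#' @param smoothSigma Gaussian pre-smoothing sigma for the difference
#'   image, px (0 = off).
#' @return list `(x, y, area)` with 0-based sub-pixel centroid
#'   (x = column, y = row, origin top-left), or `NULL` when no pixel
#'   exceeds the threshold (absence is a valid outcome).
#' @export
detectInFrame <- function(frame, bg, laneRoi, threshold = NULL,
                          smoothSigma = 0) {
  rows <- (laneRoi$y0 + 1L):(laneRoi$y1 + 1L)
  cols <- (laneRoi$x0 + 1L):(laneRoi$x1 + 1L)
  if (min(rows) < 1 || max(rows) > nrow(frame) ||
      min(cols) < 1 || max(cols) > ncol(frame))
    stop("lane ROI outside frame bounds")
  d <- frame[rows, cols] - bg$image[rows, cols]
  d <- d - stats::median(d)
  if (smoothSigma > 0) d <- gaussSmooth2D(d, smoothSigma)
  a <- abs(d)
  if (is.null(threshold)) {
    threshold <- 5 * stats::mad(as.vector(d))
    # noise-free difference images have zero MAD; fall back to half the
    # peak difference so the blob core still segments cleanly
    if (threshold <= 0) threshold <- 0.5 * max(a)
    if (threshold <= 0) return(NULL)
  }
  mask <- a > threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  idx <- which(keep, arr.ind = TRUE)
  list(x = mean(idx[, 2] - 1) + laneRoi$x0,
       y = mean(idx[, 1] - 1) + laneRoi$y0,
       area = nrow(idx))
}

#' Track larvae across a frame sequence
#'
#' Runs background-subtraction detection in every lane of every frame. The
#' background is re-estimated every `updatePeriod` frames from the trailing
#' `window` frames (the first background comes from the leading window), to
#' compensate slow environmental drift. Missed detections are retained as
#' invalid samples, never interpolated here.
#'
#' @param frames H x W x T array or `frameStack` (whose times are used).
#' @param lanes list of lane ROIs ([laneGeometry()] `lanes`).
#' @param updatePeriod frames between background re-estimations; `Inf`
#'   keeps the initial background for the whole recording.
#' @param window frames per background estimate.
#' @param stride frame subsampling inside the background window.
#' @param threshold fixed detection threshold, or `NULL` for the per-frame
#'   robust default.
#' @param smoothSigma difference-image smoothing sigma, px.
#' @param times frame timestamps (seconds); default 1 s spacing.
#' @return list of [Trajectory-class] objects (units px), one per lane.
#' @export
track <- function(frames, lanes, updatePeriod = 1000, window = 100,
                  stride = 5L, threshold = NULL, smoothSigma = 0,
                  times = NULL) {
  if (inherits(frames, "frameStack")) {
    if (is.null(times)) times <- frames$times
    frames <- frames$frames
  }
  if (!length(lanes)) stop("empty lane list")
  nT <- dim(frames)[3]
  if (is.null(times)) times <- seq_len(nT) - 1
  window <- min(window, nT)
  bg <- buildBackground(frames, window = window, start = 1L,
                        stride = stride)
  nL <- length(lanes)
  xs <- matrix(NA_real_, nT, nL)
  ys <- matrix(NA_real_, nT, nL)
  ok <- matrix(FALSE, nT, nL)
  for (ti in seq_len(nT)) {
    if (is.finite(updatePeriod) && ti > window &&
        (ti - 1) %% updatePeriod == 0)
      bg <- buildBackground(frames, window = window,
                            start = ti - window, stride = stride)
    fr <- frames[, , ti]
    for (li in seq_len(nL)) {
      det <- detectInFrame(fr, bg, lanes[[li]], threshold = threshold,
                           smoothSigma = smoothSigma)
      if (!is.null(det)) {
        xs[ti, li] <- det$x
        ys[ti, li] <- det$y
        ok[ti, li] <- TRUE
      }
    }
  }
  lapply(seq_len(nL), function(li)
    Trajectory(times = times, x = xs[, li], y = ys[, li], valid = ok[, li],
               laneId = paste0("lane", li), units = "px"))
}
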