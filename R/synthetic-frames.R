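#' Lane geometry for rendered videos
#'
#' Describes how one or more lanes map onto the pixel grid of a rendered
#' frame: lanes are stacked vertically, each `widthMm` tall, with a margin
#' of background pixels around the lane block.
#'
#' @param lengthMm lane length, mm.
#' @param widthMm lane width, mm.
#' @param pxPerMm pixel pitch.
#' @param nLanes number of lanes stacked along y.
#' @param marginPx background margin around the lane block, pixels.
#' @return list of class `laneGeometry` with frame size and per-lane ROIs
#'   (`x0`, `x1`, `y0`, `y1`, 0-based inclusive pixel bounds).
#' @export
laneGeometry <- function(lengthMm = 65, widthMm = 3, pxPerMm = 1.6,
                         nLanes = 1, marginPx = 4) {
  checkPositive(lengthMm, "lengthMm"); checkPositive(widthMm, "widthMm")
  checkPositive(pxPerMm, "pxPerMm")
  laneW <- as.integer(ceiling(lengthMm * pxPerMm))
  laneH <- as.integer(ceiling(widthMm * pxPerMm))
  marginPx <- as.integer(marginPx)
  W <- laneW + 2L * marginPx
  H <- as.integer(nLanes) * laneH + 2L * marginPx
  ## lanes partition the frame in y; each ROI spans the full width so a
  ## blob resting against a lane end is not clipped by the ROI boundary
  rois <- lapply(seq_len(nLanes), function(i) {
    y0 <- marginPx + (i - 1L) * laneH
    list(x0 = 0L, x1 = W - 1L, y0 = y0, y1 = y0 + laneH - 1L)
  })
  structure(list(width = W, height = H, pxPerMm = pxPerMm,
                 lengthMm = lengthMm, widthMm = widthMm,
                 marginPx = marginPx, lanes = rois),
            class = "laneGeometry")
}

## additive Gaussian blob, evaluated on the pixel grid (0-based centers)
addBlob <- function(frame, cx, cy, sigma, amplitude) {
  H <- nrow(frame); W <- ncol(frame)
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop(sprintf("blob center (%.1f, %.1f) outside frame bounds", cx, cy))
  r <- ceiling(6 * sigma)
  xs <- max(0, floor(cx) - r):min(W - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(H - 1, ceiling(cy) + r)
  g <- amplitude * outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
                         exp(-(xs - cx)^2 / (2 * sigma^2)))
  frame[ys + 1L, xs + 1L] <- frame[ys + 1L, xs + 1L] + g
  frame
}

#' Render lane-video frames from trajectories
#'
#' Produces grayscale frames with one Gaussian blob per lane at the planted
#' positions, over a background that may drift slowly in intensity (the
#' evaporation-like disturbance the rolling background model compensates).
#' The drift is spatially structured: per-pixel rate =
#' `backgroundDrift * driftPattern`.
#'
#' @param trajs a [Trajectory-class] (mm units) or list of them, one per
#'   lane of `geometry`, all sharing the same frame times.
#' @param geometry a [laneGeometry()].
#' @param blobSigma blob Gaussian sigma, px.
#' @param blobAmplitude blob peak intensity above background.
#' @param backgroundDrift intensity drift per frame (scales `driftPattern`).
#' @param driftPattern `"gradient"` (left-to-right ramp 0..1), `"uniform"`,
#'   or a matrix of per-pixel rates (frame-sized).
#' @param noiseSd i.i.d. Gaussian pixel noise SD.
#' @param background base background: scalar or frame-sized matrix.
#' @param seed RNG seed for the noise.
#' @return list of class `frameStack`: `frames` (H x W x T array),
#'   `times`, `geometry`, `truth` (planted px positions per lane/frame).
#' @export
renderFrames <- function(trajs, geometry, blobSigma = 2, blobAmplitude = 120,
                         backgroundDrift = 0, driftPattern = "gradient",
                         noiseSd = 0, background = 30, seed = 1L) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (length(trajs) != length(geometry$lanes))
    stop("need one trajectory per lane")
  H <- geometry$height; W <- geometry$width
  nT <- length(frameTimes(trajs[[1]]))
  base <- if (is.matrix(background)) background else
    matrix(background, H, W)
  stopifnot(all(dim(base) == c(H, W)))
  pat <- if (is.matrix(driftPattern)) driftPattern
  else switch(driftPattern,
              gradient = matrix(rep(seq(0, 1, length.out = W), each = H),
                                H, W),
              uniform = matrix(1, H, W),
              stop("unknown driftPattern"))
  pxmm <- geometry$pxPerMm
  nL <- length(trajs)
  truth <- data.frame(lane = rep(seq_len(nL), each = nT),
                      frame = rep(seq_len(nT), times = nL),
                      x = NA_real_, y = NA_real_)
  withSeed(seed, {
    frames <- array(0, dim = c(H, W, nT))
    for (ti in seq_len(nT)) {
      fr <- base + backgroundDrift * (ti - 1) * pat
      for (li in seq_len(nL)) {
        tr <- trajs[[li]]
        roi <- geometry$lanes[[li]]
        cx <- roi$x0 + tr@x[ti] * pxmm
        cy <- roi$y0 + tr@y[ti] * pxmm
        fr <- addBlob(fr, cx, cy, blobSigma, blobAmplitude)
        k <- (li - 1L) * nT + ti
        truth$x[k] <- cx
        truth$y[k] <- cy
      }
      if (noiseSd > 0)
        fr <- fr + matrix(stats::rnorm(H * W, sd = noiseSd), H, W)
      frames[, , ti] <- fr
    }
    structure(list(frames = frames, times = frameTimes(trajs[[1]]),
                   geometry = geometry, truth = truth),
              class = "frameStack")
  })
}
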