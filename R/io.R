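#' Write / read trajectories as CSV
#'
#' Long format, one row per lane and frame: `lane`, `frame`, `t`, `x`,
#' `y`, `valid`. Units and calibration travel in a JSON-free header
#' comment-less design: they are columns `units` and `pxPerMm` repeated
#' per lane (kept simple so any table reader can ingest the file).
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(trajs, path) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr)
    data.frame(lane = laneId(tr), frame = seq_along(tr@times),
               t = tr@times, x = tr@x, y = tr@y, valid = tr@valid,
               units = tr@units, pxPerMm = tr@pxPerMm))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @param path CSV path written by [writeTrajectoryCSV()].
#' @return for the reader: list of [Trajectory-class] objects.
#' @export
readTrajectoryCSV <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$lane), function(s)
    Trajectory(times = s$t, x = s$x, y = s$y, valid = s$valid,
               laneId = s$lane[1], units = s$units[1],
               pxPerMm = s$pxPerMm[1]))
}

#' Write / read a 3-D stack as multi-page TIFF
#'
#' z slices become TIFF pages. Values are stored as 32-bit floats scaled
#' by `scale` into \[0, 1\] (the TIFF writer's range); the reader applies
#' the inverse, so round-trips are lossless up to float precision.
#'
#' @param stack 3-D numeric array (x, y, z as rows, cols, pages).
#' @param path TIFF path.
#' @param scale intensity scale mapped to 1.0; default the stack maximum.
#' @return `path` invisibly (writer); the 3-D array (reader; values in
#'   `[0, scale]`).
#' @export
writeStackTIFF <- function(stack, path, scale = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (is.null(scale)) scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(z) {
    pg <- stack[, , z] / scale
    pg[pg < 0] <- 0
    pg[pg > 1] <- 1
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  attr(path, "scale") <- scale
  invisible(path)
}

#' @rdname writeStackTIFF
#' @export
readStackTIFF <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    arr[, , z] <- if (length(dim(pg)) == 3) pg[, , 1] else pg
  }
  arr * scale
}

#' Read a checkpoint table CSV
#'
#' Expects per-larva metadata columns followed by checkpoint columns named
#' `t<minutes>` (e.g. `t5, t10, ...`) holding 0/1 or logical responses.
#'
#' @param path CSV path.
#' @param interval checkpoint spacing, minutes.
#' @return an [emergenceTimes()] record table.
#' @export
readCheckTable <- function(path, interval = 5) {
  d <- utils::read.csv(path)
  tcols <- grep("^t[0-9]+$", names(d))
  if (!length(tcols)) stop("no checkpoint columns (t5, t10, ...) found")
  o <- tcols[order(as.integer(sub("^t", "", names(d)[tcols])))]
  emergenceTimes(d[, o] != 0, interval = interval,
                 meta = d[, setdiff(seq_along(d), tcols), drop = FALSE])
}
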