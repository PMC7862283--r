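#' @rdname Trajectory-class
#' @export
setMethod("laneId", "Trajectory", function(object) object@laneId)

#' @rdname Trajectory-class
#' @export
setMethod("frameTimes", "Trajectory", function(object) object@times)

#' @rdname Trajectory-class
#' @export
setMethod("coords", "Trajectory", function(object)
  cbind(x = object@x, y = object@y))

#' @rdname Trajectory-class
#' @export
setMethod("isValid", "Trajectory", function(object) object@valid)

#' @rdname Trajectory-class
#' @export
setMethod("groundTruth", "Trajectory", function(object) object@groundTruth)

#' Path length of a trajectory
#'
#' Total Euclidean path length over consecutive valid samples. Segments
#' spanning an invalid frame are skipped.
#'
#' @rdname Trajectory-class
#' @export
setMethod("pathLength", "Trajectory", function(object) {
  v <- object@valid
  if (sum(v) < 2) return(0)
  ok <- v[-length(v)] & v[-1]
  dx <- diff(object@x)[ok]
  dy <- diff(object@y)[ok]
  sum(sqrt(dx^2 + dy^2))
})

#' @export
setMethod("length", "Trajectory", function(x) length(x@times))

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("Trajectory '%s': %d frames, %.1f s, units=%s (%d%% valid)\n",
              object@laneId, n,
              if (n) diff(range(object@times)) else 0, object@units,
              if (n) round(100 * mean(object@valid)) else 0L))
  if (length(object@groundTruth))
    cat(sprintf("  ground truth: %d bouts logged\n",
                nrow(object@groundTruth$bouts)))
})

#' @rdname ActivityStackSet-class
#' @export
setMethod("stackDims", "ActivityStackSet", function(object) object@dims)

#' @rdname ActivityStackSet-class
#' @export
setMethod("nFish", "ActivityStackSet", function(object) length(object@perk))

#' @rdname ActivityStackSet-class
#' @export
setMethod("fishMeta", "ActivityStackSet", function(object) object@meta)

setMethod("show", "ActivityStackSet", function(object) {
  cat(sprintf("ActivityStackSet: %d fish, %s voxels\n", nFish(object),
              paste(object@dims, collapse = " x ")))
  print(table(object@meta$group))
})

#' @rdname SignificanceMap-class
#' @export
setMethod("stackDims", "SignificanceMap", function(object) dim(object@z))

#' @rdname SignificanceMap-class
#' @export
setMethod("zMap", "SignificanceMap", function(object) object@z)

#' @rdname SignificanceMap-class
#' @export
setMethod("pMap", "SignificanceMap", function(object) object@p)

#' @rdname SignificanceMap-class
#' @export
setMethod("medianDiffMap", "SignificanceMap",
          function(object) object@medianDiff)

#' @rdname SignificanceMap-class
#' @export
setMethod("signedMask", "SignificanceMap", function(object) object@signedMask)

setMethod("show", "SignificanceMap", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("SignificanceMap: %s voxels, %d analyzed, groups n=%s\n",
              paste(dim(object@z), collapse = " x "), nv,
              paste(object@nPerGroup, collapse = "/")))
  if (length(object@threshold))
    cat(sprintf("  threshold: %s at %g -> %d voxels flagged (%d+/%d-)\n",
                object@threshold$mode, object@threshold$level,
                sum(object@signedMask != 0), sum(object@signedMask == 1),
                sum(object@signedMask == -1)))
})
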