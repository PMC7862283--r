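#' @rdname Trajectory-class
#' @param object,x a `Trajectory`.
#' @export
setGeneric("laneId", function(object) standardGeneric("laneId"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname Trajectory-class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname Trajectory-class
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))

#' @rdname Trajectory-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname Trajectory-class
#' @export
setGeneric("pathLength", function(object) standardGeneric("pathLength"))

#' @rdname ActivityStackSet-class
#' @param object an `ActivityStackSet` or `SignificanceMap`.
#' @export
setGeneric("stackDims", function(object) standardGeneric("stackDims"))

#' @rdname ActivityStackSet-class
#' @export
setGeneric("nFish", function(object) standardGeneric("nFish"))

#' @rdname ActivityStackSet-class
#' @export
setGeneric("fishMeta", function(object) standardGeneric("fishMeta"))

#' @rdname SignificanceMap-class
#' @export
setGeneric("zMap", function(object) standardGeneric("zMap"))

#' @rdname SignificanceMap-class
#' @export
setGeneric("pMap", function(object) standardGeneric("pMap"))

#' @rdname SignificanceMap-class
#' @export
setGeneric("medianDiffMap", function(object) standardGeneric("medianDiffMap"))

#' @rdname SignificanceMap-class
#' @export
setGeneric("signedMask", function(object) standardGeneric("signedMask"))
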