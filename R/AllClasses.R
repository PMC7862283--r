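#' Trajectory: per-lane larval center-of-mass positions over time
#'
#' Holds one lane's tracked (or simulated) center-of-mass time series.
#' Positions are in mm (synthetic data) or pixels (tracking output, with a
#' `pxPerMm` calibration for conversion). Frames where detection failed are
#' retained with `valid = FALSE`; analysis code must tolerate such gaps.
#'
#' @slot laneId single identifier for the lane.
#' @slot times frame timestamps in seconds, strictly increasing.
#' @slot x,y per-frame center-of-mass coordinates (finite wherever valid).
#' @slot valid logical per frame: detection success.
#' @slot units `"mm"` or `"px"`.
#' @slot pxPerMm pixel pitch calibration (NA when unknown or units are mm).
#' @slot groundTruth list; for simulated trajectories, the planted event log
#'   (`bouts`, `dwells`, `events` polyline, `params`, `seed`).
#' @export
setClass("Trajectory",
  representation(laneId = "character", times = "numeric", x = "numeric",
                 y = "numeric", valid = "logical", units = "character",
                 pxPerMm = "numeric", groundTruth = "list"),
  prototype(laneId = "lane1", units = "mm", pxPerMm = NA_real_,
            groundTruth = list()))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@valid) != n)
    return("times, x, y and valid must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  v <- object@valid
  if (any(v & (!is.finite(object@x) | !is.finite(object@y))))
    return("x and y must be finite wherever valid")
  if (!object@units %in% c("mm", "px"))
    return("units must be 'mm' or 'px'")
  TRUE
})

#' Construct a Trajectory
#'
#' @param times,x,y,valid per-frame samples; `valid` defaults to all TRUE.
#' @param laneId lane identifier.
#' @param units `"mm"` or `"px"`.
#' @param pxPerMm calibration, pixels per mm (NA if unknown).
#' @param groundTruth optional planted-event log for simulated data.
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(times, x, y, valid = rep(TRUE, length(times)),
                       laneId = "lane1", units = "mm", pxPerMm = NA_real_,
                       groundTruth = list()) {
  new("Trajectory", laneId = as.character(laneId), times = as.numeric(times),
      x = as.numeric(x), y = as.numeric(y), valid = as.logical(valid),
      units = units, pxPerMm = as.numeric(pxPerMm),
      groundTruth = groundTruth)
}

#' ActivityStackSet: grouped pERK/tERK stacks on a common registered grid
#'
#' One pair of registered 3-D image stacks (pERK, tERK) per fish, all on the
#' same voxel grid, with per-fish metadata (at least a `group` column;
#' `genotype` and `condition` columns support ROI summaries).
#'
#' @slot perk,terk lists of 3-D numeric arrays, one per fish, equal dims.
#' @slot meta data.frame with one row per fish; must contain `group`.
#' @slot dims integer(3) voxel grid (x, y, z) stored as array dims.
#' @export
setClass("ActivityStackSet",
  representation(perk = "list", terk = "list", meta = "data.frame",
                 dims = "integer"))

setValidity("ActivityStackSet", function(object) {
  n <- length(object@perk)
  if (length(object@terk) != n) return("perk and terk lengths differ")
  if (nrow(object@meta) != n) return("meta must have one row per fish")
  if (!"group" %in% names(object@meta)) return("meta must contain 'group'")
  for (s in c(object@perk, object@terk)) {
    if (!is.array(s) || length(dim(s)) != 3L)
      return("stacks must be 3-D arrays")
    if (!identical(dim(s), object@dims)) return("stack dims differ")
  }
  TRUE
})

#' Construct an ActivityStackSet
#'
#' @param perk,terk lists of 3-D arrays (one per fish).
#' @param meta per-fish data.frame with a `group` column.
#' @return an [ActivityStackSet-class].
#' @export
ActivityStackSet <- function(perk, terk, meta) {
  new("ActivityStackSet", perk = perk, terk = terk,
      meta = as.data.frame(meta), dims = dim(perk[[1]]))
}

#' SignificanceMap: voxel-wise group-comparison results
#'
#' Per-voxel Mann-Whitney Z deviates, two-sided p values, median ratio
#' differences (group A minus group B) and, after thresholding, a signed
#' significance mask (+1 group A greater, -1 group B greater, 0 not
#' significant).
#'
#' @slot z,p,medianDiff 3-D numeric arrays (NA outside analyzed voxels).
#' @slot valid logical array: voxel analyzed (valid in all fish, both groups).
#' @slot signedMask integer array in \{-1, 0, +1\}.
#' @slot threshold list describing the applied threshold (mode, level, pCut).
#' @slot nPerGroup integer(2) group sizes.
#' @export
setClass("SignificanceMap",
  representation(z = "array", p = "array", medianDiff = "array",
                 valid = "array", signedMask = "array", threshold = "list",
                 nPerGroup = "integer"))

setValidity("SignificanceMap", function(object) {
  d <- dim(object@z)
  for (s in list(object@p, object@medianDiff, object@valid,
                 object@signedMask))
    if (!identical(dim(s), d)) return("component arrays must share dims")
  sm <- object@signedMask
  if (!all(sm %in% c(-1L, 0L, 1L))) return("signedMask must be -1/0/+1")
  TRUE
})
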