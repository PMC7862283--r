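#' Per-voxel pERK/tERK ratio with a validity mask
#'
#' Divides the pERK stack by the tERK stack voxel-wise to normalize for
#' individual staining variability. Voxels with tERK below `terkFloor` are
#' masked invalid (NA) rather than producing blow-ups; the default floor is
#' the 5th percentile of the nonzero tERK values of the stack.
#'
#' @param perk,terk 3-D arrays of equal dims.
#' @param terkFloor minimum tERK for a voxel to be analyzed.
#' @return list: `ratio` (3-D array, NA where invalid), `valid` (logical
#'   array).
#' @export
ratioStack <- function(perk, terk, terkFloor = NULL) {
  if (!identical(dim(perk), dim(terk)))
    stop("pERK and tERK stack dims differ")
  if (is.null(terkFloor)) {
    nz <- terk[terk > 0]
    terkFloor <- if (length(nz)) stats::quantile(nz, 0.05) else Inf
  }
  valid <- is.finite(terk) & terk >= terkFloor & is.finite(perk)
  ratio <- array(NA_real_, dim = dim(perk))
  ratio[valid] <- perk[valid] / terk[valid]
  list(ratio = ratio, valid = valid)
}

#' Ratio stacks for every fish of an ActivityStackSet
#'
#' @param set an [ActivityStackSet-class].
#' @param terkFloor per-stack floor passed to [ratioStack()].
#' @return list of [ratioStack()] results, one per fish.
#' @export
ratioStacks <- function(set, terkFloor = NULL)
  lapply(seq_len(nFish(set)), function(i)
    ratioStack(set@perk[[i]], set@terk[[i]], terkFloor = terkFloor))

## linear resampling of a vectorized axis to a new length (block mean when
## the factor is an integer; interpolation at cell centers otherwise)
resampleAxis <- function(a, along, target) {
  d <- dim(a)
  n <- d[along]
  if (target == n) return(a)
  if (target > n) stop("target dims must not exceed input dims")
  perm <- c(along, setdiff(1:3, along))
  m <- aperm(a, perm)
  dim(m) <- c(n, prod(d[perm[-1]]))
  out <- if (n %% target == 0) {
    f <- n %/% target
    g <- rep(seq_len(target), each = f)
    rowsum(m, g) / f
  } else {
    src <- (seq_len(n) - 0.5) / n
    dst <- (seq_len(target) - 0.5) / target
    apply(m, 2, function(col)
      stats::approx(src, col, xout = dst, rule = 2)$y)
  }
  dim(out) <- c(target, d[perm[-1]])
  aperm(out, order(perm))
}

#' Downsample and smooth a stack
#'
#' Resamples the stack to `targetDims` (block mean when the reduction
#' factor is integer, linear interpolation at cell centers otherwise), then
#' smooths each z slice with a 2-D Gaussian of the given sigma. Both steps
#' preserve the mean of a constant stack exactly; with `sigma = 0` and
#' `targetDims` equal to the input dims the operation is the identity.
#'
#' @param stack 3-D array.
#' @param targetDims integer(3) output grid (each <= the input dim);
#'   `NULL` keeps the input grid.
#' @param sigma per-slice Gaussian sigma, px (0 = off).
#' @return processed 3-D array.
#' @export
preprocessStack <- function(stack, targetDims = NULL, sigma = 0) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (!is.null(targetDims)) {
    if (length(targetDims) != 3L || any(targetDims < 1))
      stop("targetDims must be three positive integers")
    if (any(targetDims > dim(stack)))
      stop("target dims must not exceed input dims")
    for (ax in 1:3) stack <- resampleAxis(stack, ax, targetDims[ax])
  }
  if (sigma > 0)
    for (z in seq_len(dim(stack)[3]))
      stack[, , z] <- gaussSmooth2D(stack[, , z], sigma)
  stack
}

## per-voxel Mann-Whitney over a voxels x fish matrix; returns z and
## median difference (first nA columns = group A). Same statistic as
## mannWhitney(mode = "normal"), vectorized over voxels.
voxelMW <- function(m, nA) {
  n <- ncol(m)
  nB <- n - nA
  ia <- seq_len(nA)
  t(apply(m, 1, function(v) {
    r <- rank(v)
    U <- sum(r[ia]) - nA * (nA + 1) / 2
    ts <- tieSum(v)
    s2 <- nA * nB / 12 * ((n + 1) - ts / (n * (n - 1)))
    z <- if (s2 > 0) (U - nA * nB / 2) / sqrt(s2) else 0
    c(z, stats::median(v[ia]) - stats::median(v[-ia]))
  }))
}

#' Voxel-wise Mann-Whitney Z map between two groups of ratio stacks
#'
#' For every voxel valid in all fish of both groups (complete-case rule, so
#' group sizes are constant per voxel), computes the tie-corrected normal
#' Mann-Whitney Z deviate of group A vs group B across fish, the two-sided
#' p value, and the difference of group medians (A minus B).
#'
#' @param groupA,groupB lists of [ratioStack()] results (or plain 3-D
#'   arrays with NA at invalid voxels), >= 2 fish per group.
#' @return a [SignificanceMap-class] with `z`, `p`, `medianDiff` filled
#'   and an empty threshold.
#' @export
voxelZMap <- function(groupA, groupB) {
  getArr <- function(x) if (is.list(x) && !is.null(x$ratio)) x$ratio else x
  ga <- lapply(groupA, getArr)
  gb <- lapply(groupB, getArr)
  if (length(ga) < 2 || length(gb) < 2)
    stop("need at least two fish per group")
  d <- dim(ga[[1]])
  for (s in c(ga, gb)) if (!identical(dim(s), d))
    stop("all stacks must share dims")
  m <- vapply(c(ga, gb), as.vector, numeric(prod(d)))
  valid <- rowSums(!is.finite(m)) == 0
  z <- p <- md <- array(NA_real_, dim = d)
  if (any(valid)) {
    res <- voxelMW(m[valid, , drop = FALSE], length(ga))
    z[valid] <- res[, 1]
    p[valid] <- 2 * stats::pnorm(-abs(res[, 1]))
    md[valid] <- res[, 2]
  }
  new("SignificanceMap", z = z, p = p, medianDiff = md,
      valid = array(valid, dim = d),
      signedMask = array(0L, dim = d), threshold = list(),
      nPerGroup = c(length(ga), length(gb)))
}

#' Threshold a significance map
#'
#' FDR mode applies the Benjamini-Hochberg step-up over the analyzed
#' voxels; fixed mode thresholds the per-voxel p directly (the figure-style
#' threshold is 5e-5). The sign of a flagged voxel comes from the median
#' difference: +1 where group A is greater, -1 where group B is greater.
#'
#' @param map a [voxelZMap()] result.
#' @param mode `"fdr"` or `"fixed"`.
#' @param level FDR level q, or the fixed p threshold.
#' @return the map with `signedMask` and `threshold` filled.
#' @export
thresholdMap <- function(map, mode = c("fdr", "fixed"), level = 0.05) {
  mode <- match.arg(mode)
  valid <- map@valid
  if (!any(valid)) stop("no analyzed voxels")
  pv <- map@p[valid]
  rej <- if (mode == "fdr") bhFdr(pv, q = level)$reject else pv <= level
  sm <- array(0L, dim = dim(map@z))
  sm[valid][rej] <- ifelse(map@medianDiff[valid][rej] > 0, 1L,
                           ifelse(map@medianDiff[valid][rej] < 0, -1L, 0L))
  map@signedMask <- sm
  map@threshold <- list(mode = mode, level = level,
                        pCut = if (mode == "fdr")
                          bhFdr(pv, q = level)$threshold else level)
  map
}

#' Render a thresholded map as signed 16-bit intensities
#'
#' At flagged voxels the intensity is proportional to the absolute median
#' difference, scaled linearly to the 0-65535 range with saturation at
#' `saturationFrac` of the maximum |median difference| over flagged voxels
#' (60% by default); unflagged voxels are 0. Maximum-intensity and
#' standard-deviation z projections are emitted for inspection.
#'
#' @param map a thresholded [SignificanceMap-class].
#' @param saturationFrac saturation point as a fraction of the maximum.
#' @return list: `intensity` (3-D array of 0-65535 integers), `sign`
#'   (the signed mask), `mip` and `sdProj` (H x W projections of the
#'   intensity volume).
#' @export
renderSignificance <- function(map, saturationFrac = 0.6) {
  flagged <- map@signedMask != 0
  intensity <- array(0, dim = dim(map@z))
  if (any(flagged)) {
    M <- max(abs(map@medianDiff[flagged]))
    sat <- saturationFrac * M
    intensity[flagged] <- round(
      65535 * pmin(abs(map@medianDiff[flagged]) / sat, 1))
  }
  list(intensity = intensity, sign = map@signedMask,
       mip = apply(intensity, c(1, 2), max),
       sdProj = apply(intensity, c(1, 2), stats::sd))
}

#' Per-ROI mean ratios with genotype x condition statistics
#'
#' Computes, for every fish of the set, the mean pERK/tERK ratio over the
#' valid voxels of each labelled ROI, then runs a two-way ANOVA (genotype x
#' condition) with Sidak-adjusted genotype contrasts per condition in each
#' ROI (interaction / genotype / condition p
#' followed by per-condition pairwise p).
#'
#' @param set an [ActivityStackSet-class] whose `meta` has `genotype` and
#'   `condition` columns.
#' @param roiMasks 3-D integer label array on the common grid (0 =
#'   unlabelled).
#' @param roiNames optional named translation of labels.
#' @param terkFloor passed to [ratioStack()].
#' @return list: `values` (fish x ROI long table of mean ratios) and
#'   `stats` (per-ROI ANOVA p values and per-condition adjusted contrast
#'   p values; NULL when a factor has a single level).
#' @export
roiSummarize <- function(set, roiMasks, roiNames = NULL, terkFloor = NULL) {
  if (!all(c("genotype", "condition") %in% names(set@meta)))
    stop("set meta needs 'genotype' and 'condition' columns")
  if (!identical(dim(roiMasks), stackDims(set)))
    stop("ROI label volume must be on the common grid")
  labs <- sort(setdiff(unique(as.integer(roiMasks)), 0L))
  if (!length(labs)) stop("no ROI labels found")
  rs <- ratioStacks(set, terkFloor = terkFloor)
  vals <- list()
  for (lb in labs) {
    inRoi <- roiMasks == lb
    nm <- if (!is.null(roiNames) && !is.null(roiNames[[as.character(lb)]]))
      roiNames[[as.character(lb)]] else paste0("roi", lb)
    mr <- vapply(rs, function(r) {
      v <- r$ratio[inRoi & r$valid]
      if (!length(v)) stop(sprintf("ROI '%s' (label %d) is empty", nm, lb))
      mean(v)
    }, numeric(1))
    vals[[length(vals) + 1L]] <-
      data.frame(roi = nm, fishId = seq_len(nFish(set)),
                 genotype = set@meta$genotype,
                 condition = set@meta$condition, meanRatio = mr)
  }
  values <- do.call(rbind, vals)
  stats <- NULL
  if (length(unique(values$genotype)) >= 2 &&
      length(unique(values$condition)) >= 2) {
    stats <- do.call(rbind, lapply(split(values, values$roi), function(v) {
      aa <- twoWayAnovaSidak(v$meanRatio, v$genotype, v$condition)
      tab <- aa$anova
      row <- data.frame(roi = v$roi[1],
                        interactionP = tab$p[tab$term == "interaction"],
                        genotypeP = tab$p[tab$term == "factorA"],
                        conditionP = tab$p[tab$term == "factorB"])
      cons <- aa$contrasts
      for (i in seq_len(nrow(cons)))
        row[[paste0("p_", cons$condition[i])]] <- cons$pAdj[i]
      row
    }))
    rownames(stats) <- NULL
  }
  list(values = values, stats = stats)
}
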