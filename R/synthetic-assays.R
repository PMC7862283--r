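#' Four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10(dose)) * hill))`.
#' With negative `hill` the curve descends with dose (loss of response as
#' anesthetic concentration rises); at `dose == EC50` the value is exactly
#' `(top + bottom) / 2`.
#'
#' @param dose positive doses (molar).
#' @param top,bottom upper and lower asymptotes.
#' @param logEC50 log10 of the midpoint concentration.
#' @param hill Hill slope.
#' @return response values.
#' @export
fourPL <- function(dose, top, bottom, logEC50, hill)
  bottom + (top - bottom) / (1 + 10^((logEC50 - log10(dose)) * hill))

#' Propofol dose series of the behavioral assay
#'
#' The seven bath concentrations (molar) at which the three behavioral
#' endpoints are scored: 0.05, 1, 2, 4, 6, 8 and 10 uM.
#'
#' @return numeric vector of 7 molar concentrations.
#' @export
propofolDoses <- function() c(0.05, 1, 2, 4, 6, 8, 10) * 1e-6

#' Simulate per-dose response counts from a 4PL curve
#'
#' Binomial draws with success probability given by the four-parameter
#' logistic at each dose.
#'
#' @param ec50 midpoint concentration (molar), > 0.
#' @param hill Hill slope (negative for loss-of-response curves).
#' @param doses dose series (molar).
#' @param nPerDose larvae tested per dose (>= 1).
#' @param top,bottom asymptotes of the generating curve.
#' @param seed RNG seed.
#' @return data.frame: `dose`, `responding`, `total`, `proportion`,
#'   `trueProb`.
#' @export
simulateDoseResponse <- function(ec50, hill, doses, nPerDose, top = 1,
                                 bottom = 0, seed = 1L) {
  checkPositive(ec50, "ec50")
  if (any(doses <= 0)) stop("doses must be positive")
  if (nPerDose < 1) stop("'nPerDose' must be >= 1")
  p <- fourPL(doses, top, bottom, log10(ec50), hill)
  withSeed(seed, {
    resp <- stats::rbinom(length(doses), nPerDose, p)
    data.frame(dose = doses, responding = resp, total = nPerDose,
               proportion = resp / nPerDose, trueProb = p)
  })
}

#' Simulate checkpointed emergence times
#'
#' Latent continuous emergence times are log-normal per genotype (median
#' `groupMedians[g]`, sdlog `spread`), rounded UP to the next checkpoint of
#' the 5-min-style grid; latent times beyond `maxFollowUp` are censored at
#' the last checkpoint.
#'
#' @param groupMedians named vector of median emergence times (minutes),
#'   one per genotype/group.
#' @param nPerGroup larvae per group (recycled over groups).
#' @param spread log-normal sdlog of latent times.
#' @param checkInterval checkpoint spacing, minutes.
#' @param maxFollowUp censoring horizon, minutes.
#' @param seed RNG seed.
#' @return data.frame of emergence records: `larvaId`, `genotype`,
#'   `emergenceTime` (on the grid), `censored`, `latent`.
#' @export
simulateEmergenceTimes <- function(groupMedians, nPerGroup, spread = 0.2,
                                   checkInterval = 5, maxFollowUp = 360,
                                   seed = 1L) {
  checkPositive(checkInterval, "checkInterval")
  checkPositive(maxFollowUp, "maxFollowUp")
  if (is.null(names(groupMedians)))
    names(groupMedians) <- paste0("group", seq_along(groupMedians))
  nPerGroup <- rep_len(nPerGroup, length(groupMedians))
  lastCheck <- floor(maxFollowUp / checkInterval) * checkInterval
  withSeed(seed, {
    out <- mapply(function(g, med, n) {
      latent <- stats::rlnorm(n, meanlog = log(med), sdlog = spread)
      cens <- latent > maxFollowUp
      tt <- ifelse(cens, lastCheck,
                   ceiling(latent / checkInterval) * checkInterval)
      data.frame(larvaId = paste0(g, "_", seq_len(n)), genotype = g,
                 emergenceTime = tt, censored = cens, latent = latent)
    }, names(groupMedians), groupMedians, nPerGroup, SIMPLIFY = FALSE)
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Planted-effect specification for synthetic activity stacks
#'
#' @param roiMask 3-D logical array marking the voxels that carry the
#'   planted group difference.
#' @param ratioShift additive shift of the group-B pERK/tERK ratio inside
#'   the mask.
#' @param noiseSd per-fish, per-voxel ratio noise SD.
#' @param nPerGroup fish per group (>= 2).
#' @return validated list of class `StackEffectSpec`.
#' @export
stackEffectSpec <- function(roiMask, ratioShift, noiseSd = 0.1,
                            nPerGroup = 16) {
  if (!is.array(roiMask) || length(dim(roiMask)) != 3L ||
      !is.logical(roiMask))
    stop("'roiMask' must be a 3-D logical array")
  checkPositive(noiseSd, "noiseSd")
  if (nPerGroup < 2) stop("'nPerGroup' must be >= 2")
  structure(list(roiMask = roiMask, ratioShift = ratioShift,
                 noiseSd = noiseSd, nPerGroup = as.integer(nPerGroup),
                 stackDims = dim(roiMask)),
            class = "StackEffectSpec")
}

#' Simulate registered pERK/tERK stack pairs for two groups
#'
#' Per fish, the tERK channel is a positive log-normal staining field and
#' the pERK channel is `ratio * tERK`, where the per-voxel ratio is
#' `1 + N(0, noiseSd)` plus, for group B only and inside the ROI mask,
#' `ratioShift`. Noise is independent across fish and voxels, so with
#' `ratioShift = 0` the two groups are exchangeable.
#'
#' @param spec a [stackEffectSpec()].
#' @param seed RNG seed.
#' @param groups labels for the two groups.
#' @param baselineRatio ratio level outside any effect.
#' @param terkLevel median tERK staining intensity.
#' @return an [ActivityStackSet-class] with `meta$group` filled.
#' @export
simulateActivityStacks <- function(spec, seed = 1L,
                                   groups = c("A", "B"),
                                   baselineRatio = 1, terkLevel = 100) {
  if (!inherits(spec, "StackEffectSpec"))
    stop("'spec' must come from stackEffectSpec()")
  d <- spec$stackDims
  nv <- prod(d)
  withSeed(seed, {
    perk <- list(); terk <- list(); grp <- character(0)
    for (g in 1:2) for (i in seq_len(spec$nPerGroup)) {
      ratio <- baselineRatio + stats::rnorm(nv, sd = spec$noiseSd)
      if (g == 2) ratio[spec$roiMask] <- ratio[spec$roiMask] +
          spec$ratioShift
      tk <- terkLevel * exp(stats::rnorm(nv, sd = 0.2))
      perk[[length(perk) + 1L]] <- array(ratio * tk, dim = d)
      terk[[length(terk) + 1L]] <- array(tk, dim = d)
      grp <- c(grp, groups[g])
    }
    ActivityStackSet(perk, terk,
                     meta = data.frame(
                       fishId = paste0(grp, "_",
                                       rep(seq_len(spec$nPerGroup), 2)),
                       group = grp))
  })
}
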