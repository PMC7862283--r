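test_that("ratio stacks divide channels, guard zeros, and scale-cancel", {
  perk <- array(4, c(3, 3, 2)); terk <- array(2, c(3, 3, 2))
  r <- ratioStack(perk, terk, terkFloor = 1e-9)
  expect_true(all(r$valid))
  expect_true(all(r$ratio == 2))
  terk[1, 1, 1] <- 0
  r2 <- ratioStack(perk, terk, terkFloor = 1e-9)
  expect_false(r2$valid[1, 1, 1])
  expect_true(is.na(r2$ratio[1, 1, 1]))
  # scaling both channels leaves the ratio unchanged
  r3 <- ratioStack(perk * 7, terk * 7, terkFloor = 1e-9)
  expect_equal(r3$ratio[r2$valid], r2$ratio[r2$valid])
  expect_error(ratioStack(perk, array(1, c(2, 2, 2))), "dims differ")
})

test_that("preprocessing is the identity at native dims and preserves means", {
  st <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_identical(preprocessStack(st, targetDims = c(8, 8, 3), sigma = 0),
                   st)
  cst <- array(3.7, c(8, 8, 4))
  out <- preprocessStack(cst, targetDims = c(4, 4, 2), sigma = 1.5)
  expect_equal(as.vector(out), rep(3.7, 4 * 4 * 2), tolerance = 1e-12)
  expect_error(preprocessStack(st, targetDims = c(16, 8, 3)),
               "must not exceed")
})

test_that("a smoothed impulse matches the closed-form Gaussian kernel", {
  st <- array(0, c(41, 41, 1))
  st[21, 21, 1] <- 1
  sm <- preprocessStack(st, sigma = 2)
  ys <- xs <- seq_len(41) - 21
  closed <- outer(exp(-ys^2 / 8), exp(-xs^2 / 8))
  closed <- closed / sum(closed)
  # away from borders (kernel radius 12 fits fully inside)
  expect_lt(max(abs(sm[, , 1] - closed)), 1e-6)
})

test_that("copied groups give an identically null Z map", {
  set.seed(67)
  fish <- lapply(1:3, function(i) array(runif(4 * 4 * 2), c(4, 4, 2)))
  zm <- voxelZMap(fish, fish)
  expect_true(all(zMap(zm) == 0))
  expect_true(all(medianDiffMap(zm) == 0))
  expect_true(all(pMap(zm) == 1))
})

test_that("the voxel Z map equals the stats-module Mann-Whitney per voxel", {
  set.seed(71)
  gA <- lapply(1:3, function(i) array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  gB <- lapply(1:4, function(i) array(rnorm(4 * 4 * 2, 0.5), c(4, 4, 2)))
  zm <- voxelZMap(gA, gB)
  for (v in seq_len(4 * 4 * 2)) {
    idx <- arrayInd(v, c(4, 4, 2))
    a <- vapply(gA, function(s) s[idx[1], idx[2], idx[3]], numeric(1))
    b <- vapply(gB, function(s) s[idx[1], idx[2], idx[3]], numeric(1))
    ref <- mannWhitney(a, b, mode = "normal")
    expect_equal(zMap(zm)[idx[1], idx[2], idx[3]], ref$z, tolerance = 1e-12)
    expect_equal(pMap(zm)[idx[1], idx[2], idx[3]], ref$p, tolerance = 1e-12)
    expect_equal(medianDiffMap(zm)[idx[1], idx[2], idx[3]],
                 median(a) - median(b), tolerance = 1e-12)
  }
  expect_error(voxelZMap(gA[1], gB), "two fish")
})

test_that("thresholding flags by fixed p or FDR with signs from medians", {
  set.seed(73)
  gA <- lapply(1:6, function(i) array(rnorm(6 * 6 * 2), c(6, 6, 2)))
  gB <- lapply(1:6, function(i) array(rnorm(6 * 6 * 2), c(6, 6, 2)))
  zm <- voxelZMap(gA, gB)
  # all p = 1 case: degenerate identical groups
  zm0 <- voxelZMap(gA, gA)
  tm0 <- thresholdMap(zm0, "fdr", 0.05)
  expect_true(all(signedMask(tm0) == 0))
  # fixed threshold keeps only voxels with p below it
  tm <- thresholdMap(zm, "fixed", 5e-5)
  expect_equal(sum(signedMask(tm) != 0), sum(pMap(zm) <= 5e-5))
  # signs follow the median difference
  tm2 <- thresholdMap(zm, "fixed", 0.5)
  sm <- signedMask(tm2)
  md <- medianDiffMap(zm)
  expect_true(all(md[sm == 1] > 0))
  expect_true(all(md[sm == -1] < 0))
})

test_that("rendering follows the 60%-saturation arithmetic exactly", {
  d <- c(5, 5, 1)
  md <- array(0, d)
  md[1, 1, 1] <- 10; md[2, 1, 1] <- 6; md[3, 1, 1] <- 3
  md[4, 1, 1] <- -6
  sm <- array(0L, d)
  sm[md != 0] <- ifelse(md[md != 0] > 0, 1L, -1L)
  map <- new("SignificanceMap", z = array(0, d), p = array(0, d),
             medianDiff = md, valid = array(TRUE, d), signedMask = sm,
             threshold = list(mode = "fixed", level = 5e-5, pCut = 5e-5),
             nPerGroup = c(2L, 2L))
  r <- renderSignificance(map, saturationFrac = 0.6)
  expect_equal(r$intensity[1, 1, 1], 65535)           # at max
  expect_equal(r$intensity[2, 1, 1], 65535)           # at 0.6 * max
  expect_lte(abs(r$intensity[3, 1, 1] - 32768), 1)    # half scale
  expect_equal(r$intensity[4, 1, 1], 65535)           # magnitude only
  expect_equal(r$intensity[5, 1, 1], 0)               # unflagged
  # monotone: larger |median diff| never maps lower
  o <- order(abs(md[sm != 0]))
  ints <- r$intensity[sm != 0][o]
  expect_true(all(diff(ints) >= 0))
  expect_equal(dim(r$mip), c(5, 5))
})

test_that("planted ROI effects light up inside the mask and stay quiet outside", {
  mask <- array(FALSE, c(24, 24, 4))
  mask[8:14, 8:14, 2:3] <- TRUE
  spec <- stackEffectSpec(mask, ratioShift = 0.3, noiseSd = 0.1,
                          nPerGroup = 16)
  st <- simulateActivityStacks(spec, seed = 79)
  rs <- ratioStacks(st, terkFloor = 1e-9)
  zm <- voxelZMap(rs[1:16], rs[17:32])
  tm <- thresholdMap(zm, "fdr", 0.05)
  sm <- signedMask(tm)
  expect_gte(mean(sm[mask] != 0), 0.8)
  expect_lte(mean(sm[!mask] != 0), 0.05)
  # planted shift is in group B: flagged voxels carry a negative sign
  expect_true(all(sm[mask][sm[mask] != 0] == -1))
})

test_that("ROI summaries recover a planted genotype effect in one region only", {
  dims <- c(16, 16, 2)
  roi <- array(0L, dims)
  roi[2:6, 2:6, 1] <- 1L
  roi[10:14, 10:14, 2] <- 2L
  set.seed(83)
  geno <- rep(rep(c("wt", "mut"), each = 4), 2)
  cond <- rep(c("baseline", "propofol"), each = 8)
  perk <- list(); terk <- list()
  for (i in seq_len(16)) {
    ratio <- array(1 + rnorm(prod(dims), sd = 0.05), dims)
    if (geno[i] == "mut") ratio[roi == 1L] <- ratio[roi == 1L] + 0.5
    tk <- array(100 * exp(rnorm(prod(dims), sd = 0.1)), dims)
    perk[[i]] <- ratio * tk; terk[[i]] <- tk
  }
  st <- ActivityStackSet(perk, terk,
                         meta = data.frame(group = cond, genotype = geno,
                                           condition = cond))
  out <- roiSummarize(st, roi, terkFloor = 1e-9)
  expect_equal(nrow(out$values), 32)
  s <- out$stats
  expect_lt(s$genotypeP[s$roi == "roi1"], 0.01)
  expect_gt(s$genotypeP[s$roi == "roi2"], 0.01)
  # ROI means are invariant to voxel ordering within the mask (means of
  # the same voxel multiset)
  v1 <- out$values$meanRatio[out$values$roi == "roi1" &
                               out$values$fishId == 1]
  r1 <- ratioStack(perk[[1]], terk[[1]], terkFloor = 1e-9)
  expect_equal(v1, mean(sample(r1$ratio[roi == 1L])), tolerance = 1e-12)
  # empty ROI errors by name
  roi2 <- roi; roi2[roi2 == 2L] <- 0L; roi2[1, 1, 1] <- 3L
  st2 <- st; st2@terk[[1]][1, 1, 1] <- 0
  expect_error(roiSummarize(st2, roi2, terkFloor = 1e-9), "roi3")
})
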