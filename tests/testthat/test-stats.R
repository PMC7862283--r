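test_that("Mann-Whitney matches hand-computed fixtures", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)

  r <- mannWhitney(c(1.2, 3.4, 5.6, 7.8), c(2.3, 4.5, 6.7, 8.9),
                   mode = "normal")
  expect_equal(r$U, 6)
  expect_equal(r$z, -2 / sqrt(12), tolerance = 1e-12)

  # identical multisets: U at null mean, z = 0
  r <- mannWhitney(c(2, 4, 4, 7), c(2, 4, 4, 7))
  expect_equal(r$U, 16 / 2)
  expect_equal(r$z, 0)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration, with ties", {
  set.seed(42)
  for (i in 1:60) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- randomTiedSample(na); b <- randomTiedSample(nb)
    expect_equal(mannWhitney(a, b, mode = "exact")$p, bruteMWExact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("normal-mode Mann-Whitney matches wilcox.test without continuity", {
  set.seed(7)
  for (i in 1:40) {
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1)) + 0.5
    mine <- mannWhitney(a, b, mode = "normal")
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches the hand rank-sum fixture and kruskal.test", {
  expect_equal(kruskalWallis(list(1:3, 4:6, 7:9))$H, 7.2, tolerance = 1e-12)
  expect_equal(kruskalWallis(list(c(3, 3, 3), c(3, 3, 3)))$H, 0)
  set.seed(11)
  for (i in 1:40) {
    g <- lapply(1:3, function(k) randomTiedSample(sample(3:8, 1)))
    mine <- kruskalWallis(g)
    ref <- kruskal.test(g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Dunn post hoc reproduces hand mean ranks and adjustment identities", {
  d <- dunnPosthoc(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(d$meanRankDiff[d$group1 == "a" & d$group2 == "c"], -6)
  # unadjusted vs bonferroni: p_bonf = min(1, 3 p) for 3 comparisons
  d0 <- dunnPosthoc(list(a = 1:3, b = 4:6, c = 7:9), adjust = "none")
  expect_equal(d$pAdj, pmin(1, 3 * d0$p))
  # two identical groups among three: their adjusted p ~ 1
  d2 <- dunnPosthoc(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 10, 11)))
  expect_gt(d2$pAdj[d2$group1 == "a" & d2$group2 == "b"], 0.99)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(10) + 1; c3 <- rnorm(6)
  f <- function(x) exp(2 * x) + 5
  expect_equal(mannWhitney(a, b, mode = "normal")$z,
               mannWhitney(f(a), f(b), mode = "normal")$z)
  expect_equal(kruskalWallis(list(a, b, c3))$H,
               kruskalWallis(list(f(a), f(b), f(c3)))$H)
})

test_that("two-sided p is symmetric under group-label swap", {
  set.seed(5)
  a <- randomTiedSample(9); b <- randomTiedSample(7)
  m1 <- mannWhitney(a, b, mode = "normal")
  m2 <- mannWhitney(b, a, mode = "normal")
  expect_equal(m1$z, -m2$z)
  expect_equal(m1$p, m2$p)
  e1 <- mannWhitney(a, b, mode = "exact")
  e2 <- mannWhitney(b, a, mode = "exact")
  expect_equal(e1$p, e2$p)
})

test_that("Kaplan-Meier matches the product-limit hand fixture and survfit", {
  km <- kaplanMeier(c(5, 10, 10, 20))
  expect_equal(km$surv, c(0.75, 0.25, 0))
  # no censoring: S equals 1 - empirical CDF
  tt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km2 <- kaplanMeier(tt)
  expect_equal(km2$surv,
               vapply(km2$time, function(u) mean(tt > u), numeric(1)))
  # all censored: S identically 1
  km3 <- kaplanMeier(c(5, 10), censored = c(TRUE, TRUE))
  expect_equal(nrow(km3), 0)
  expect_equal(kmSurvAt(km3, c(1, 100)), c(1, 1))
  set.seed(9)
  t4 <- sample(1:8, 30, replace = TRUE)
  c4 <- rbinom(30, 1, 0.3) == 1
  km4 <- kaplanMeier(t4, c4)
  sf <- survival::survfit(survival::Surv(t4, !c4) ~ 1)
  ref <- summary(sf, times = km4$time)
  expect_equal(km4$surv, ref$surv, tolerance = 1e-12)
})

test_that("log-rank matches the textbook oracle and survdiff", {
  lr0 <- logRank(rep(c(1, 5, 7), 2), rep(FALSE, 6), rep(c("A", "B"), 3))
  expect_equal(lr0$chisq, 0)
  t1 <- c(1, 2, 3); t2 <- c(10, 20, 30)
  mine <- logRank(c(t1, t2), rep(FALSE, 6), rep(c("A", "B"), each = 3))
  ref <- bruteLogRank2(t1, rep(FALSE, 3), t2, rep(FALSE, 3))
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-9)
  set.seed(13)
  for (i in 1:20) {
    tm <- sample(1:10, 24, replace = TRUE)
    cn <- rbinom(24, 1, 0.2) == 1
    g <- rep(c("A", "B", "C"), each = 8)
    if (all(cn)) next
    mine <- logRank(tm, cn, g)
    ref <- survival::survdiff(survival::Surv(tm, !cn) ~ g)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-9)
  }
})

test_that("log-rank p is null-calibrated when one group is split at random", {
  set.seed(17)
  base <- rexp(40) + 0.5
  ps <- vapply(1:200, function(i) {
    g <- sample(rep(c("A", "B"), each = 20))
    logRank(base, rep(FALSE, 40), g)$p
  }, numeric(1))
  # uniformity: rejection rate at 0.05 within binomial error over 200 draws
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("BH-FDR reproduces the step-up fixture and p.adjust decisions", {
  r <- bhFdr(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.02)
  expect_equal(bhFdr(rep(1, 5), 0.05)$nRejected, 0L)
  set.seed(19)
  for (i in 1:30) {
    p <- runif(50)^sample(1:3, 1)
    mine <- bhFdr(p, q = 0.05)
    expect_equal(mine$reject, p.adjust(p, "BH") <= 0.05)
  }
})

test_that("Sidak adjustment and the two-way ANOVA match car::Anova type II", {
  expect_equal(sidakAdjust(0.01, 4), 1 - 0.99^4)
  expect_equal(round(sidakAdjust(0.01, 4), 4), 0.0394)
  set.seed(23)
  for (bal in c(TRUE, FALSE)) {
    n <- if (bal) 4 else NA
    A <- rep(c("wt", "mut"), each = 16)
    B <- rep(rep(paste0("c", 1:4), each = 4), 2)
    if (!bal) { drop <- sample(32, 5); A <- A[-drop]; B <- B[-drop] }
    y <- rnorm(length(A)) + (A == "mut") * 0.8
    mine <- twoWayAnovaSidak(y, A, B)
    ref <- car::Anova(lm(y ~ a * b,
                         data.frame(y = y, a = factor(A), b = factor(B))),
                      type = 2)
    expect_equal(mine$anova$SS[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-9)
    expect_equal(mine$anova$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-9)
  }
})

test_that("two-way ANOVA flags zero-residual designs and planted effects", {
  A <- rep(c("a", "b"), each = 4)
  B <- rep(c("x", "y"), 4)
  out <- twoWayAnovaSidak(rep(2, 8), A, B)
  expect_true(out$degenerate)
  expect_true(all(is.na(out$anova$F[1:3])))
  # planted genotype main effect: genotype p small, interaction calibrated
  set.seed(29)
  pint <- vapply(1:100, function(i) {
    y <- rnorm(24) + rep(c(0, 1.5), each = 12)
    r <- twoWayAnovaSidak(rep(c(0, 1.5), each = 12) + rnorm(24),
                          rep(c("wt", "mut"), each = 12),
                          rep(rep(c("c1", "c2"), each = 6), 2))
    r$anova$p[r$anova$term == "interaction"]
  }, numeric(1))
  expect_lt(abs(mean(pint < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
  r <- twoWayAnovaSidak(rep(c(0, 2), each = 12) + rnorm(24, sd = 0.5),
                        rep(c("wt", "mut"), each = 12),
                        rep(rep(c("c1", "c2"), each = 6), 2))
  expect_lt(r$anova$p[1], 0.01)
})

test_that("statistical inputs are validated", {
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
  expect_error(kruskalWallis(list(1:3)), "two groups")
  expect_error(kruskalWallis(list(1:3, numeric(0))), "non-empty")
  expect_error(logRank(c(1, 2), c(TRUE, TRUE), c("a", "b")), "no events")
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
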