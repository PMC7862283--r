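## Rank-based tests used throughout the pipeline. Implemented from their
## defining formulas with midranks and tie-corrected variances, because
## emergence times sit on a 5-min grid and voxel ratios are discretized, so
## ties are structural. The voxel map code calls the same kernels.

## sum of (t^3 - t) over tie groups of the pooled sample
tieSum <- function(x) {
  t <- rle(sort(x))$lengths
  sum(t^3 - t)
}

mwCore <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  ts <- tieSum(pooled)
  sigma2 <- na * nb / 12 * ((N + 1) - ts / (N * (N - 1)))
  list(U = U, mu = na * nb / 2, sigma2 = sigma2, ranks = r, ties = ts > 0)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with midranks for ties. In `"normal"` mode the
#' U statistic is referred to its tie-corrected normal approximation,
#' `z = (U - n_a n_b / 2) / sigma` (continuity correction off by default,
#' matching the Z-score map definition). In `"exact"` mode the two-sided
#' p value is computed by full enumeration of all group assignments of the
#' pooled midranks (permutation-exact, so ties are handled correctly);
#' `"auto"` uses exact enumeration when `n_a + n_b <= 12`.
#'
#' @param a,b numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param continuity apply a 0.5 continuity correction in normal mode.
#' @return a `rankTestResult` list: `U` (for sample `a`), `z`, `p`,
#'   `method`, `tieCorrected`, `nPerGroup`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p   # 0.1
#' @export
mannWhitney <- function(a, b, mode = c("auto", "exact", "normal"),
                        continuity = FALSE) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  na <- length(a); nb <- length(b); N <- na + nb
  cc <- mwCore(a, b)
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  dev <- cc$U - cc$mu
  z <- if (cc$sigma2 > 0) {
    adj <- if (continuity) -sign(dev) * 0.5 else 0
    (dev + adj) / sqrt(cc$sigma2)
  } else 0
  if (mode == "exact") {
    picks <- utils::combn(N, na)
    Us <- colSums(matrix(cc$ranks[picks], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= cc$U), mean(Us >= cc$U)))
  } else {
    p <- if (cc$sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  structure(list(U = cc$U, z = z, p = p, method = mode,
                 tieCorrected = cc$ties, nPerGroup = c(na, nb)),
            class = "rankTestResult")
}

#' @export
print.rankTestResult <- function(x, ...) {
  st <- intersect(c("U", "H"), names(x))[1]
  cat(sprintf("%s = %.4g, z = %.4g, p = %.4g (n = %s%s)\n", st, x[[st]],
              if (!is.null(x$z)) x$z else NA, x$p,
              paste(x$nPerGroup, collapse = "/"),
              if (isTRUE(x$tieCorrected)) ", tie-corrected" else ""))
  invisible(x)
}

#' Kruskal-Wallis rank ANOVA
#'
#' Tie-corrected H statistic over `k >= 2` groups with a chi-square
#' (k - 1 df) reference distribution.
#'
#' @param groups list of numeric samples (all non-empty).
#' @return a `rankTestResult` list: `H`, `p`, `df`, `meanRanks`,
#'   `tieCorrected`, `nPerGroup`.
#' @examples
#' kruskalWallis(list(1:3, 4:6, 7:9))$H   # 7.2
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  n <- lengths(groups)
  if (any(n == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stop("samples must not contain NA")
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), n)
  Rsum <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ts <- tieSum(pooled)
  C <- 1 - ts / (N^3 - N)
  H <- if (C > 0) H / C else 0
  df <- length(groups) - 1
  structure(list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE),
                 df = df, meanRanks = as.numeric(Rsum / n),
                 tieCorrected = ts > 0, nPerGroup = as.integer(n)),
            class = "rankTestResult")
}

#' Dunn's post hoc multiple comparisons
#'
#' Pairwise mean-rank differences after a Kruskal-Wallis test, with the
#' tie-corrected standard error
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12 (N-1))) (1/n_i + 1/n_j))` and a
#' two-sided normal p value, adjusted for `choose(k, 2)` comparisons.
#'
#' @param groups named or unnamed list of numeric samples.
#' @param adjust `"bonferroni"` (default), `"sidak"` or `"none"`.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `meanRankDiff` (group1 minus group2), `z`, `p`, `pAdj`.
#' @export
dunnPosthoc <- function(groups, adjust = c("bonferroni", "sidak", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  n <- lengths(groups)
  if (any(n == 0)) stop("all groups must be non-empty")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), n)
  mr <- tapply(r, g, mean)
  ts <- tieSum(pooled)
  v <- N * (N + 1) / 12 - ts / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  k <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(k), function(ii) {
    i <- pairs[1, ii]; j <- pairs[2, ii]
    se <- sqrt(v * (1 / n[i] + 1 / n[j]))
    d <- mr[i] - mr[j]
    z <- if (se > 0) d / se else 0
    data.frame(group1 = nm[i], group2 = nm[j], meanRankDiff = as.numeric(d),
               z = as.numeric(z), p = 2 * stats::pnorm(-abs(z)))
  }))
  out$pAdj <- switch(adjust,
    bonferroni = pmin(1, out$p * k),
    sidak = 1 - (1 - out$p)^k,
    none = out$p)
  rownames(out) <- NULL
  out
}
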