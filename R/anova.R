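#' Sidak adjustment for k independent comparisons
#'
#' @param p raw p values.
#' @param k number of comparisons in the family.
#' @return adjusted p values `1 - (1 - p)^k`.
#' @examples
#' sidakAdjust(0.01, 4)   # 0.0394...
#' @export
sidakAdjust <- function(p, k) 1 - (1 - p)^k

#' Two-way ANOVA with Sidak-adjusted genotype contrasts per condition
#'
#' Fits a two-factor linear model (factorA x factorB) and reports Type-II
#' sums of squares (each main effect adjusted for the other, the interaction
#' adjusted for both), which coincide with the classical balanced-design
#' decomposition when cell sizes are equal. Pairwise factor-A contrasts are
#' then computed within each level of factor B using the pooled residual
#' mean square, with Sidak adjustment over all contrasts in the family.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (>= 2 levels each); every cell must have
#'   at least one observation and the design >= 2 replicates per cell on
#'   average so the residual df is positive.
#' @return list: `anova` (term, df, SS, MS, F, p), `contrasts`
#'   (condition, group1, group2, estimate, t, p, pAdj), `degenerate`
#'   (TRUE when the residual SS is zero; F undefined and flagged).
#' @export
twoWayAnovaSidak <- function(values, factorA, factorB) {
  values <- as.numeric(values)
  A <- factor(factorA); B <- factor(factorB)
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need at least two levels")
  if (any(table(A, B) == 0)) stop("every factor cell must be non-empty")
  d <- data.frame(y = values, A = A, B = B)
  rssOf <- function(f) sum(stats::resid(stats::lm(f, data = d))^2)
  full <- stats::lm(y ~ A * B, data = d)
  rssFull <- sum(stats::resid(full)^2)
  rssAB <- rssOf(y ~ A + B)
  ssA <- rssOf(y ~ B) - rssAB
  ssB <- rssOf(y ~ A) - rssAB
  ssInt <- rssAB - rssFull
  dfA <- nlevels(A) - 1
  dfB <- nlevels(B) - 1
  dfInt <- dfA * dfB
  dfRes <- full$df.residual
  if (dfRes < 1) stop("no residual degrees of freedom")
  mse <- rssFull / dfRes
  degenerate <- mse <= .Machine$double.eps * max(1, stats::var(values))
  row <- function(term, ss, df) {
    f <- if (degenerate) NA_real_ else (ss / df) / mse
    data.frame(term = term, df = df, SS = ss, MS = ss / df, F = f,
               p = if (degenerate) NA_real_ else
                 stats::pf(f, df, dfRes, lower.tail = FALSE))
  }
  tab <- rbind(row("factorA", ssA, dfA), row("factorB", ssB, dfB),
               row("interaction", ssInt, dfInt),
               data.frame(term = "residual", df = dfRes, SS = rssFull,
                          MS = mse, F = NA_real_, p = NA_real_))
  ## per-condition pairwise factor-A contrasts, pooled-MSE t tests
  pairsA <- utils::combn(levels(A), 2)
  k <- nlevels(B) * ncol(pairsA)
  cons <- list()
  for (b in levels(B)) for (ii in seq_len(ncol(pairsA))) {
    a1 <- pairsA[1, ii]; a2 <- pairsA[2, ii]
    y1 <- values[A == a1 & B == b]
    y2 <- values[A == a2 & B == b]
    est <- mean(y1) - mean(y2)
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    tv <- if (degenerate || se == 0) NA_real_ else est / se
    p <- if (is.na(tv)) NA_real_ else
      2 * stats::pt(-abs(tv), dfRes)
    cons[[length(cons) + 1L]] <-
      data.frame(condition = b, group1 = a1, group2 = a2, estimate = est,
                 t = tv, p = p, pAdj = sidakAdjust(p, k))
  }
  list(anova = tab, contrasts = do.call(rbind, cons),
       degenerate = degenerate)
}
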