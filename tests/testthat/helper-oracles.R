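# Independent Dunn oracle: mean ranks computed by pairwise counting
# (r_i = 1 + #{x_j < x_i} + 0.5 #{j != i, x_j == x_i}) rather than rank(),
# variance from the tie-group definition on explicit run lengths.
bruteDunn <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- vapply(seq_len(N), function(i)
    1 + sum(pooled < pooled[i]) + 0.5 * sum(pooled == pooled[i]) - 0.5,
    numeric(1))
  g <- rep(seq_along(groups), lengths(groups))
  mr <- vapply(seq_along(groups), function(k) mean(r[g == k]), numeric(1))
  ts <- 0
  for (u in unique(pooled)) {
    t <- sum(pooled == u)
    ts <- ts + t^3 - t
  }
  v <- N * (N + 1) / 12 - ts / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  out <- NULL
  for (ii in seq_len(ncol(pairs))) {
    i <- pairs[1, ii]; j <- pairs[2, ii]
    se <- sqrt(v * (1 / sum(g == i) + 1 / sum(g == j)))
    z <- if (se > 0) (mr[i] - mr[j]) / se else 0
    out <- rbind(out, c(diff = mr[i] - mr[j], z = z,
                        p = 2 * pnorm(-abs(z))))
  }
  out
}

# product-limit estimate computed by sequential probability multiplication
# over a time grid (independent of the package's risk-table construction)
bruteKM <- function(times, censored) {
  ut <- sort(unique(times[!censored]))
  s <- numeric(length(ut))
  cur <- 1
  for (k in seq_along(ut)) {
    atRisk <- sum(times >= ut[k])
    ev <- sum(times == ut[k] & !censored)
    cur <- cur * (atRisk - ev) / atRisk
    s[k] <- cur
  }
  list(time = ut, surv = s)
}
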