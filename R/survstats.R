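## Failure-time machinery for the emergence analyses: product-limit survival
## estimate and k-group log-rank test from the observed-vs-expected events
## definition. Ties are expected (checkpoint grid) and handled by the
## at-risk-set formulation.

#' Kaplan-Meier product-limit estimator
#'
#' Estimates S(t), the probability of not yet having emerged (responded) by
#' time t. Right-censored observations leave the risk set at their censoring
#' time without contributing an event.
#'
#' @param times positive event or censoring times.
#' @param censored logical; TRUE marks a right-censored record.
#' @return data.frame with one row per distinct event time: `time`,
#'   `nRisk`, `nEvent`, `nCensored` (censorings in `(previous, time]`),
#'   `surv`. With no events the estimate is identically 1 (zero rows).
#' @examples
#' kaplanMeier(c(5, 10, 10, 20))$surv   # 0.75 0.25 0.00
#' @export
kaplanMeier <- function(times, censored = rep(FALSE, length(times))) {
  times <- as.numeric(times)
  censored <- as.logical(censored)
  if (length(times) != length(censored))
    stop("times and censored must have equal length")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive and finite")
  ut <- sort(unique(times[!censored]))
  if (!length(ut))
    return(data.frame(time = numeric(0), nRisk = integer(0),
                      nEvent = integer(0), nCensored = integer(0),
                      surv = numeric(0)))
  s <- 1
  prev <- -Inf
  out <- lapply(ut, function(tt) {
    nRisk <- sum(times >= tt)
    nEvent <- sum(times == tt & !censored)
    nCens <- sum(times > prev & times <= tt & censored)
    prev <<- tt
    s <<- s * (1 - nEvent / nRisk)
    data.frame(time = tt, nRisk = nRisk, nEvent = nEvent,
               nCensored = nCens, surv = s)
  })
  do.call(rbind, out)
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km data.frame from [kaplanMeier()].
#' @param t times at which to evaluate the right-continuous step function.
#' @return numeric vector of survival probabilities.
#' @export
kmSurvAt <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test for k groups
#'
#' Standard observed-vs-expected events statistic over the pooled distinct
#' event times, using the hypergeometric variance-covariance of the per-group
#' event counts; the chi-square statistic is formed on the first k - 1
#' groups with k - 1 degrees of freedom.
#'
#' @param times positive event/censoring times.
#' @param censored logical censoring flags.
#' @param group group labels (>= 2 levels).
#' @return list: `chisq`, `df`, `p`, and a per-group table with `n`,
#'   `observed`, `expected`.
#' @export
logRank <- function(times, censored, group) {
  times <- as.numeric(times)
  censored <- as.logical(censored)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (length(unique(c(length(times), length(censored), length(group)))) != 1)
    stop("times, censored and group must have equal length")
  if (all(censored)) stop("no events: log-rank test undefined")
  k <- nlevels(group)
  ut <- sort(unique(times[!censored]))
  O <- tapply(!censored, group, sum)
  O[is.na(O)] <- 0
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in ut) {
    atRisk <- times >= tt
    nj <- sum(atRisk)
    dj <- sum(times == tt & !censored)
    ngj <- tapply(atRisk, group, sum)
    ngj[is.na(ngj)] <- 0
    E <- E + dj * ngj / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj - 1)
      for (gi in seq_len(k)) for (gj in seq_len(k)) {
        d <- if (gi == gj) 1 else 0
        V[gi, gj] <- V[gi, gj] +
          f * (ngj[gi] / nj) * (d - ngj[gj] / nj)
      }
    }
  }
  d <- (as.numeric(O) - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(d) < 1e-12)) 0 else {
    ## eigen-based pseudoinverse: V can be singular when a group's risk
    ## set never overlaps an event time
    ev <- eigen(Vs, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    if (!any(keep)) 0 else {
      vi <- ev$vectors[, keep, drop = FALSE]
      as.numeric(t(d) %*% vi %*% ((t(vi) %*% d) / ev$values[keep]))
    }
  }
  df <- k - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(group = levels(group),
                          n = as.integer(table(group)),
                          observed = as.numeric(O), expected = E))
}
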