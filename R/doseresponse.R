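#' Stimulus schedule of the three-endpoint behavioral assay
#'
#' One cycle is 30 s lights-on, then lights-off with a tap delivered 20 s
#' into the dark period, then 10 s more darkness (60 s per cycle); the cycle
#' repeats `nCycles` times and responses are scored in the listed cycles.
#' Endpoint windows within a cycle: spontaneous swimming during lights-on
#' (0-30 s), visual-motor response in the `responseWindow` after the dark
#' transition (30 s), tap response in the `responseWindow` after the tap
#' (50 s).
#'
#' @param lightsOn,dark1,dark2 segment durations, s.
#' @param nCycles number of cycles.
#' @param scoredCycles cycles whose responses are scored.
#' @param responseWindow scoring window after each stimulus, s.
#' @return list of class `stimulusSchedule`.
#' @export
stimulusSchedule <- function(lightsOn = 30, dark1 = 20, dark2 = 10,
                             nCycles = 5, scoredCycles = c(4, 5),
                             responseWindow = 5) {
  cycle <- lightsOn + dark1 + dark2
  if (responseWindow > dark1)
    stop("response windows would overlap within a cycle")
  structure(list(lightsOn = lightsOn, dark1 = dark1, dark2 = dark2,
                 cycleLength = cycle, nCycles = nCycles,
                 scoredCycles = scoredCycles,
                 responseWindow = responseWindow,
                 total = cycle * nCycles),
            class = "stimulusSchedule")
}

#' Score the three behavioral endpoints from movement traces
#'
#' `activity` is a larva x second logical matrix (moved during that 1-s
#' bin). Per scored cycle, a larva responds to the light endpoint if it
#' moves at any time during lights-on, to the VMR endpoint if it moves in
#' the `responseWindow` after the dark transition, and to the tap endpoint
#' if it moves in the `responseWindow` after the tap. Counts are pooled
#' over scored cycles: by default a larva counts as responding if it
#' responds in any scored cycle (`pool = "any"`); `pool = "per-cycle"`
#' counts larva-cycle pairs instead.
#'
#' @param activity logical matrix, larvae x seconds, covering the protocol.
#' @param schedule a [stimulusSchedule()].
#' @param pool `"any"` or `"per-cycle"`.
#' @return data.frame: `endpoint` (light, vmr, tap), `responding`,
#'   `total`, `proportion`.
#' @export
scoreEndpoints <- function(activity, schedule = stimulusSchedule(),
                           pool = c("any", "per-cycle")) {
  pool <- match.arg(pool)
  activity <- as.matrix(activity)
  if (ncol(activity) < schedule$total)
    stop(sprintf("trace covers %d s but the protocol needs %d s",
                 ncol(activity), schedule$total))
  nL <- nrow(activity)
  winIdx <- function(cyc, from, len) {
    t0 <- (cyc - 1) * schedule$cycleLength + from
    seq.int(t0 + 1L, t0 + len)           # 1-based second bins
  }
  resp <- list(light = NULL, vmr = NULL, tap = NULL)
  for (cyc in schedule$scoredCycles) {
    win <- list(
      light = winIdx(cyc, 0, schedule$lightsOn),
      vmr = winIdx(cyc, schedule$lightsOn, schedule$responseWindow),
      tap = winIdx(cyc, schedule$lightsOn + schedule$dark1,
                   schedule$responseWindow))
    for (ep in names(win)) {
      r <- rowSums(activity[, win[[ep]], drop = FALSE]) > 0
      resp[[ep]] <- cbind(resp[[ep]], r)
    }
  }
  out <- lapply(names(resp), function(ep) {
    m <- resp[[ep]]
    if (pool == "any") {
      r <- sum(rowSums(m) > 0); tot <- nL
    } else {
      r <- sum(m); tot <- length(m)
    }
    data.frame(endpoint = ep, responding = r, total = tot,
               proportion = r / tot)
  })
  do.call(rbind, out)
}

#' Normalize a dose-response panel to its no-anesthetic baseline
#'
#' Divides each endpoint's proportions by the corresponding baseline
#' proportion and clips to \[0, 1\], so the fitted 4PL asymptotes stay
#' interpretable as fractions of baseline responsiveness.
#'
#' @param proportions numeric vector (or matrix with endpoints in columns).
#' @param baseline baseline proportion(s), > 0, recycled across rows.
#' @return normalized values, clipped to \[0, 1\].
#' @export
normalizePanel <- function(proportions, baseline) {
  if (any(!is.finite(baseline) | baseline <= 0)) {
    bad <- which(!is.finite(baseline) | baseline <= 0)
    nm <- names(baseline)[bad]
    stop(sprintf("zero or invalid baseline for endpoint %s",
                 paste(if (is.null(nm)) bad else nm, collapse = ", ")))
  }
  if (is.matrix(proportions))
    pmin(1, pmax(0, sweep(proportions, 2, baseline, "/")))
  else pmin(1, pmax(0, proportions / baseline))
}

#' Fit a constrained four-parameter logistic dose-response curve
#'
#' Bounded least-squares fit of [fourPL()] to proportions over doses using
#' the Levenberg-Marquardt algorithm. "Constraining the Hill slope" bounds
#' `hill` inside `hillBounds` (default `[-3, -0.5]`, a descending curve).
#' When the responses are essentially flat the fit is degenerate: the
#' asymptotes collapse and the EC50 is unidentifiable (returned as NA,
#' flagged).
#'
#' @param doses positive doses (>= 4 distinct values).
#' @param proportions observed proportions, one per dose.
#' @param constrainHill bound the Hill slope.
#' @param hillBounds length-2 bounds for `hill` when constrained.
#' @param weights optional least-squares weights (e.g. binomial
#'   `n / (p(1-p))`).
#' @param flatTol response range below which the fit is declared
#'   degenerate.
#' @return list of class `fit4PL`: `top`, `bottom`, `logEC50`, `hill`,
#'   `ec50`, `rss`, `fitted`, `converged`, `degenerate`.
#' @export
fit4PL <- function(doses, proportions, constrainHill = TRUE,
                   hillBounds = c(-3, -0.5), weights = NULL,
                   flatTol = 0.05) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (length(doses) != length(proportions))
    stop("doses and proportions must have equal length")
  o <- order(doses)                     # fit is invariant to row order
  d <- doses[o]; y <- proportions[o]
  w <- if (is.null(weights)) rep(1, length(d)) else weights[o]
  if (diff(range(y)) < flatTol) {
    out <- list(top = mean(y), bottom = mean(y), logEC50 = NA_real_,
                hill = NA_real_, ec50 = NA_real_,
                rss = sum(w * (y - mean(y))^2),
                fitted = rep(mean(y), length(y))[order(o)],
                converged = TRUE, degenerate = TRUE)
    class(out) <- "fit4PL"
    return(out)
  }
  ld <- log10(d)
  ## start values: asymptotes from the data, EC50 from the mid crossing
  mid <- (max(y) + min(y)) / 2
  cross <- which(diff(sign(y - mid)) != 0)
  lec0 <- if (length(cross)) {
    i <- cross[1]
    ld[i] + (mid - y[i]) * diff(ld[i + 0:1]) / diff(y[i + 0:1])
  } else stats::median(ld)
  hb <- if (constrainHill) sort(hillBounds) else c(-20, 20)
  ## multi-start over Hill slope and EC50 guesses: steep noiseless curves
  ## can give a singular gradient from a single unlucky start
  h0s <- unique(pmin(pmax(c(-1, -0.6, -1.8, -2.8), hb[1]), hb[2]))
  l0s <- unique(c(lec0, stats::median(ld)))
  fit <- NULL
  lastErr <- NULL
  for (l0 in l0s) for (h0 in h0s) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourPL(d, top, bottom, logEC50, hill),
        start = list(top = max(y), bottom = min(y), logEC50 = l0,
                     hill = h0),
        lower = c(0, 0, min(ld) - 3, hb[1]),
        upper = c(1.5, 1, max(ld) + 3, hb[2]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { lastErr <<- conditionMessage(e); NULL })
    if (!is.null(cand) &&
        (is.null(fit) || sum(w * stats::resid(cand)^2) <
           sum(w * stats::resid(fit)^2)))
      fit <- cand
  }
  if (is.null(fit))
    stop(sprintf("4PL fit failed to converge: %s", lastErr), call. = FALSE)
  cf <- stats::coef(fit)
  out <- list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
              logEC50 = unname(cf["logEC50"]), hill = unname(cf["hill"]),
              ec50 = 10^unname(cf["logEC50"]),
              rss = sum(w * stats::resid(fit)^2),
              fitted = stats::fitted(fit)[order(o)],
              converged = TRUE, degenerate = FALSE)
  class(out) <- "fit4PL"
  out
}

#' @export
print.fit4PL <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("4PL fit: degenerate (flat response ~ %.3f); EC50 unidentifiable\n",
                x$top))
  else
    cat(sprintf("4PL fit: top=%.3f bottom=%.3f EC50=%.3g hill=%.2f rss=%.3g\n",
                x$top, x$bottom, x$ec50, x$hill, x$rss))
  invisible(x)
}
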