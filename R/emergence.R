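#' Convert a checkpoint response table into emergence records
#'
#' After anesthetic washout, larvae are probed with a vibration stimulus at
#' fixed intervals; the emergence time is the time of the first positive
#' checkpoint (first-passage definition: later response lapses are
#' ignored). Larvae that never respond are right-censored at the last
#' checkpoint.
#'
#' @param checks logical matrix or data.frame, larvae x checkpoints, in
#'   checkpoint order (column `j` = response at `j * interval` minutes).
#' @param interval checkpoint spacing, minutes.
#' @param meta optional data.frame of per-larva covariates (genotype,
#'   anesthetic, exposure, ...) bound onto the records.
#' @return data.frame of class `emergenceRecords`: `larvaId`,
#'   `emergenceTime` (minutes, on the grid), `censored`, plus `meta`
#'   columns.
#' @export
emergenceTimes <- function(checks, interval = 5, meta = NULL) {
  checks <- as.matrix(checks)
  if (!nrow(checks) || !ncol(checks)) stop("empty checkpoint table")
  mode(checks) <- "logical"
  checkPositive(interval, "interval")
  first <- apply(checks, 1, function(r) {
    i <- which(r)
    if (length(i)) i[1] else NA_integer_
  })
  censored <- is.na(first)
  tt <- ifelse(censored, ncol(checks) * interval, first * interval)
  ids <- rownames(checks)
  if (is.null(ids)) ids <- paste0("larva", seq_len(nrow(checks)))
  out <- data.frame(larvaId = ids, emergenceTime = tt, censored = censored)
  if (!is.null(meta)) {
    if (nrow(as.data.frame(meta)) != nrow(checks))
      stop("meta must have one row per larva")
    out <- cbind(out, as.data.frame(meta))
  }
  rownames(out) <- NULL
  class(out) <- c("emergenceRecords", "data.frame")
  out
}

#' Compare emergence times across groups
#'
#' Runs the full group comparison on emergence records: Kruskal-Wallis with
#' Dunn's multiple comparisons on the observed (uncensored) times — rank
#' tests assume observed event times, so censored records are excluded with
#' a warning when a group loses all its members — and Kaplan-Meier curves
#' with a log-rank test on all records (censoring handled by the risk
#' sets).
#'
#' @param records an [emergenceTimes()] or [simulateEmergenceTimes()]
#'   data.frame with `emergenceTime` and `censored` columns.
#' @param grouping name of the grouping column (default `"genotype"`).
#' @param adjust Dunn adjustment, see [dunnPosthoc()].
#' @return list: `kruskalWallis`, `dunn` (pairwise mean-rank differences
#'   and adjusted p), `km` (per-group product-limit estimates),
#'   `logRank`, and `summary` — a one-row-per-pair report in an H /
#'   p / rank / p layout.
#' @export
compareEmergence <- function(records, grouping = "genotype",
                             adjust = "bonferroni") {
  if (!grouping %in% names(records))
    stop(sprintf("no '%s' column in records", grouping))
  g <- factor(records[[grouping]])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("each group needs at least two records")
  tt <- records$emergenceTime
  cens <- records$censored
  ## rank tests on observed times only
  obs <- !cens
  keepLev <- levels(g)[tapply(obs, g, sum) > 0]
  if (length(keepLev) < nlevels(g))
    warning(sprintf(
      "group(s) %s have only censored records; excluded from KW/Dunn",
      paste(setdiff(levels(g), keepLev), collapse = ", ")))
  groupsObs <- split(tt[obs], droplevels(g[obs]))
  kw <- if (length(groupsObs) >= 2) kruskalWallis(groupsObs) else NULL
  dunn <- if (length(groupsObs) >= 2)
    dunnPosthoc(groupsObs, adjust = adjust) else NULL
  km <- lapply(split(seq_along(tt), g), function(i)
    kaplanMeier(tt[i], cens[i]))
  lr <- logRank(tt, cens, g)
  summ <- if (!is.null(dunn))
    data.frame(H = kw$H, kwP = kw$p, comparison = paste(dunn$group1, "vs",
                                                        dunn$group2),
               meanRankDiff = dunn$meanRankDiff, dunnP = dunn$pAdj)
  else NULL
  list(kruskalWallis = kw, dunn = dunn, km = km, logRank = lr,
       summary = summ)
}
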