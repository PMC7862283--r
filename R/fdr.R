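#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure at level `q`: with sorted p values `p_(1) <= ... <=
#' p_(m)`, find the largest `i` with `p_(i) <= q i / m`; all p values up to
#' `p_(i)` are rejected and `p_(i)` is returned as the data-dependent
#' significance threshold.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param q target false discovery rate.
#' @return list: `reject` (logical mask aligned with `p`), `threshold`
#'   (largest p passing, `NA` if none), `nRejected`.
#' @examples
#' bhFdr(c(0.001, 0.01, 0.02, 0.9), q = 0.05)$reject  # T T T F
#' @export
bhFdr <- function(p, q = 0.05) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= q * seq_len(m) / m)
  if (!length(pass))
    return(list(reject = rep(FALSE, m), threshold = NA_real_,
                nRejected = 0L))
  thr <- ps[max(pass)]
  list(reject = p <= thr, threshold = thr, nRejected = sum(p <= thr))
}
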