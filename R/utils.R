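#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators are pure functions of
#' `(parameters, seed)` and never perturb the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## single positive finite scalar check used by parameter constructors
checkPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Discrete Gaussian kernel
#'
#' Normalized 1-D Gaussian kernel sampled on integer offsets, truncated at
#' `radius` (default 6 sigma, where the discarded tail mass is negligible).
#'
#' @param sigma standard deviation in pixels.
#' @param radius half-width in pixels; default `ceiling(6 * sigma)`.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @keywords internal
gaussKernel <- function(sigma, radius = ceiling(6 * sigma)) {
  checkPositive(sigma, "sigma")
  off <- seq.int(-radius, radius)
  k <- exp(-off^2 / (2 * sigma^2))
  k / sum(k)
}

## 1-D convolution of matrix columns (along = 1) or rows (along = 2) with a
## symmetric kernel; borders renormalized over the in-range kernel support so
## constant inputs stay constant everywhere.
convolveRenorm <- function(m, k, along = 1) {
  r <- (length(k) - 1L) %/% 2L
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  n <- if (along == 1) nrow(m) else ncol(m)
  for (j in seq.int(-r, r)) {
    w <- k[j + r + 1L]
    src <- seq_len(n) + j
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (along == 1) {
      num[ok, ] <- num[ok, ] + w * m[src[ok], ]
      den[ok, ] <- den[ok, ] + w
    } else {
      num[, ok] <- num[, ok] + w * m[, src[ok]]
      den[, ok] <- den[, ok] + w
    }
  }
  num / den
}

#' 2-D Gaussian smoothing of a matrix
#'
#' Separable Gaussian filter with border renormalization: away from borders
#' the impulse response equals the normalized discrete Gaussian kernel, and a
#' constant image is returned unchanged (mean preservation).
#'
#' @param m numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` returns `m`.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussSmooth2D <- function(m, sigma) {
  stopifnot(is.matrix(m))
  if (sigma == 0) return(m)
  k <- gaussKernel(sigma)
  convolveRenorm(convolveRenorm(m, k, along = 1), k, along = 2)
}
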