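# Internal helpers shared across modules.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Generators take an explicit seed and must
# not disturb global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coerce to a 3D array (2D input becomes a single-slice volume)
as_vol <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop_gq("expected a 2D or 3D array")
  x
}

#' Otsu threshold of an image histogram
#'
#' Resolves the threshold that maximizes the between-class variance over a
#' 256-bin histogram. For 8-bit data (`bins = "u8"`, the default when all
#' values are integers in \[0, 255\]) the bins are the 256 intensity levels and
#' the returned threshold is an intensity; foreground is `value > threshold`
#' (strict). For arbitrary numeric data the 256 bins span the value range, so
#' the threshold is relative to the range and invariant to affine rescaling.
#'
#' Ties (several thresholds reaching the maximal between-class variance) are
#' broken toward the smallest threshold.
#'
#' @param x numeric array of intensities.
#' @return threshold on the scale of `x`, or `NA` if the image is constant.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (rng[1] == rng[2]) return(NA_real_)
  u8 <- all(v >= 0 & v <= 255 & v == floor(v))
  if (u8) {
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    mids <- 0:255
    edges <- 0:255           # threshold candidates: t in 0..254, class2 = > t
  } else {
    breaks <- seq(rng[1], rng[2], length.out = 257L)
    idx <- pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L), 256L)
    counts <- tabulate(idx, nbins = 256L)
    mids <- (breaks[-257] + breaks[-1]) / 2
    edges <- breaks[-1]      # upper edge of each bin
  }
  n <- sum(counts)
  p <- counts / n
  omega <- cumsum(p)                    # P(class1) for threshold at bin k
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  k <- 1:255                            # split after bin k
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- (mu_t * omega[k] - mu[k])^2 / denom
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which.max(sigma_b)            # smallest maximizer
  as.numeric(edges[best])
}
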