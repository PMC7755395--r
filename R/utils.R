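#' @importFrom stats fft rnorm rpois runif median quantile sd var cor cor.test
#'   wilcox.test t.test fisher.test p.adjust acf coef lm plogis qlogis
#'   setNames convolve aggregate
#' @importFrom utils read.table write.table combn
NULL

# single source of truth for derived per-stage seeds: a fixed affine counter
# scheme keeps every derived seed inside the 32-bit integer range
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 9973) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_ts <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, what) {
  if (any(!is.finite(x))) stop_ts(what, " contains non-finite values")
  invisible(x)
}

# reflect a vector into [lo, hi] (triangle-wave folding); used for the bounded
# random walk of oscillation frequency
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

row_max <- function(m) {
  # pmax over columns; faster and NA-safe compared to apply(m, 1, max)
  out <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2L:ncol(m)) out <- pmax(out, m[, j])
  out
}

# Euclidean cross-distance between rows of two n x 3 coordinate matrices
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
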