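#' Inverse-distance spatial weight matrix
#'
#' `W_ij = 1 / d_ij` for `i != j`, zero diagonal — the standard weight choice
#' for Moran statistics on parcellated cortical maps, with `d` the average
#' geodesic (here great-circle) distance between parcels.
#'
#' @param distmat Symmetric distance matrix, zero diagonal, positive
#'   off-diagonal entries.
#' @return A symmetric non-negative matrix of class `matrix`.
#' @export
inverse_distance_weights <- function(distmat) {
  distmat <- as.matrix(distmat)
  if (!isTRUE(all.equal(distmat, t(distmat))))
    stop_ts("distance matrix must be symmetric")
  if (any(diag(distmat) != 0)) stop_ts("distance matrix diagonal must be zero")
  off <- distmat[upper.tri(distmat)]
  if (any(off <= 0))
    stop_ts("zero or negative off-diagonal distance (duplicate parcels?)")
  W <- 1 / distmat
  diag(W) <- 0
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / sum(W)) * (z' W z) / (z' z)` with `z` the centered map values.
#'
#' @param values Numeric vector (or a [parcel_map()]).
#' @param W Spatial weight matrix (n x n, symmetric, zero diagonal).
#' @return Scalar Moran's I.
#' @export
moran_I <- function(values, W) {
  if (inherits(values, "parcel_map")) values <- values$values
  n <- length(values)
  stopifnot(nrow(W) == n, ncol(W) == n)
  z <- values - mean(values)
  szz <- sum(z^2)
  if (szz == 0) stop_ts("Moran's I undefined for a zero-variance map")
  (n / sum(W)) * as.numeric(crossprod(z, W %*% z)) / szz
}

# eigenbasis of the doubly centered weight matrix, excluding the constant
# direction; cached on the weight matrix so repeated null draws are cheap
moran_eigenbasis <- function(W) {
  n <- nrow(W)
  H <- diag(n) - matrix(1 / n, n, n)
  Wc <- H %*% W %*% H
  Wc <- (Wc + t(Wc)) / 2
  e <- eigen(Wc, symmetric = TRUE)
  # the constant vector is an eigenvector with eigenvalue 0; exclude the
  # basis column with the largest overlap with it
  overlap <- abs(colSums(e$vectors)) / sqrt(n)
  iconst <- which.max(overlap)
  dropped <- sum(abs(e$values[-iconst]) < max(abs(e$values)) * 1e-12)
  if (dropped > 0)
    message(sprintf("moran eigenbasis: %d near-zero eigenvalue(s) retained in basis",
                    dropped))
  list(vectors = e$vectors[, -iconst, drop = FALSE],
       values = e$values[-iconst])
}

#' Moran spectral randomization null maps
#'
#' Generates spatial-autocorrelation-preserving surrogate maps: the centered
#' map is expressed in the eigenvector basis of the doubly centered weight
#' matrix (the Moran spectral basis), and each null randomizes the signs of
#' the spectral coefficients (the singleton procedure). Every null exactly
#' preserves the map's mean, variance, and Moran's I, while being
#' uncorrelated with the empirical map in expectation. A constant
#' (zero-variance) map passes through unchanged.
#'
#' @param map A [parcel_map()] or numeric vector; must have no invalid
#'   parcels within the analysis set.
#' @param W Spatial weight matrix matching the map's dimension.
#' @param n_null Number of null maps.
#' @param seed Integer seed; identical seeds give bit-identical ensembles.
#' @param procedure Null-generation procedure; only `"singleton"` is
#'   implemented (tag retained so alternative engines can be added).
#' @return An object of class `null_ensemble`: list with `nulls`
#'   (n_null x n matrix), `seed`, `method`, `n_null`.
#' @export
msr_nulls <- function(map, W, n_null = 1000L, seed = 1,
                      procedure = c("singleton")) {
  procedure <- match.arg(procedure)
  x <- if (inherits(map, "parcel_map")) map$values else as.numeric(map)
  if (anyNA(x)) stop_ts("map has invalid parcels; restrict the analysis set first")
  n <- length(x)
  stopifnot(nrow(W) == n)
  mu <- mean(x)
  z <- x - mu
  if (sum(z^2) == 0) {
    nulls <- matrix(mu, n_null, n)
  } else {
    basis <- moran_eigenbasis(W)
    r <- as.numeric(crossprod(basis$vectors, z))
    signs <- with_seed_(seed,
                        matrix(sample(c(-1, 1), length(r) * n_null,
                                      replace = TRUE), length(r), n_null))
    nulls <- t(basis$vectors %*% (signs * r)) + mu
  }
  structure(list(nulls = nulls, seed = seed,
                 method = paste0("msr_", procedure),
                 n_null = as.integer(n_null)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d nulls x %d parcels (%s, seed %s)\n",
              nrow(x$nulls), ncol(x$nulls), x$method, format(x$seed)))
  invisible(x)
}

map_values_pair <- function(map_x, map_y) {
  vx <- if (inherits(map_x, "parcel_map")) map_x$values else as.numeric(map_x)
  vy <- if (inherits(map_y, "parcel_map")) map_y$values else as.numeric(map_y)
  if (length(vx) != length(vy)) stop_ts("maps must share a parcel set")
  keep <- is.finite(vx) & is.finite(vy)
  list(x = vx[keep], y = vy[keep], keep = keep)
}

#' Spatial-autocorrelation-corrected Spearman correlation
#'
#' Correlates two parcel maps with Spearman's rho and computes a two-tailed
#' p-value against the null distribution of rho obtained by correlating each
#' SA-preserving null of `map_x` with `map_y`:
#' `p = (1 + #{|rho_null| >= |rho|}) / (n_null + 1)`. The p-value is bounded
#' below by `1/(n_null + 1)` and never exactly zero. Invalid parcels are
#' excluded pairwise.
#'
#' @param map_x,map_y [parcel_map()]s or numeric vectors on one parcel set.
#' @param nulls_of_x A [msr_nulls()] ensemble generated from `map_x`.
#' @return An object of class `sa_cor`: list with `rho`, `p_sa`, `n_null`,
#'   `null_rhos`, `n_used`.
#' @export
sa_corrected_correlation <- function(map_x, map_y, nulls_of_x) {
  stopifnot(inherits(nulls_of_x, "null_ensemble"))
  pr <- map_values_pair(map_x, map_y)
  if (length(pr$x) < 10L)
    stop_ts("fewer than 10 common valid parcels")
  rho <- cor(pr$x, pr$y, method = "spearman")
  N <- nulls_of_x$nulls[, pr$keep, drop = FALSE]
  ry <- rank(pr$y)
  # apply over rows gives a parcels x n_null matrix of per-null ranks;
  # Pearson on ranks == Spearman for tie-free maps
  null_rhos <- as.numeric(cor(apply(N, 1L, rank), ry))
  n_null <- nrow(N)
  p <- (1 + sum(abs(null_rhos) >= abs(rho))) / (n_null + 1)
  structure(list(rho = rho, p_sa = p, n_null = n_null,
                 null_rhos = null_rhos, n_used = length(pr$x)),
            class = "sa_cor")
}

#' @export
print.sa_cor <- function(x, ...) {
  cat(sprintf("<sa_cor> rho = %.4f, p_sa = %.4g (n_null = %d, n = %d)\n",
              x$rho, x$p_sa, x$n_null, x$n_used))
  invisible(x)
}

#' Binned spatial variogram
#'
#' Semivariance `gamma(h) = mean((v_i - v_j)^2) / 2` over parcel pairs
#' grouped into `n_bins` equal-pair-count distance bins — the diagnostic used
#' to check that null maps reproduce the empirical map's spatial
#' autocorrelation.
#'
#' @param values Numeric vector or [parcel_map()] (invalid parcels dropped).
#' @param distmat Inter-parcel distance matrix.
#' @param n_bins Number of equal-count distance bins.
#' @return data.frame `distance` (bin mean), `semivariance`, `n_pairs`.
#' @export
variogram <- function(values, distmat, n_bins = 25L) {
  if (inherits(values, "parcel_map")) values <- values$values
  keep <- is.finite(values)
  if (sum(keep) < 2L) stop_ts("need at least 2 valid parcels")
  v <- values[keep]
  D <- as.matrix(distmat)[keep, keep, drop = FALSE]
  iu <- upper.tri(D)
  d <- D[iu]
  g <- (outer(v, v, "-")^2 / 2)[iu]
  n_bins <- min(n_bins, length(d))
  # equal-count bins stabilize the variance of long-distance bins
  ord <- order(d)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin[bin > n_bins] <- n_bins
  data.frame(
    distance = as.numeric(tapply(d[ord], bin, mean)),
    semivariance = as.numeric(tapply(g[ord], bin, mean)),
    n_pairs = as.integer(tapply(d[ord], bin, length)))
}

#' Write a null ensemble (delimited matrix + JSON-style sidecar)
#'
#' The matrix file has one row per null; the sidecar records seed, method,
#' and ensemble size as a minimal JSON object.
#'
#' @param ens A [msr_nulls()] ensemble.
#' @param matrix_path,meta_path File paths.
#' @return Invisibly, the two paths.
#' @export
write_null_ensemble <- function(ens, matrix_path, meta_path) {
  write.table(ens$nulls, matrix_path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  writeLines(sprintf(
    '{"seed": %s, "method": "%s", "n_null": %d}',
    format(ens$seed), ens$method, ens$n_null), meta_path)
  invisible(c(matrix_path, meta_path))
}
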