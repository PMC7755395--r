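#' Spherical surface geometry fixture
#'
#' A cheap analogue of a parcellated cortical hemisphere: `n_parcels` parcel
#' centroids placed on a sphere by a Fibonacci lattice (deterministic), each
#' surrounded by jittered member points (the stand-ins for voxels/vertices),
#' with inter-parcel distance taken as the great-circle distance between
#' centroids (the geodesic-distance analogue). The default 100 mm diameter
#' matches the scale of a human hemisphere.
#'
#' @param n_parcels Number of parcels.
#' @param points_per_parcel Member points generated around each centroid.
#' @param radius_mm Sphere radius in mm.
#' @param point_jitter_mm Tangential jitter of member points (mm).
#' @param seed Integer seed for the point jitter.
#' @return An object of class `surface_geometry`: `n_parcels`, `parcel_ids`,
#'   `centroids` (n x 3, mm), `points` (data.frame `point_id`, `x`, `y`, `z`,
#'   `parcel_id`), and `parcel_distance` (symmetric mm matrix, zero diagonal).
#' @export
sphere_geometry <- function(n_parcels = 180L, points_per_parcel = 8L,
                            radius_mm = 50, point_jitter_mm = 3, seed = 1) {
  stopifnot(n_parcels >= 2L, points_per_parcel >= 1L, radius_mm > 0)
  i <- seq_len(n_parcels) - 0.5
  golden <- pi * (3 - sqrt(5))
  theta <- acos(1 - 2 * i / n_parcels)
  phi <- golden * (seq_len(n_parcels) - 1)
  cen <- radius_mm * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                           cos(theta))
  parcel_ids <- sprintf("P%03d", seq_len(n_parcels))
  rownames(cen) <- parcel_ids

  pts <- with_seed_(seed, {
    jitter <- matrix(rnorm(n_parcels * points_per_parcel * 3, 0,
                           point_jitter_mm), ncol = 3L)
    rep_cen <- cen[rep(seq_len(n_parcels), each = points_per_parcel), ,
                   drop = FALSE]
    raw <- rep_cen + jitter
    raw * (radius_mm / sqrt(rowSums(raw^2)))   # re-project onto the sphere
  })
  points <- data.frame(
    point_id = sprintf("V%05d", seq_len(nrow(pts))),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    parcel_id = rep(parcel_ids, each = points_per_parcel),
    stringsAsFactors = FALSE)

  # great-circle distance between centroids
  cosang <- tcrossprod(cen / radius_mm)
  cosang <- pmin(pmax(cosang, -1), 1)
  dmat <- radius_mm * acos(cosang)
  diag(dmat) <- 0
  dmat <- (dmat + t(dmat)) / 2
  dimnames(dmat) <- list(parcel_ids, parcel_ids)

  structure(list(n_parcels = as.integer(n_parcels), parcel_ids = parcel_ids,
                 centroids = cen, points = points, parcel_distance = dmat),
            class = "surface_geometry")
}

#' @export
print.surface_geometry <- function(x, ...) {
  cat(sprintf("<surface_geometry> %d parcels, %d points, max distance %.1f mm\n",
              x$n_parcels, nrow(x$points), max(x$parcel_distance)))
  invisible(x)
}

geometry_point_matrix <- function(geometry) {
  as.matrix(geometry$points[, c("x", "y", "z")])
}

#' Per-parcel scalar map with confidence
#'
#' The currency of all spatial analyses: one value and one confidence in
#' `[0, 1]` per parcel of a fixed parcellation. Parcels with confidence below
#' `conf_threshold` (default 0.5, the "electrode within 4 mm" criterion) are
#' marked invalid and carry `NA` values.
#'
#' @param parcel_ids Character vector of parcel identifiers.
#' @param values Per-parcel values (NA where invalid).
#' @param confidence Per-parcel confidence in `[0, 1]`.
#' @param conf_threshold Validity threshold on confidence.
#' @return An object of class `parcel_map`.
#' @export
parcel_map <- function(parcel_ids, values, confidence = rep(1, length(values)),
                       conf_threshold = 0.5) {
  stopifnot(length(parcel_ids) == length(values),
            length(values) == length(confidence))
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop_ts("confidence must lie in [0, 1]")
  values <- unname(as.numeric(values))
  confidence <- unname(as.numeric(confidence))
  confidence[is.na(confidence)] <- 0
  valid <- confidence >= conf_threshold & !is.na(values)
  values[!valid] <- NA_real_
  structure(list(parcel_ids = unname(as.character(parcel_ids)),
                 values = values, confidence = confidence,
                 valid = valid, conf_threshold = conf_threshold),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("<parcel_map> %d parcels, %d valid (conf >= %g)\n",
              length(x$values), sum(x$valid), x$conf_threshold))
  invisible(x)
}

#' Write / read a parcel map as delimited text
#'
#' Columns: `parcel_id`, `value`, `confidence`, `valid` (0/1).
#'
#' @param map A [parcel_map()].
#' @param path File path.
#' @return `path` invisibly (writer); a [parcel_map()] (reader).
#' @export
write_parcel_map <- function(map, path) {
  tab <- data.frame(parcel_id = map$parcel_ids, value = map$values,
                    confidence = map$confidence,
                    valid = as.integer(map$valid))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcel_map
#' @export
read_parcel_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  parcel_map(tab$parcel_id, tab$value, tab$confidence)
}

#' Write / read a surface geometry as two delimited files
#'
#' `points_path` holds `point_id`, `x`, `y`, `z`, `parcel_id`;
#' `dist_path` holds the dense inter-parcel distance matrix with parcel-id
#' header row and column.
#'
#' @param geometry A [sphere_geometry()]-style `surface_geometry`.
#' @param points_path,dist_path Output file paths.
#' @return Invisibly, the two paths (writer); a `surface_geometry` without
#'   centroids (reader).
#' @export
write_geometry <- function(geometry, points_path, dist_path) {
  write.table(geometry$points, points_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  dm <- data.frame(parcel_id = rownames(geometry$parcel_distance),
                   geometry$parcel_distance, check.names = FALSE)
  write.table(dm, dist_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(points_path, dist_path))
}

#' @rdname write_geometry
#' @export
read_geometry <- function(points_path, dist_path) {
  points <- read.table(points_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  dm <- read.table(dist_path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  parcel_ids <- dm$parcel_id
  dmat <- as.matrix(dm[, -1L, drop = FALSE])
  dimnames(dmat) <- list(parcel_ids, parcel_ids)
  cen <- do.call(rbind, lapply(split(points[, c("x", "y", "z")],
                                     points$parcel_id), colMeans))
  cen <- cen[parcel_ids, , drop = FALSE]
  structure(list(n_parcels = length(parcel_ids), parcel_ids = parcel_ids,
                 centroids = cen, points = points, parcel_distance = dmat),
            class = "surface_geometry")
}

#' Generate a spatially autocorrelated parcel map
#'
#' Draws a zero-mean, unit-variance Gaussian random field over parcels with
#' squared-exponential covariance `exp(-d^2 / (2 * length_scale^2))` on the
#' inter-parcel distances, emulating the smooth spatial variation of cortical
#' maps. Confidence is 1 everywhere. If the covariance matrix is not positive
#' definite, diagonal jitter is added (and reported via a message).
#'
#' @param geometry A `surface_geometry`.
#' @param length_scale Correlation length in mm (> 0).
#' @param seed Integer seed.
#' @return A [parcel_map()].
#' @export
generate_sa_map <- function(geometry, length_scale = 20, seed = 1) {
  stopifnot(inherits(geometry, "surface_geometry"), length_scale > 0)
  C <- sa_covariance_chol(geometry$parcel_distance, length_scale)
  vals <- with_seed_(seed, drop(crossprod(C, rnorm(geometry$n_parcels))))
  parcel_map(geometry$parcel_ids, vals)
}

# upper Cholesky factor of the squared-exponential covariance, with escalating
# diagonal jitter when needed; cached per (distance matrix, length scale)
sa_covariance_chol <- local({
  cache <- new.env(parent = emptyenv())
  function(dmat, length_scale) {
    key <- paste0(format(length_scale, digits = 12), "_", nrow(dmat), "_",
                  format(sum(dmat), digits = 15))
    if (!is.null(cache[[key]])) return(cache[[key]])
    C <- exp(-dmat^2 / (2 * length_scale^2))
    jitter <- 0
    for (attempt in 0:6) {
      ch <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
      if (!is.null(ch)) {
        if (jitter > 0)
          message(sprintf(
            "sa covariance not positive definite; added diagonal jitter %g",
            jitter))
        cache[[key]] <- ch
        return(ch)
      }
      jitter <- if (jitter == 0) 1e-10 else jitter * 10
    }
    # strongly rank-deficient covariance (very long length scales): use the
    # eigendecomposition with clipped eigenvalues as the matrix square root
    message("sa covariance rank-deficient; using eigendecomposition")
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    ch <- t(e$vectors %*% (t(e$vectors) * sqrt(lam)))
    cache[[key]] <- ch
    ch
  }
})

# matrix of SA fields (n_parcels x n_fields), unit marginal variance
sa_field_matrix <- function(geometry, length_scale, n_fields, seed) {
  C <- sa_covariance_chol(geometry$parcel_distance, length_scale)
  with_seed_(seed,
             crossprod(C, matrix(rnorm(geometry$n_parcels * n_fields),
                                 geometry$n_parcels, n_fields)))
}
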