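#' Gaussian distance weight (confidence mask)
#'
#' `w(r) = exp(-r^2 / alpha^2)`: the weight/confidence an electrode assigns to
#' a location `r` mm away. A location directly under an electrode has weight
#' 1.
#'
#' @param r Distance(s) in mm, non-negative.
#' @param alpha Distance scaling constant in mm (> 0); see [default_alpha()].
#' @return Weight(s) in `(0, 1]`.
#' @export
gaussian_weight <- function(r, alpha = default_alpha()) {
  if (any(r < 0)) stop_ts("distances must be non-negative")
  if (alpha <= 0) stop_ts("alpha must be positive")
  exp(-(r^2) / alpha^2)
}

#' Default distance scaling constant
#'
#' The unique `alpha` for which a location 4 mm from an electrode receives
#' 50% weight: `alpha = 4 / sqrt(ln 2)`, about 4.8045 mm.
#'
#' @return alpha in mm.
#' @export
default_alpha <- function() 4 / sqrt(log(2))

#' Electrode set for one subject
#'
#' @param subject_id Subject identifier.
#' @param positions n x 3 matrix of electrode positions in mm.
#' @param values Per-electrode scalar values (e.g. timescale in seconds).
#' @return An object of class `electrode_set`.
#' @export
electrode_set <- function(subject_id, positions, values) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop_ts("need at least one electrode")
  if (ncol(positions) != 3L) stop_ts("positions must be an n x 3 matrix (mm)")
  if (nrow(positions) != length(values))
    stop_ts("positions and values disagree in length")
  assert_finite(positions, "positions")
  assert_finite(values, "values")
  structure(list(subject_id = as.character(subject_id), positions = positions,
                 values = as.numeric(values)),
            class = "electrode_set")
}

#' Project one subject's electrode values onto geometry points
#'
#' Every point receives the weight-normalized average of all the subject's
#' electrode values, `sum_i w(r_i) v_i / sum_i w(r_i)` with Euclidean
#' distances `r_i`, and a confidence equal to the maximum single-electrode
#' weight (i.e. the weight of the closest electrode). No hard distance
#' cutoff is applied: remote electrodes contribute with exponentially small
#' weights. If the total weight underflows at a point, its value is `NA`
#' with confidence 0 (never NaN).
#'
#' @param es An [electrode_set()].
#' @param geometry A `surface_geometry` in the same mm coordinate frame.
#' @param alpha Distance scaling constant (mm).
#' @return data.frame with `point_id`, `parcel_id`, `value`, `confidence`.
#' @export
project_subject <- function(es, geometry, alpha = default_alpha()) {
  stopifnot(inherits(es, "electrode_set"),
            inherits(geometry, "surface_geometry"))
  D <- cross_dist(geometry_point_matrix(geometry), es$positions)
  W <- gaussian_weight(D, alpha)
  sw <- rowSums(W)
  value <- as.numeric(W %*% es$values) / sw
  conf <- row_max(W)
  dead <- sw < .Machine$double.xmin | !is.finite(value)
  value[dead] <- NA_real_
  conf[dead] <- 0
  data.frame(point_id = geometry$points$point_id,
             parcel_id = geometry$points$parcel_id,
             value = value, confidence = conf, stringsAsFactors = FALSE)
}

#' Aggregate point values into a parcel map
#'
#' Parcel value = confidence-weighted arithmetic mean over member points;
#' parcel confidence = maximum member-point confidence. Parcels with zero
#' total confidence are invalid.
#'
#' @param points A data.frame as returned by [project_subject()].
#' @param geometry A `surface_geometry` (defines the parcel order).
#' @param conf_threshold Validity threshold for the resulting map.
#' @return A [parcel_map()].
#' @export
aggregate_to_parcels <- function(points, geometry, conf_threshold = 0.5) {
  pid <- factor(points$parcel_id, levels = geometry$parcel_ids)
  if (anyNA(pid)) stop_ts("points reference parcels absent from the geometry")
  cv <- points$confidence * points$value
  cv[is.na(cv)] <- 0
  num <- tapply(cv, pid, sum, default = 0)
  den <- tapply(points$confidence, pid, sum, default = 0)
  conf <- tapply(points$confidence, pid, max, default = 0)
  vals <- ifelse(den > 0, num / den, NA_real_)
  parcel_map(geometry$parcel_ids, as.numeric(vals), as.numeric(conf),
             conf_threshold = conf_threshold)
}

#' Combine subject parcel maps into a group map
#'
#' Per parcel, the confidence-weighted average of values across subjects with
#' a valid parcel; group confidence is the maximum subject confidence.
#' Parcels valid in no subject are invalid in the group map.
#'
#' @param maps List of [parcel_map()]s on an identical parcellation.
#' @param conf_threshold Validity threshold for the group map.
#' @return A [parcel_map()].
#' @export
combine_subjects <- function(maps, conf_threshold = 0.5) {
  stopifnot(length(maps) >= 1L)
  ids <- maps[[1L]]$parcel_ids
  for (m in maps)
    if (!identical(m$parcel_ids, ids))
      stop_ts("all subject maps must share the same parcellation")
  V <- do.call(rbind, lapply(maps, `[[`, "values"))
  C <- do.call(rbind, lapply(maps, `[[`, "confidence"))
  use <- do.call(rbind, lapply(maps, `[[`, "valid"))
  Cw <- C * use
  num <- colSums(Cw * ifelse(is.na(V), 0, V))
  den <- colSums(Cw)
  vals <- ifelse(den > 0, num / den, NA_real_)
  conf <- apply(C, 2L, max)
  # a parcel valid in no subject is invalid regardless of raw confidence
  conf[den == 0] <- 0
  parcel_map(ids, vals, conf, conf_threshold = conf_threshold)
}

#' Per-parcel subject coverage
#'
#' Counts, per parcel, the subjects whose parcel confidence reaches
#' `confidence_floor`. With the default calibration, confidence 0.5
#' corresponds to an electrode within 4 mm.
#'
#' @param maps List of subject [parcel_map()]s.
#' @param confidence_floor Confidence threshold counted as coverage.
#' @param alpha Distance scaling constant used to report the implied
#'   electrode-distance bound.
#' @return data.frame `parcel_id`, `n_subjects`; the implied distance bound
#'   (mm) is attached as attribute `distance_bound_mm`.
#' @export
coverage_report <- function(maps, confidence_floor = 0.5,
                            alpha = default_alpha()) {
  ids <- maps[[1L]]$parcel_ids
  C <- do.call(rbind, lapply(maps, `[[`, "confidence"))
  counts <- colSums(C >= confidence_floor)
  out <- data.frame(parcel_id = ids, n_subjects = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "distance_bound_mm") <- alpha * sqrt(-log(confidence_floor))
  out
}

#' Write / read electrode tables as delimited text
#'
#' Columns: `subject_id`, `x_mm`, `y_mm`, `z_mm`, `value`. Multiple subjects
#' may share one file.
#'
#' @param sets List of [electrode_set()]s (or a single one).
#' @param path File path.
#' @return `path` invisibly (writer); a list of [electrode_set()]s (reader).
#' @export
write_electrode_table <- function(sets, path) {
  if (inherits(sets, "electrode_set")) sets <- list(sets)
  tab <- do.call(rbind, lapply(sets, function(es) {
    data.frame(subject_id = es$subject_id, x_mm = es$positions[, 1L],
               y_mm = es$positions[, 2L], z_mm = es$positions[, 3L],
               value = es$values, stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_electrode_table
#' @export
read_electrode_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "x_mm", "y_mm", "z_mm", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_ts("electrode table missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(tab, tab$subject_id), function(d) {
    electrode_set(d$subject_id[1L], as.matrix(d[, c("x_mm", "y_mm", "z_mm")]),
                  d$value)
  })
}
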