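#' Pipeline configuration
#'
#' Flat configuration for the end-to-end synthetic benchmark; unknown keys
#' are rejected so typos fail before any compute.
#'
#' @param seed Global seed; per-stage seeds are derived from it by a fixed
#'   counter scheme (see Details in the vignette).
#' @param n_parcels,points_per_parcel,length_scale Geometry / map structure.
#' @param n_subjects,electrodes_per_subject,value_noise_std Electrode cohort.
#' @param n_null Null-ensemble size.
#' @param n_genes,n_associated,effect_size,expr_noise_sd Expression design.
#' @param n_terms Toy-ontology size.
#' @param wm_subjects,wm_trials,delay_expansion Working-memory track.
#' @param aging_subjects,compression_per_year Aging track.
#' @param alpha Projection distance-scaling constant (mm).
#' @param ... Rejected; present to catch unknown keys.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_parcels = 180L, points_per_parcel = 8L,
                            length_scale = 20,
                            n_subjects = 50L, electrodes_per_subject = 20L,
                            value_noise_std = 0.1,
                            n_null = 500L,
                            n_genes = 1000L, n_associated = 50L,
                            effect_size = 1, expr_noise_sd = 0.5,
                            n_terms = 40L,
                            wm_subjects = 14L, wm_trials = 40L,
                            delay_expansion = 1.2,
                            aging_subjects = 71L,
                            compression_per_year = 0.005,
                            alpha = default_alpha(), ...) {
  extra <- list(...)
  if (length(extra))
    stop_ts("unknown configuration key(s): ",
            paste(names(extra), collapse = ", "))
  cfg <- as.list(environment())
  cfg$extra <- NULL
  structure(cfg, class = "pipeline_config")
}

write_config_snapshot <- function(config, path) {
  keys <- setdiff(names(config), "extra")
  writeLines(sprintf("%s\t%s", keys,
                     vapply(keys, function(k) format(config[[k]], digits = 12),
                            "")), path)
  invisible(path)
}

#' Run the end-to-end synthetic benchmark pipeline
#'
#' Composes the package's stages in analysis order on synthetic data with
#' known ground truth: geometry and planted timescale map -> electrode cohort
#' -> projection and group map -> MSR nulls -> SA-corrected map correlations
#' -> planted-gene expression -> PLS null-map gene selection -> ontology
#' enrichment; plus the working-memory and aging tracks. Every stage uses a
#' seed derived deterministically from the global seed, all derived seeds are
#' logged, and the effective configuration is snapshotted, so identical
#' configurations yield byte-identical summary tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; existing files overwritten).
#' @return Invisibly, a list of in-memory stage results (`group_map`,
#'   `map_recovery`, `gene_selection`, `enrichment`, `wm`, `aging`, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_log <- file.path(out_dir, "seeds.log")
  cat("stage\tseed\n", file = seed_log)
  stage_seed <- function(stage, k) {
    s <- derive_seed(config$seed, k)
    cat(sprintf("%s\t%d\n", stage, s), file = seed_log, append = TRUE)
    s
  }
  write_config_snapshot(config, file.path(out_dir, "config.tsv"))

  # --- spatial track -------------------------------------------------------
  geometry <- sphere_geometry(config$n_parcels, config$points_per_parcel,
                              seed = stage_seed("geometry", 1L))
  true_map <- generate_sa_map(geometry, config$length_scale,
                              seed = stage_seed("true_map", 2L))
  cohort <- generate_electrode_dataset(
    geometry, true_map, config$n_subjects, config$electrodes_per_subject,
    value_noise_std = config$value_noise_std * sd(true_map$values),
    seed = stage_seed("electrodes", 3L))
  subject_maps <- lapply(cohort, function(es)
    aggregate_to_parcels(project_subject(es, geometry, config$alpha),
                         geometry))
  group_map <- combine_subjects(subject_maps)
  write_parcel_map(group_map, file.path(out_dir, "group_map.tsv"))
  write_electrode_table(cohort, file.path(out_dir, "electrodes.tsv"))
  write_geometry(geometry, file.path(out_dir, "geometry_points.tsv"),
                 file.path(out_dir, "geometry_distance.tsv"))

  W <- inverse_distance_weights(geometry$parcel_distance)
  nulls <- msr_nulls(true_map, W, n_null = config$n_null,
                     seed = stage_seed("nulls", 4L))
  write_null_ensemble(nulls, file.path(out_dir, "nulls.tsv"),
                      file.path(out_dir, "nulls.json"))
  keep <- group_map$valid
  recov <- cor(true_map$values[keep], group_map$values[keep],
               method = "spearman")

  # --- transcriptomic track ------------------------------------------------
  expr <- generate_expression_matrix(
    geometry, true_map, config$n_genes, config$n_associated,
    effect_size = config$effect_size, noise_sd = config$expr_noise_sd,
    length_scale = config$length_scale, seed = stage_seed("expression", 5L))
  sel <- null_pls_gene_selection(expr$X, true_map$values, nulls)
  write.table(sel, file.path(out_dir, "gene_selection.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  onto <- generate_toy_ontology(expr$gene_ids, config$n_terms,
                                seed = stage_seed("ontology", 6L))
  onto$annotation <- rbind(onto$annotation,
                           data.frame(term_id = "TERM_PLANTED",
                                      gene_id = expr$truth$associated_genes))
  onto$terms <- rbind(onto$terms,
                      data.frame(term_id = "TERM_PLANTED",
                                 name = "planted associated set",
                                 namespace = "BP"))
  study <- sel$gene_id[sel$significant]
  enr <- if (length(study))
    go_enrichment(study, expr$gene_ids, onto$annotation, onto$terms) else NULL
  if (!is.null(enr))
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)

  # --- working-memory track ------------------------------------------------
  wm_data <- generate_trial_dataset(
    n_subjects = config$wm_subjects, n_trials = config$wm_trials,
    delay_expansion = config$delay_expansion,
    seed = stage_seed("wm", 7L))
  wm_feat <- wm_cohort_features(wm_data)
  wm_stats <- wm_region_stats(wm_feat)
  wm_beh <- wm_behavior_correlation(wm_feat, wm_data$accuracy)
  write.table(wm_feat, file.path(out_dir, "wm_features.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(wm_stats$delay_change, file.path(out_dir, "wm_delay_change.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # --- aging track ---------------------------------------------------------
  aging <- generate_aging_cohort(
    geometry, parcel_map(true_map$parcel_ids,
                         0.03 + 0.01 * scale01(true_map$values)),
    n_subjects = config$aging_subjects,
    compression_per_year = config$compression_per_year,
    seed = stage_seed("aging", 8L))
  am <- aging_subject_means(aging$tau_matrix)
  kept <- setdiff(rownames(aging$tau_matrix), am$excluded_subjects)
  ages_kept <- aging$ages[match(kept, rownames(aging$tau_matrix))]
  acorr <- if (length(kept) >= 10L)
    aging_age_correlation(am$means, ages_kept)
  else list(rho = NA_real_, p = NA_real_, n = length(kept))
  apw <- aging_parcelwise(aging$tau_matrix, aging$ages)
  write.table(data.frame(subject_id = kept, age = ages_kept,
                         mean_norm_tau = am$means),
              file.path(out_dir, "aging_means.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  first_or_na <- function(x) if (length(x) >= 1L) x[[1L]] else NA_real_
  summary_tab <- data.frame(
    quantity = c("group_map_recovery_rho", "n_selected_genes",
                 "planted_term_p", "wm_median_expansion",
                 "wm_pfc_behavior_rho", "aging_age_rho", "aging_parcel_t"),
    value = c(recov, length(study),
              first_or_na(if (!is.null(enr))
                enr$p[enr$term_id == "TERM_PLANTED"]),
              first_or_na(
                median(exp(wm_feat$delta_log_tau[wm_feat$region == "PFC"]))),
              first_or_na(wm_beh$rho[wm_beh$region == "PFC"]),
              acorr$rho, apw$t))
  write.table(summary_tab, file.path(out_dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  invisible(list(out_dir = out_dir, geometry = geometry, true_map = true_map,
                 group_map = group_map, map_recovery = recov,
                 gene_selection = sel, enrichment = enr,
                 wm_features = wm_feat, wm_stats = wm_stats,
                 wm_behavior = wm_beh, aging_means = am,
                 aging_age = acorr, aging_parcelwise = apw,
                 summary = summary_tab))
}

scale01 <- function(x) (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)

#' Validate pipeline input files
#'
#' Schema checks for every delimited dialect the package reads: electrode
#' tables, geometry files, parcel maps, expression matrices, and ontology
#' annotations. Issues are collected into one report rather than thrown
#' one-by-one.
#'
#' @param paths Named list; recognized names: `electrodes`, `points`,
#'   `distances`, `parcel_map`, `expression`, `annotation`.
#' @return data.frame `input`, `issue` (zero rows when everything is
#'   well-formed).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(input, issue)
    issues[[length(issues) + 1L]] <<- data.frame(input = input, issue = issue,
                                                 stringsAsFactors = FALSE)
  read_tab <- function(path) tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) NULL)

  if (!is.null(paths$electrodes)) {
    tab <- read_tab(paths$electrodes)
    if (is.null(tab)) note("electrodes", "unreadable file") else {
      miss <- setdiff(c("subject_id", "x_mm", "y_mm", "z_mm", "value"),
                      names(tab))
      if (length(miss))
        note("electrodes", paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
      else if (any(!is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm",
                                                "value")]))))
        note("electrodes", "non-finite coordinates or values")
    }
  }
  if (!is.null(paths$points)) {
    tab <- read_tab(paths$points)
    if (is.null(tab)) note("points", "unreadable file") else {
      miss <- setdiff(c("point_id", "x", "y", "z", "parcel_id"), names(tab))
      if (length(miss))
        note("points", paste("missing column(s):",
                             paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(paths$distances)) {
    tab <- read_tab(paths$distances)
    if (is.null(tab)) note("distances", "unreadable file") else {
      m <- as.matrix(tab[, -1L, drop = FALSE])
      if (nrow(m) != ncol(m)) note("distances", "matrix is not square")
      else {
        if (any(abs(m - t(m)) > 1e-8)) note("distances", "matrix not symmetric")
        if (any(diag(m) != 0)) note("distances", "nonzero diagonal")
        if (max(m) > 1000)
          note("distances", "distances exceed 1000 (expected mm scale)")
      }
    }
  }
  if (!is.null(paths$parcel_map)) {
    tab <- read_tab(paths$parcel_map)
    if (is.null(tab)) note("parcel_map", "unreadable file") else {
      miss <- setdiff(c("parcel_id", "value", "confidence"), names(tab))
      if (length(miss))
        note("parcel_map", paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
      else if (any(tab$confidence < 0 | tab$confidence > 1, na.rm = TRUE))
        note("parcel_map", "confidence outside [0, 1]")
      if (!length(miss) && anyDuplicated(tab$parcel_id))
        note("parcel_map", "duplicated parcel_id")
    }
  }
  if (!is.null(paths$expression)) {
    tab <- read_tab(paths$expression)
    if (is.null(tab)) note("expression", "unreadable file") else {
      if (names(tab)[1L] != "gene_id")
        note("expression", "first column must be gene_id")
      else if (anyDuplicated(tab$gene_id))
        note("expression", "duplicated gene_id")
      if (ncol(tab) < 3L) note("expression", "fewer than 2 parcel columns")
    }
  }
  if (!is.null(paths$annotation)) {
    tab <- read_tab(paths$annotation)
    if (is.null(tab)) note("annotation", "unreadable file") else {
      miss <- setdiff(c("term_id", "gene_id"), names(tab))
      if (length(miss))
        note("annotation", paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(input = character(0), issue = character(0))
}
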