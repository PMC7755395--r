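#' Synthetic sparse electrode cohort
#'
#' Places each subject's electrodes at random geometry points and assigns
#' each electrode the ground-truth parcel value plus Gaussian noise,
#' emulating the sparse, idiosyncratic coverage of intracranial cohorts.
#'
#' @param geometry A `surface_geometry`.
#' @param true_map A [parcel_map()] of ground-truth values.
#' @param n_subjects Number of subjects.
#' @param electrodes_per_subject Electrodes per subject (scalar or vector of
#'   length `n_subjects`).
#' @param value_noise_std SD of additive Gaussian measurement noise.
#' @param seed Integer seed.
#' @return List of [electrode_set()]s, with the sampled point rows attached
#'   per set as attribute `point_index`.
#' @export
generate_electrode_dataset <- function(geometry, true_map, n_subjects,
                                       electrodes_per_subject,
                                       value_noise_std = 0, seed = 1) {
  stopifnot(inherits(geometry, "surface_geometry"),
            inherits(true_map, "parcel_map"),
            all(electrodes_per_subject >= 1))
  npts <- nrow(geometry$points)
  epn <- rep_len(electrodes_per_subject, n_subjects)
  truth <- setNames(true_map$values, true_map$parcel_ids)
  with_seed_(seed, {
    lapply(seq_len(n_subjects), function(s) {
      idx <- sample.int(npts, min(epn[s], npts),
                        replace = epn[s] > npts)
      vals <- truth[geometry$points$parcel_id[idx]] +
        rnorm(length(idx), 0, value_noise_std)
      es <- electrode_set(sprintf("S%03d", s),
                          geometry_point_matrix(geometry)[idx, , drop = FALSE],
                          vals)
      attr(es, "point_index") <- idx
      es
    })
  })
}

#' Synthetic gene-by-parcel expression matrix with planted associations
#'
#' A planted subset of genes tracks `target_map` linearly
#' (`effect_size * map + noise_sd * SA field`); the remaining genes are pure
#' spatially autocorrelated noise with unit variance. Ground truth (planted
#' gene ids, effect size) is recorded for recovery tests.
#'
#' @param geometry A `surface_geometry`.
#' @param target_map A [parcel_map()] the planted genes follow.
#' @param n_genes Total genes.
#' @param n_associated Number of planted genes (`<= n_genes`).
#' @param effect_size Linear association strength.
#' @param noise_sd SD of the SA noise added to planted genes.
#' @param length_scale Correlation length of the SA gene noise, mm.
#' @param seed Integer seed.
#' @return List with `X` (genes x parcels matrix, gene ids as rownames),
#'   `gene_ids`, and `truth` (list `associated_genes`, `effect_size`).
#' @export
generate_expression_matrix <- function(geometry, target_map, n_genes,
                                       n_associated, effect_size = 1,
                                       noise_sd = 0.5, length_scale = 20,
                                       seed = 1) {
  stopifnot(n_associated <= n_genes)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  fields <- sa_field_matrix(geometry, length_scale, n_genes,
                            derive_seed(seed, 1L))
  planted <- with_seed_(derive_seed(seed, 2L),
                        sort(sample.int(n_genes, n_associated)))
  X <- t(fields)                              # genes x parcels, unit-variance SA
  if (n_associated > 0L)
    X[planted, ] <- noise_sd * X[planted, , drop = FALSE] +
      matrix(effect_size * target_map$values, n_associated,
             geometry$n_parcels, byrow = TRUE)
  rownames(X) <- gene_ids
  colnames(X) <- geometry$parcel_ids
  list(X = X, gene_ids = gene_ids,
       truth = list(associated_genes = gene_ids[planted],
                    effect_size = effect_size))
}

#' Toy term-to-gene ontology annotation
#'
#' Random term-to-gene assignments cycled over the BP/CC/MF namespaces; a
#' fixture for enrichment recovery tests. Specific terms (e.g. one equal to
#' a planted gene set) can be appended by the caller.
#'
#' @param gene_ids Universe of gene identifiers.
#' @param n_terms Number of terms.
#' @param term_size_range Two-element integer range of genes per term.
#' @param seed Integer seed.
#' @return List with `annotation` (data.frame `term_id`, `gene_id`) and
#'   `terms` (data.frame `term_id`, `name`, `namespace`).
#' @export
generate_toy_ontology <- function(gene_ids, n_terms, term_size_range = c(5, 50),
                                  seed = 1) {
  if (max(term_size_range) > length(gene_ids))
    stop_ts("term sizes cannot exceed the number of genes")
  term_ids <- sprintf("TERM%04d", seq_len(n_terms))
  ns <- rep(c("BP", "CC", "MF"), length.out = n_terms)
  ann <- with_seed_(seed, {
    sizes <- sample(seq(term_size_range[1L], term_size_range[2L]), n_terms,
                    replace = TRUE)
    do.call(rbind, lapply(seq_len(n_terms), function(i) {
      data.frame(term_id = term_ids[i],
                 gene_id = sample(gene_ids, sizes[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  list(annotation = ann,
       terms = data.frame(term_id = term_ids,
                          name = paste("toy process", seq_len(n_terms)),
                          namespace = ns, stringsAsFactors = FALSE))
}

#' Synthetic working-memory trial dataset
#'
#' Simulates epoched field-potential data for a cohort performing a
#' delayed-response task: per subject, region, and trial, one baseline epoch
#' with a region-specific synaptic timescale and two delay epochs whose
#' timescale is multiplied by the subject's delay-expansion factor
#' (lognormally dispersed around `delay_expansion`). Behavioral accuracy is
#' generated as a logistic function of the subject's planted prefrontal
#' log-expansion plus noise, so that only a monotone association is planted.
#'
#' @param n_subjects Number of subjects.
#' @param regions Subset of `c("PC", "PFC", "OFC", "MTL")`.
#' @param n_trials Trials per subject and region.
#' @param baseline_tau_by_region Named vector of baseline timescales (s).
#' @param delay_expansion Multiplicative delay-period timescale factor.
#' @param subject_sd SD of the subject log-expansion dispersion.
#' @param fs Sampling rate, Hz.
#' @param epoch_s Epoch duration, seconds (900 ms default).
#' @param event_rate Poisson event rate passed to the signal simulator.
#' @param behavior Generate per-subject accuracy?
#' @param seed Integer seed.
#' @return List with `epochs` (list of records: `subject_id`, `region`,
#'   `channel_id`, `period` in baseline/delay1/delay2, `trial`, `ts`),
#'   `accuracy` (data.frame `subject_id`, `accuracy`, or NULL), and `truth`
#'   (list `delay_expansion`, `subject_expansion`, `baseline_tau_by_region`).
#' @export
generate_trial_dataset <- function(n_subjects = 14L,
                                   regions = c("PC", "PFC", "OFC", "MTL"),
                                   n_trials = 40L,
                                   baseline_tau_by_region =
                                     c(PC = 0.020, PFC = 0.025,
                                       OFC = 0.030, MTL = 0.035),
                                   delay_expansion = 1.2,
                                   subject_sd = 0.05,
                                   fs = 1000, epoch_s = 0.9,
                                   event_rate = 1000,
                                   behavior = TRUE, seed = 1) {
  if (!all(regions %in% c("PC", "PFC", "OFC", "MTL")))
    stop_ts("regions must be a subset of PC, PFC, OFC, MTL")
  if (delay_expansion <= 0) stop_ts("delay_expansion must be positive")
  taus <- baseline_tau_by_region[regions]
  if (anyNA(taus)) stop_ts("baseline_tau_by_region must cover all regions")
  if (epoch_s * fs < 2 * fs * max(taus) * delay_expansion)
    stop_ts("epochs too short to resolve the longest timescale")
  subj_ids <- sprintf("S%03d", seq_len(n_subjects))
  expansion <- with_seed_(derive_seed(seed, 1L),
                          delay_expansion *
                            exp(rnorm(n_subjects, 0, subject_sd)))
  names(expansion) <- subj_ids

  epochs <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (rg in regions) {
      for (tr in seq_len(n_trials)) {
        tau_b <- unname(taus[rg])
        tau_d <- tau_b * expansion[s]
        for (period in c("baseline", "delay1", "delay2")) {
          k <- k + 1L
          tau <- if (period == "baseline") tau_b else tau_d
          epochs[[k]] <- list(
            subject_id = subj_ids[s], region = rg, channel_id = "ch1",
            period = period, trial = tr,
            ts = sim_synaptic_current(fs, epoch_s, tau, event_rate,
                                      seed = derive_seed(seed, 100L + k)))
        }
      }
    }
  }

  accuracy <- NULL
  if (behavior) {
    noise <- with_seed_(derive_seed(seed, 2L), rnorm(n_subjects, 0, 0.02))
    acc <- plogis(qlogis(0.8) +
                    8 * (log(expansion) - log(delay_expansion))) + noise
    accuracy <- data.frame(subject_id = subj_ids,
                           accuracy = pmin(pmax(acc, 0.01), 0.99),
                           stringsAsFactors = FALSE)
  }
  list(epochs = epochs, accuracy = accuracy,
       truth = list(delay_expansion = delay_expansion,
                    subject_expansion = expansion,
                    baseline_tau_by_region = taus))
}

#' Synthetic aging cohort of subject-by-parcel timescale maps
#'
#' Emulates a task-free cohort with sparse electrode coverage and a planted
#' linear timescale compression with age: subject `s` of age `a_s` carries
#' the map `true_map * (1 - compression_per_year * a_s)`, sampled at a
#' variable number of random electrodes, projected and aggregated to parcels;
#' parcels below the confidence threshold are missing (`NA`), never imputed.
#'
#' @param geometry A `surface_geometry`.
#' @param true_map A [parcel_map()] of baseline (age-0) timescales.
#' @param n_subjects Number of subjects.
#' @param age_range Two-element range of ages, years.
#' @param compression_per_year Fractional timescale loss per year of age.
#' @param electrodes_range Two-element range of electrodes per subject.
#' @param value_noise_frac Electrode noise SD as a fraction of sd(true map).
#' @param seed Integer seed.
#' @return List with `tau_matrix` (subjects x parcels, NA = missing),
#'   `ages`, and `truth` (list `compression_per_year`).
#' @export
generate_aging_cohort <- function(geometry, true_map, n_subjects = 71L,
                                  age_range = c(13, 62),
                                  compression_per_year = 0.005,
                                  electrodes_range = c(5, 30),
                                  value_noise_frac = 0.1, seed = 1) {
  stopifnot(inherits(true_map, "parcel_map"))
  ages <- with_seed_(derive_seed(seed, 1L),
                     sort(runif(n_subjects, age_range[1L], age_range[2L])))
  n_el <- with_seed_(derive_seed(seed, 2L),
                     sample(seq(electrodes_range[1L], electrodes_range[2L]),
                            n_subjects, replace = TRUE))
  noise_sd <- value_noise_frac * sd(true_map$values)
  rows <- lapply(seq_len(n_subjects), function(s) {
    scaled <- parcel_map(true_map$parcel_ids,
                         true_map$values *
                           (1 - compression_per_year * ages[s]),
                         true_map$confidence)
    es <- generate_electrode_dataset(geometry, scaled, 1L, n_el[s],
                                     value_noise_std = noise_sd,
                                     seed = derive_seed(seed, 10L + s))[[1L]]
    aggregate_to_parcels(project_subject(es, geometry), geometry)$values
  })
  tau_matrix <- do.call(rbind, rows)
  dimnames(tau_matrix) <- list(sprintf("S%03d", seq_len(n_subjects)),
                               geometry$parcel_ids)
  list(tau_matrix = tau_matrix, ages = ages,
       truth = list(compression_per_year = compression_per_year))
}

#' Write / read an expression matrix as a delimited gene x parcel table
#'
#' First column `gene_id`, remaining columns one per parcel.
#'
#' @param X Genes x parcels matrix with gene-id rownames.
#' @param path File path.
#' @return `path` invisibly (writer); a matrix (reader).
#' @export
write_expression_matrix <- function(X, path) {
  tab <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(X) <- tab$gene_id
  X
}

#' Write / read a term-to-gene annotation
#'
#' `pairs_path`: two columns `term_id`, `gene_id`; `terms_path`: metadata
#' columns `term_id`, `name`, `namespace`.
#'
#' @param ontology A list as returned by [generate_toy_ontology()].
#' @param pairs_path,terms_path File paths.
#' @return Invisibly the paths (writer); an ontology list (reader).
#' @export
write_ontology <- function(ontology, pairs_path, terms_path) {
  write.table(ontology$annotation, pairs_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(ontology$terms, terms_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(pairs_path, terms_path))
}

#' @rdname write_ontology
#' @export
read_ontology <- function(pairs_path, terms_path) {
  list(annotation = read.table(pairs_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE),
       terms = read.table(terms_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}
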