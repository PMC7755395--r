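test_that("trial features encode the log-timescale change", {
  # tau 20 -> 24 ms corresponds to delta log tau = log(1.2)
  expect_equal(log(0.024) - log(0.020), log(1.2), tolerance = 1e-12)
  expect_equal(log(1.2), 0.1823216, tolerance = 1e-6)

  # identical epochs give a delta of zero
  ep <- sim_synaptic_current(1000, 0.9, 0.025, seed = 5)
  ft <- wm_trial_features(ep, ep, ep)
  expect_equal(ft$delta_log_tau, 0)
  expect_equal(ft$delta_theta, 0)
  expect_equal(ft$delta_exponent, 0)
  expect_equal(ft$delay_tau, ft$baseline_tau)
})

test_that("cohort features aggregate channels then trials and drop failures", {
  wm <- generate_trial_dataset(n_subjects = 3L, regions = c("PC", "PFC"),
                               n_trials = 6L, subject_sd = 0, seed = 131)
  feat <- wm_cohort_features(wm)
  expect_setequal(feat$region, c("PC", "PFC"))
  expect_true(all(feat$n_trials <= 6L))
  expect_true(all(is.finite(feat$delta_log_tau)))

  # permuting epoch order changes nothing
  wm2 <- wm
  wm2$epochs <- wm2$epochs[rev(seq_along(wm2$epochs))]
  feat2 <- wm_cohort_features(wm2)
  expect_equal(feat2[order(feat2$subject_id, feat2$region), ],
               feat[order(feat$subject_id, feat$region), ],
               ignore_attr = TRUE)
})

test_that("region statistics detect a planted hierarchy and expansion", {
  wm <- generate_trial_dataset(n_subjects = 10L, n_trials = 16L,
                               baseline_tau_by_region =
                                 c(PC = 0.010, PFC = 0.015,
                                   OFC = 0.022, MTL = 0.030),
                               delay_expansion = 1.4, subject_sd = 0,
                               seed = 141)
  feat <- wm_cohort_features(wm)
  st <- wm_region_stats(feat)

  # recovered baseline medians preserve the planted order
  med <- vapply(split(feat$baseline_tau, feat$region), median, 0)
  expect_true(med[["PC"]] < med[["PFC"]],
              med[["PFC"]] < med[["OFC"]])
  expect_true(med[["OFC"]] < med[["MTL"]])

  adj <- subset(st$baseline_pairwise,
                paste(region_a, region_b) %in%
                  c("PC PFC", "OFC PFC", "MTL OFC", "OFC PC", "MTL PC",
                    "PFC PC", "PFC OFC", "OFC MTL", "PC OFC", "PC MTL"))
  expect_true(all(adj$p < 0.05))
  expect_true(all(st$delay_change$p < 0.05))
  expect_true(all(st$delay_change$median_expansion > 1))

  # single-region input: only the delay-change test runs
  solo <- feat[feat$region == "PFC", ]
  st1 <- wm_region_stats(solo)
  expect_null(st1$baseline_pairwise)
  expect_equal(nrow(st1$delay_change), 1L)
})

test_that("behavior correlation is exact for monotone accuracy", {
  feat <- data.frame(subject_id = sprintf("S%02d", 1:8),
                     region = "PFC",
                     delta_log_tau = seq(0.05, 0.4, length.out = 8))
  acc <- data.frame(subject_id = feat$subject_id,
                    accuracy = plogis(feat$delta_log_tau * 3))
  res <- wm_behavior_correlation(feat, acc)
  expect_equal(res$rho[res$region == "PFC"], 1)

  # shuffled accuracies: null correlation on average
  set.seed(6)
  rhos <- replicate(200, {
    acc$accuracy <- sample(acc$accuracy)
    wm_behavior_correlation(feat, acc)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("aging normalization and thresholds follow the stated rules", {
  M <- rbind(S1 = c(10, 4, NA), S2 = c(20, 2, 6))
  colnames(M) <- c("P1", "P2", "P3")
  am <- aging_subject_means(M, min_valid_parcels = 2L)
  # parcel columns normalized by their max: P1 -> 0.5, 1.0
  expect_equal(unname(am$means[["S1"]]), mean(c(0.5, 1.0)))
  expect_equal(unname(am$means[["S2"]]), mean(c(1.0, 0.5, 1.0)))
  expect_length(am$excluded_subjects, 0L)

  # subject below the valid-parcel threshold is excluded
  M2 <- rbind(S1 = c(10, 4, 6), S2 = c(20, NA, NA))
  colnames(M2) <- colnames(M)
  am2 <- aging_subject_means(M2, min_valid_parcels = 2L)
  expect_equal(am2$excluded_subjects, "S2")

  # boundary: exactly min_valid_parcels - 1 valid parcels is excluded
  M3 <- matrix(rnorm(10 * 12, 10), 10, 12,
               dimnames = list(sprintf("S%02d", 1:10), NULL))
  M3[1L, 1:3] <- NA     # subject 1 left with 9 of 12 parcels
  am3 <- aging_subject_means(M3, min_valid_parcels = 10L)
  expect_true("S01" %in% am3$excluded_subjects)

  # normalized values in (0, 1] and each parcel attains 1
  Mn <- sweep(M2, 2L, apply(M2, 2L, max, na.rm = TRUE), "/")
  expect_true(all(Mn <= 1, na.rm = TRUE))
  expect_true(all(apply(Mn, 2L, max, na.rm = TRUE) == 1))
})

test_that("aging correlations recover a planted compression", {
  geom <- test_geom
  base <- parcel_map(geom$parcel_ids,
                     0.03 + 0.01 * (seq_len(geom$n_parcels) /
                                      geom$n_parcels))
  aging <- generate_aging_cohort(geom, base, n_subjects = 40L,
                                 compression_per_year = 0.006,
                                 electrodes_range = c(8, 30), seed = 151)
  am <- aging_subject_means(aging$tau_matrix, min_valid_parcels = 5L)
  kept <- !(rownames(aging$tau_matrix) %in% am$excluded_subjects)
  res <- aging_age_correlation(am$means, aging$ages[kept])
  expect_lt(res$rho, 0)

  pw <- aging_parcelwise(aging$tau_matrix, aging$ages, min_subjects = 5L)
  expect_lt(pw$mean_rho, 0)
  expect_lt(pw$t, 0)
  expect_gt(pw$n_parcels, 5L)

  # all parcels below min_subjects: explicit mask, no silent zeros
  sparse <- aging$tau_matrix
  sparse[] <- NA
  sparse[1:2, 1:3] <- 0.03
  pw0 <- aging_parcelwise(sparse, aging$ages, min_subjects = 5L)
  expect_true(all(is.na(pw0$parcel_rho)))
  expect_equal(pw0$n_parcels, 0L)
})

test_that("no planted aging effect gives null correlations", {
  geom <- test_geom
  base <- parcel_map(geom$parcel_ids, rep(0.03, geom$n_parcels))
  aging <- generate_aging_cohort(geom, base, n_subjects = 40L,
                                 compression_per_year = 0,
                                 value_noise_frac = 0, seed = 161)
  # noiseless flat map, no compression: correlations undefined or tiny
  pw <- suppressWarnings(aging_parcelwise(aging$tau_matrix, aging$ages))
  expect_true(is.na(pw$mean_rho) || abs(pw$mean_rho) < 0.2)
})
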