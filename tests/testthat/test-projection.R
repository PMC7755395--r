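test_that("the Gaussian confidence mask obeys its calibration", {
  expect_equal(gaussian_weight(0), 1)
  expect_equal(gaussian_weight(4), 0.5)
  expect_equal(gaussian_weight(8), 0.0625)           # 2^-4
  expect_equal(default_alpha(), 4 / sqrt(log(2)))
  expect_equal(gaussian_weight(4, 2 * default_alpha()), 0.5^0.25)
  expect_equal(gaussian_weight(0, 0.123), 1)
  expect_error(gaussian_weight(-1), "non-negative")
  expect_error(gaussian_weight(1, 0), "positive")
})

test_that("projection implements the weighted-average formula exactly", {
  geom <- test_geom
  p1 <- unlist(geom$points[1, c("x", "y", "z")])

  # single electrode on a point: identity with confidence 1
  es <- electrode_set("s1", rbind(p1), 0.025)
  pr <- project_subject(es, geom)
  expect_equal(pr$value[1L], 0.025)
  expect_equal(pr$confidence[1L], 1)

  # electrodes at 0 and 4 mm: hand-evaluated weighted mean
  dir <- c(1, 0, 0)
  es2 <- electrode_set("s2", rbind(p1, p1 + 4 * dir), c(10, 30))
  pr2 <- project_subject(es2, geom)
  expect_equal(pr2$value[1L], (1 * 10 + 0.5 * 30) / 1.5, tolerance = 1e-10)
  expect_equal(pr2$confidence[1L], 1)

  # two equidistant electrodes average symmetrically
  es3 <- electrode_set("s3", rbind(p1 + 3 * dir, p1 - 3 * dir), c(10, 30))
  pr3 <- project_subject(es3, geom)
  expect_equal(pr3$value[1L], 20, tolerance = 1e-9)

  # projected values bounded by contributing electrode values
  expect_true(all(pr2$value >= 10 - 1e-12 & pr2$value <= 30 + 1e-12))
})

test_that("parcel aggregation is the confidence-weighted mean", {
  geom <- test_geom
  pts <- data.frame(point_id = c("a", "b"),
                    parcel_id = rep(geom$parcel_ids[1L], 2),
                    value = c(10, 20), confidence = c(1.0, 0.5))
  pm <- aggregate_to_parcels(pts, geom)
  expect_equal(pm$values[1L], (1 * 10 + 0.5 * 20) / 1.5, tolerance = 1e-10)
  expect_equal(pm$confidence[1L], 1.0)
  # parcels with no evidence are invalid
  expect_false(any(pm$valid[-1L]))
  expect_true(all(is.na(pm$values[-1L])))

  # constant member values pass through
  pts$value <- c(7, 7)
  expect_equal(aggregate_to_parcels(pts, geom)$values[1L], 7)
})

test_that("subject combination weights by confidence and handles identity", {
  ids <- c("P1", "P2")
  m1 <- parcel_map(ids, c(10, 5), c(1, 1))
  expect_equal(combine_subjects(list(m1))$values, m1$values)

  m2 <- parcel_map(ids, c(30, 7), c(1, 1))
  expect_equal(combine_subjects(list(m1, m2))$values[1L], 20)

  m3 <- parcel_map(ids, c(30, 7), c(0.25, 1), conf_threshold = 0.2)
  expect_equal(combine_subjects(list(m1, m3))$values[1L], 14)
})

test_that("projection round-trips a dense noiseless map and is order invariant", {
  geom <- test_geom
  truth <- generate_sa_map(geom, length_scale = 30, seed = 3)
  es <- generate_electrode_dataset(geom, truth, 1L,
                                   nrow(geom$points), 0, seed = 4)[[1L]]
  pm <- aggregate_to_parcels(project_subject(es, geom), geom)
  conf1 <- pm$confidence >= 1 - 1e-9
  expect_gte(sum(conf1), 3L)
  expect_gte(cor(pm$values[pm$valid], truth$values[pm$valid]), 0.99)

  # permuting electrodes changes nothing
  perm <- sample(seq_along(es$values))
  es_p <- electrode_set(es$subject_id, es$positions[perm, ], es$values[perm])
  expect_equal(project_subject(es_p, geom)$value,
               project_subject(es, geom)$value, tolerance = 1e-12)
})

test_that("coverage counts subjects above the confidence floor", {
  geom <- test_geom
  cen <- geom$centroids[1L, ]
  es <- electrode_set("s1", rbind(cen), 1)
  pm <- aggregate_to_parcels(project_subject(es, geom), geom)
  cov <- coverage_report(list(pm))
  expect_equal(attr(cov, "distance_bound_mm"), 4, tolerance = 1e-10)
  near <- which(as.matrix(dist(rbind(cen, geom$centroids)))[1L, -1L] < 2)
  expect_true(all(cov$n_subjects[near] >= 1L))
  far <- which.max(geom$parcel_distance[1L, ])
  expect_equal(cov$n_subjects[far], 0L)
})

test_that("synthetic electrode cohorts recover the planted map", {
  geom <- test_geom
  truth <- generate_sa_map(geom, length_scale = 30, seed = 5)
  cohort <- generate_electrode_dataset(geom, truth, 50L, 20L,
                                       value_noise_std = 0.1 * sd(truth$values),
                                       seed = 6)
  maps <- lapply(cohort, function(es)
    aggregate_to_parcels(project_subject(es, geom), geom))
  grp <- combine_subjects(maps)
  keep <- grp$valid
  expect_gte(cor(grp$values[keep], truth$values[keep], method = "spearman"),
             0.9)

  # single subject, single electrode: exactly one point at confidence 1
  es1 <- generate_electrode_dataset(geom, truth, 1L, 1L, 0, seed = 7)[[1L]]
  pr <- project_subject(es1, geom)
  expect_equal(sum(pr$confidence >= 1 - 1e-12), 1L)

  # determinism
  again <- generate_electrode_dataset(geom, truth, 50L, 20L,
                                      value_noise_std = 0.1 * sd(truth$values),
                                      seed = 6)
  expect_identical(lapply(cohort, `[[`, "values"),
                   lapply(again, `[[`, "values"))
})

test_that("electrode tables round trip through delimited text", {
  geom <- test_geom
  truth <- generate_sa_map(geom, 30, seed = 8)
  cohort <- generate_electrode_dataset(geom, truth, 3L, 5L, 0.01, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_electrode_table(cohort, path)
  back <- read_electrode_table(path)
  expect_length(back, 3L)
  expect_equal(back[["S002"]]$values, cohort[[2L]]$values, tolerance = 1e-9)
  expect_equal(unname(back[["S002"]]$positions),
               unname(cohort[[2L]]$positions), tolerance = 1e-9)
})

test_that("confidence increases monotonically as an electrode approaches", {
  geom <- test_geom
  p1 <- unlist(geom$points[1, c("x", "y", "z")])
  confs <- vapply(c(12, 8, 5, 2, 0.5, 0), function(r) {
    es <- electrode_set("s", rbind(p1 + c(r, 0, 0)), 1)
    project_subject(es, geom)$confidence[1L]
  }, 0)
  expect_true(all(diff(confs) > 0))
  expect_equal(confs[[6]], 1)
})
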