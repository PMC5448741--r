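test_that("configuration validation rejects impossible designs", {
  expect_error(cohort_config(n_exposed = c(30, 31, 17)), "nested")
  expect_error(cohort_config(n_unexposed = c(29, 29, 30)), "nested")
  expect_error(cohort_config(diagnosis_counts = c(31, 23, 12, 2)), "exceeds")
  expect_error(cohort_config(effects = list(t1 = c(not_a_feature = 1))), "canonical")
  expect_error(cohort_config(seed_weights = c(OMPFC = 0.3, shared = 0.7)), "seed_weights")
})

test_that("default design reproduces the study group sizes", {
  cfg <- cohort_config()
  recs <- generate_cohort(cfg, timepoint = 1, seed = 3)
  g <- vapply(recs, `[[`, numeric(1), "group")
  expect_length(recs, 59)
  expect_equal(sum(g == 1), 30)
  expect_equal(sum(g == 0), 29)
  expect_error(generate_cohort(cfg, timepoint = 4), "timepoint")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- tiny_config()
  expect_identical(generate_cohort(cfg, 1, seed = 12),
                   generate_cohort(cfg, 1, seed = 12))
  expect_identical(generate_longitudinal(cfg, seed = 12),
                   generate_longitudinal(cfg, seed = 12))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg, 1, seed = 12),
                         generate_cohort(cfg, 1, seed = 13)))
})

test_that("longitudinal cohorts have nested attrition and planted diagnosis counts", {
  cfg <- cohort_config()
  lc <- generate_longitudinal(cfg, seed = 21)
  ids <- lapply(lc$records, function(recs)
    sort(vapply(recs, `[[`, character(1), "subject_id")))
  expect_true(all(ids$t2 %in% ids$t1))
  expect_true(all(ids$t3 %in% ids$t2))
  expect_length(lc$records$t1, 59)
  expect_length(lc$records$t2, 54)
  expect_length(lc$records$t3, 38)

  cl <- lc$clinical
  dx <- vapply(0:3, function(t) sum(cl$diagnosed[cl$timepoint == t]), numeric(1))
  n <- vapply(0:3, function(t) sum(cl$timepoint == t), numeric(1))
  expect_equal(dx, c(30, 23, 12, 2))
  expect_equal(n, c(30, 30, 25, 17))
  expect_false(anyNA(cl$caps))           # every assessed subject has CAPS
  # recovery is permanent: once not diagnosed, never diagnosed again
  for (sid in unique(cl$subject_id)) {
    tr <- cl$diagnosed[cl$subject_id == sid]
    expect_true(all(diff(as.integer(tr)) <= 0))
  }
})

test_that("an empty timepoint yields an empty wave without error", {
  cfg <- cohort_config(n_exposed = c(10, 5, 0), n_unexposed = c(8, 8, 0),
                       diagnosis_counts = c(10, 8, 4, 0))
  lc <- generate_longitudinal(cfg, seed = 5)
  expect_length(lc$records$t3, 0)
  expect_false(3 %in% lc$clinical$timepoint)
})

test_that("CAPS trajectories track the configured means and diagnosed subjects score higher", {
  cfg <- cohort_config()
  caps0 <- unlist(lapply(1:25, function(s) {
    cl <- generate_longitudinal(cfg, seed = 1000 + s)$clinical
    cl$caps[cl$timepoint == 0]
  }))
  # pooled time-0 mean over many seeds concentrates on the configured 87.1
  expect_equal(mean(caps0), 87.1, tolerance = 1.0 / 87.1)

  cl <- generate_longitudinal(cfg, seed = 31)$clinical
  for (t in 1:2) {
    at <- cl[cl$timepoint == t, ]
    expect_gt(mean(at$caps[at$diagnosed]), mean(at$caps[!at$diagnosed]))
    se <- cfg$caps_sd[t + 1] / sqrt(nrow(at))
    expect_lt(abs(mean(at$caps) - cfg$caps_mean[t + 1]), 3 * se)
  }
  expect_true(all(cl$caps >= 0 & cl$caps <= 136))
})

test_that("recovery rates reproduce follow-up arithmetic", {
  counts <- data.frame(timepoint = 1:3, n_assessed = c(30, 25, 17),
                       n_diagnosed = c(23, 12, 2))
  rr <- recovery_rates(counts)
  expect_equal(rr$n_recovered, c(7, 13, 15))
  expect_equal(rr$rate, c(7 / 30, 13 / 25, 15 / 17))
  expect_equal(round(rr$percent), c(23, 52, 88))

  all_dx <- data.frame(timepoint = 1, n_assessed = 20, n_diagnosed = 20)
  expect_equal(recovery_rates(all_dx)$percent, 0)
  none_dx <- data.frame(timepoint = 1, n_assessed = 20, n_diagnosed = 0)
  expect_equal(recovery_rates(none_dx)$percent, 100)
  expect_error(recovery_rates(data.frame(timepoint = 1, n_assessed = 0,
                                         n_diagnosed = 0)), "undefined")

  lc <- generate_longitudinal(cohort_config(), seed = 41)
  expect_equal(recovery_rates(lc)$percent, 100 * c(7 / 30, 13 / 25, 15 / 17))
})

test_that("null cohorts show no standardized group shift", {
  cfg <- cohort_config(n_exposed = c(300, 25, 17), n_unexposed = c(300, 29, 21),
                       diagnosis_counts = c(300, 23, 12, 2))
  recs <- generate_cohort(cfg, 1, seed = 55)
  tbl <- extract_feature_table(recs)
  z <- standardize(tbl, fit_adjustment(tbl))
  zx <- z[z$group == 1, feature_names()]
  for (f in feature_names()) {
    se <- stats::sd(zx[[f]]) / sqrt(nrow(zx))
    expect_lt(abs(mean(zx[[f]])), 3.9 * se)  # joint over 23 features
  }
})

test_that("a planted 1-SD amygdala deficit appears as a -1 standardized shift", {
  cfg <- cohort_config(
    n_exposed = c(500, 25, 17), n_unexposed = c(500, 29, 21),
    diagnosis_counts = c(500, 23, 12, 2),
    effects = list(t1 = c(amygdala_volume = -1.0), t2 = numeric(0), t3 = numeric(0)))
  shifts <- vapply(1:6, function(s) {
    recs <- generate_cohort(cfg, 1, seed = 7000 + s)
    tbl <- extract_feature_table(recs)
    z <- standardize(tbl, fit_adjustment(tbl))
    mean(z$amygdala_volume[z$group == 1])
  }, numeric(1))
  expect_equal(mean(shifts), -1.0, tolerance = 0.15 / 1.0)
})

test_that("cohort CSV round-trip preserves the records and clinical table", {
  cfg <- tiny_config()
  lc <- generate_longitudinal(cfg, seed = 61)
  dir <- tempfile("cohort")
  write_cohort(lc, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "subjects.csv", "volumes.csv", "connectivity.csv", "seed_classification.csv")))))
  back <- read_cohort(dir)
  for (t in paste0("t", 1:3)) {
    expect_length(back$records[[t]], length(lc$records[[t]]))
  }
  tb1 <- extract_feature_table(lc$records$t1)
  tb2 <- extract_feature_table(back$records$t1)
  tb2 <- tb2[match(tb1$subject_id, tb2$subject_id), ]
  rownames(tb2) <- NULL
  expect_equal(tb1, tb2, tolerance = 1e-12)
  cl2 <- back$clinical[order(back$clinical$timepoint, back$clinical$subject_id), ]
  cl1 <- lc$clinical[order(lc$clinical$timepoint, lc$clinical$subject_id), ]
  rownames(cl1) <- rownames(cl2) <- NULL
  expect_equal(cl1$caps, cl2$caps, tolerance = 1e-10)
  expect_equal(cl1$diagnosed, cl2$diagnosed)
})

test_that("configs load from YAML with partial overrides", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_exposed: [12, 10, 8]",
               "n_unexposed: [12, 11, 9]",
               "diagnosis_counts: [12, 9, 5, 1]",
               "seed_voxels: 20",
               "effects:",
               "  t1:",
               "    amygdala_volume: -0.8"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_exposed, c(12, 10, 8))
  expect_equal(cfg$seed_voxels, 20)
  expect_equal(cfg$effects$t1, c(amygdala_volume = -0.8))
  expect_equal(cfg$caps_mean, c(87.1, 54.0, 45.6, 35.1))  # untouched default
})
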