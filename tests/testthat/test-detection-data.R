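test_that("long-format rows aggregate into the ragged nested structure", {
  d <- survey_dataset(tiny_replicates())
  shape <- dataset_shape(d)
  expect_equal(unname(shape$samples_per_site), 3L)
  expect_equal(shape$replicates_per_sample, c(3L, 3L, 3L))

  # the field-control layout: 9 sites x 6 samples + 1 site x 3 samples
  fd <- survey_dataset(field_detections())
  fshape <- dataset_shape(fd)
  expect_equal(nrow(fd$samples), 57L)
  expect_equal(nrow(fd$replicates), 171L)
  expect_equal(sort(unname(fshape$samples_per_site)), c(3L, rep(6L, 9)))
  expect_equal(sum(fd$replicates$detection), 88L)
  expect_equal(sum(tapply(fd$replicates$detection, fd$replicates$sample_idx,
                          max)), 33L)
})

test_that("invalid replicate tables are rejected", {
  bad <- tiny_replicates()
  bad$detection[4] <- 2
  expect_error(survey_dataset(bad), "0, 1 or NA")
  dup <- rbind(tiny_replicates(), tiny_replicates()[1, ])
  expect_error(survey_dataset(dup), "duplicate")
  expect_error(survey_dataset(tiny_replicates()[, -1]), "missing required")
})

test_that("CSV round-trip preserves detections and structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- random_dataset(4, c(2, 3, 1, 4), reps = 3, seed = 11,
                      with_covariate = FALSE)
  write_long_csv(d, path)
  d2 <- read_long_csv(path)
  expect_equal(d2$replicates$detection, d$replicates$detection)
  expect_equal(d2$samples, d$samples)
  expect_equal(dataset_shape(d2), dataset_shape(d))
})

test_that("missing detections are preserved as NA, never as 0", {
  reps <- tiny_replicates(c(1, NA, 0, 0, NA, 0, 1, 0, 1))
  d <- survey_dataset(reps)
  expect_equal(sum(is.na(d$replicates$detection)), 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(d, path)
  expect_equal(sum(is.na(read_long_csv(path)$replicates$detection)), 2L)
  # collapsing skips missing replicates instead of treating them as misses
  h <- collapse_histories(d, unit = "sample")
  expect_equal(h$trials, c(2L, 2L, 3L))
  expect_equal(h$detections, c(1L, 0L, 2L))
})

test_that("relative density matches the field survey table", {
  expect_equal(relative_density(3, 0.75), 4.00)
  expect_equal(round(relative_density(60, 41.75), 2), 1.44)
  expect_equal(relative_density(0, 25.0), 0)
  expect_error(relative_density(3, 0), "positive")
  expect_error(relative_density(3, -1), "positive")
})

test_that("site measurement aggregation is the mean and permutation-invariant", {
  expect_equal(aggregate_site_measurements(c(12, 14)), 13)
  expect_equal(aggregate_site_measurements(11.8), 11.8)
  expect_equal(aggregate_site_measurements(c(609, 907)), 758)
  expect_equal(aggregate_site_measurements(c(907, 609)), 758)
  expect_error(aggregate_site_measurements(numeric(0)), "no finite")
  expect_error(aggregate_site_measurements(c(NA, NaN)), "no finite")
})

test_that("covariate standardization centres, scales, and is idempotent", {
  cov <- data.frame(site = c("A", "B", "C"), x = c(1, 2, 3))
  reps <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    data.frame(site = s, sample = "s1", replicate = 1:2, detection = 0)
  }))
  d <- standardize_covariates(survey_dataset(reps, site_covariates = cov), "x")
  expect_equal(mean(d$site_covariates$x), 0)
  expect_equal(sd(d$site_covariates$x), 1)
  expect_equal(d$site_covariates$x.raw, c(1, 2, 3))
  d2 <- standardize_covariates(d, "x")
  expect_equal(d2$site_covariates$x, d$site_covariates$x, tolerance = 1e-12)

  const <- data.frame(site = c("A", "B", "C"), x = c(2, 2, 2))
  expect_error(
    standardize_covariates(survey_dataset(reps, site_covariates = const), "x"),
    "zero or undefined spread")
})

test_that("standardized relative density reproduces the printed site summary", {
  tab <- field_sites()
  expect_equal(round(mean(tab$density), 2), 0.89)
  expect_equal(round(sd(tab$density), 2), 1.18)
  d <- field_dataset()
  std <- d$site_covariates$density[d$site_covariates$site == "Cobbs Well"]
  expect_equal(std, (4 - mean(tab$density)) / sd(tab$density))
  expect_lt(abs(std - 2.63), 0.02)
})
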