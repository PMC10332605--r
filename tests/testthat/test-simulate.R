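test_that("degenerate parameter settings force the data", {
  all_on <- sim_params(6, 3, 3, beta_psi = 8, alpha_theta = 8, delta_p = 8,
                       seed = 1)
  sim <- simulate_multiscale(all_on)
  expect_true(all(sim$dataset$replicates$detection == 1))

  none <- sim_params(6, 3, 3, beta_psi = -8, alpha_theta = 2, delta_p = 2,
                     seed = 2)
  sim0 <- simulate_multiscale(none)
  expect_true(all(sim0$dataset$replicates$detection == 0))
  expect_true(all(sim0$truth$z == 0))
})

test_that("the conditional-zero law holds across random simulations", {
  for (s in 1:10) {
    sim <- simulate_multiscale(sim_params(
      12, 4, 3, beta_psi = 0.5, alpha_theta = c(0.2, density = 0.8),
      delta_p = 1,
      covariates = list(density = function(n) rlnorm(n, -0.7, 1)),
      seed = 400 + s))
    idx <- occuDNA:::dataset_index(sim$dataset)
    # no detection where the sample truly holds no eDNA
    expect_true(all(idx$d_sample[sim$truth$a == 0] == 0))
    # no sample presence where the site is unoccupied
    expect_true(all(sim$truth$a[sim$truth$z[idx$site_of_sample] == 0] == 0))
  }
})

test_that("marginal frequencies converge to psi, psi*theta, psi*theta*p", {
  psi <- 0.7; theta <- 0.6; p <- 0.8
  sim <- simulate_multiscale(sim_params(
    10000, 1, 1, beta_psi = qnorm(psi), alpha_theta = qnorm(theta),
    delta_p = qnorm(p), seed = 77))
  idx <- occuDNA:::dataset_index(sim$dataset)
  n <- 10000
  mc3 <- 3 * sqrt(psi * (1 - psi) / n)
  expect_lt(abs(mean(sim$truth$z) - psi), mc3)
  expect_lt(abs(mean(sim$truth$a) - psi * theta),
            3 * sqrt(psi * theta * (1 - psi * theta) / n))
  expect_lt(abs(mean(idx$y) - psi * theta * p),
            3 * sqrt(psi * theta * p * (1 - psi * theta * p) / n))
})

test_that("covariates are generated then standardized like the analysis", {
  sim <- simulate_multiscale(sim_params(
    50, 2, 2, beta_psi = 1, alpha_theta = c(0.4, density = 1), delta_p = 1,
    covariates = list(density = function(n) rlnorm(n, 0, 1)), seed = 5))
  x <- sim$dataset$site_covariates$density
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_true("density.raw" %in% names(sim$dataset$site_covariates))
})

test_that("the field design preset mirrors the study layout", {
  params <- field_design(seed = 9)
  expect_equal(params$n_sites, 10L)
  expect_equal(sort(params$samples_per_site), c(3L, rep(6L, 9)))
  expect_true(all(params$replicates_per_sample == 3L))
  sim <- simulate_multiscale(params)
  expect_equal(nrow(sim$dataset$samples), 57L)
  expect_equal(nrow(sim$dataset$replicates), 171L)
  # density covariate is the observed one, not random
  expect_equal(sort(sim$dataset$site_covariates$density.raw),
               sort(field_sites()$density))
})

test_that("simulated site-level detection rates match the enumeration oracle", {
  # P(site has >= 1 detection) under the constant model, computed exactly
  psi <- 0.85; theta <- 0.6; p <- 0.75
  j <- 4; k <- 3
  p_site <- psi * (1 - (1 - theta * (1 - (1 - p)^k))^j)
  hits <- vapply(1:400, function(s) {
    sim <- simulate_multiscale(sim_params(
      5, j, k, beta_psi = qnorm(psi), alpha_theta = qnorm(theta),
      delta_p = qnorm(p), seed = 9000 + s))
    idx <- occuDNA:::dataset_index(sim$dataset)
    mean(idx$d_site > 0)
  }, numeric(1))
  mc_se <- sqrt(p_site * (1 - p_site) / (400 * 5))
  expect_lt(abs(mean(hits) - p_site), 3 * mc_se)
})

test_that("invalid generator output is rejected", {
  bad <- sim_params(5, 2, 2, beta_psi = 1, alpha_theta = 1, delta_p = 1,
                    covariates = list(x = function(n) rep(NA_real_, n)),
                    seed = 3)
  expect_error(simulate_multiscale(bad), "finite value per site")
  expect_error(sim_params(5, 2, 2, beta_psi = 1,
                          alpha_theta = c(1, 0.5), delta_p = 1, seed = 1),
               "named after generated covariates")
})
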