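const_coefs <- function(psi, theta, p) {
  list(beta_psi = qnorm(psi), alpha_theta = qnorm(theta), delta_p = qnorm(p))
}

test_that("marginal likelihood matches closed forms", {
  one <- survey_dataset(data.frame(site = "A", sample = "s1", replicate = 1,
                                   detection = 1))
  spec <- model_spec()
  expect_equal(multiscale_loglik(const_coefs(0.5, 0.5, 0.5), one, spec),
               log(0.125))
  # everything detected, probabilities -> 1: log-likelihood -> 0
  full <- survey_dataset(tiny_replicates(rep(1, 9)))
  ll <- multiscale_loglik(const_coefs(1 - 1e-12, 1 - 1e-12, 1 - 1e-12),
                          full, spec)
  expect_equal(ll, 0, tolerance = 1e-6)
  expect_error(
    multiscale_loglik(list(beta_psi = c(0, 1), alpha_theta = 0, delta_p = 0),
                      one, spec),
    "beta_psi")
})

test_that("marginal likelihood equals exhaustive latent-state enumeration", {
  set.seed(33)
  spec_plain <- model_spec()
  spec_cov <- model_spec(theta = ~ density)
  for (r in 1:12) {
    n_sites <- sample(2:3, 1)
    sps <- sample(2:3, 1)          # <= 3 + 9 = 12 latent binaries
    d <- random_dataset(n_sites, sps, reps = 2, seed = 100 + r)
    for (spec in list(spec_plain, spec_cov)) {
      coefs <- list(beta_psi = rnorm(1),
                    alpha_theta = rnorm(if (identical(spec, spec_cov)) 2 else 1),
                    delta_p = rnorm(1))
      expect_equal(multiscale_loglik(coefs, d, spec),
                   enumerate_multiscale_loglik(coefs, d, spec),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood skips missing replicates", {
  with_na <- survey_dataset(tiny_replicates(c(1, NA, 0, 0, NA, 0, 1, 0, 1)))
  dropped <- tiny_replicates(c(1, NA, 0, 0, NA, 0, 1, 0, 1))
  dropped <- survey_dataset(dropped[!is.na(dropped$detection), ])
  coefs <- const_coefs(0.7, 0.6, 0.5)
  expect_equal(multiscale_loglik(coefs, with_na, model_spec()),
               multiscale_loglik(coefs, dropped, model_spec()),
               tolerance = 1e-12)
})

test_that("degenerate covariates raise an error instead of being dropped", {
  d <- random_dataset(4, 2, reps = 2, seed = 9)
  d$site_covariates$flat <- 1
  expect_error(build_err <- sample_posterior(
    d, model_spec(theta = ~ flat),
    mcmc_config(200, 100, seed = 1)), "degenerate")
  expect_error(sample_posterior(d, model_spec(theta = ~ nothere),
                                mcmc_config(200, 100, seed = 1)),
               "theta formula")
})

test_that("sampler draws respect the latent hierarchy", {
  d <- random_dataset(8, 3, reps = 3, seed = 71)
  dr <- sample_posterior(d, model_spec(theta = ~ density),
                         mcmc_config(1500, 500, seed = 4))
  idx <- occuDNA:::dataset_index(d)
  # a = 0 wherever z = 0
  z_by_sample <- dr$z[, idx$site_of_sample]
  expect_true(all(dr$a[z_by_sample == 0L] == 0L))
  # z forced on at any site with an observed detection, a at any such sample
  expect_true(all(dr$z[, idx$d_site > 0] == 1L))
  expect_true(all(dr$a[, idx$d_sample > 0] == 1L))
  expect_equal(dr$n_draws, 1000L)
})

test_that("identical seed and config give bit-identical draws", {
  d <- random_dataset(5, 3, reps = 3, seed = 13)
  cfg <- mcmc_config(800, 200, seed = 99)
  dr1 <- sample_posterior(d, model_spec(theta = ~ density), cfg)
  dr2 <- sample_posterior(d, model_spec(theta = ~ density), cfg)
  expect_identical(dr1$beta_psi, dr2$beta_psi)
  expect_identical(dr1$alpha_theta, dr2$alpha_theta)
  expect_identical(dr1$delta_p, dr2$delta_p)
  expect_identical(dr1$z, dr2$z)
  dr3 <- sample_posterior(d, model_spec(theta = ~ density),
                          mcmc_config(800, 200, seed = 100))
  expect_false(identical(dr1$beta_psi, dr3$beta_psi))

  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(dr1, path)
  exported <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(exported), dr1$n_draws)
  expect_equal(exported[["alpha_theta:density"]],
               unname(dr1$alpha_theta[, "density"]))
})

test_that("theta responds monotonically to density under a positive slope", {
  d <- random_dataset(6, 4, reps = 3, seed = 55)
  dr <- sample_posterior(d, model_spec(theta = ~ density),
                         mcmc_config(1200, 200, seed = 8))
  th <- derived_probabilities(dr, d, "theta")
  dens <- d$site_covariates$density[d$samples$site_idx]
  ord <- order(dens)
  pos_slope <- dr$alpha_theta[, "density"] > 0
  diffs <- th[pos_slope, ord, drop = FALSE]
  expect_true(all(diffs[, -1] - diffs[, -ncol(diffs)] >= -1e-12))
})

test_that("an all-positive dataset pushes every probability up", {
  d <- survey_dataset(do.call(rbind, lapply(1:6, function(i) {
    data.frame(site = paste0("S", i), sample = rep(c("a", "b"), each = 3),
               replicate = rep(1:3, 2), detection = 1)
  })))
  dr <- sample_posterior(d, model_spec(), mcmc_config(2000, 500, seed = 2))
  s <- summarize_draws(dr, transform = pnorm)
  expect_true(all(s$median > 0.9))
})

test_that("with flat priors the collapsed posterior approaches the MLE", {
  # one certainly-occupied site: the sample/replicate layers of the
  # three-level model reduce to the two-level occupancy model, with theta in
  # the role of occupancy and p in the role of detection
  set.seed(500)
  n <- 120
  occ <- rbinom(n, 1, 0.8)
  d_counts <- rbinom(n, 3, occ * 0.7)
  reps <- data.frame(site = "only",
                     sample = rep(sprintf("s%03d", 1:n), each = 3),
                     replicate = rep(1:3, n),
                     detection = as.integer(sequence(rep(3, n)) <=
                                              rep(d_counts, each = 3)))
  d2 <- survey_dataset(reps)
  mle <- fit_classic(classic_histories(d_counts, 3))
  dr <- sample_posterior(d2, model_spec(),
                         mcmc_config(6000, 1000, seed = 3, prior_sd = 10))
  theta_med <- median(pnorm(dr$alpha_theta[, 1]))
  p_med <- median(pnorm(dr$delta_p[, 1]))
  expect_equal(theta_med, mle$psi_hat, tolerance = 0.02)
  expect_equal(p_med, mle$p_hat, tolerance = 0.02)
})

test_that("posterior summaries and the effect flag behave", {
  const <- matrix(0.3, nrow = 200, ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_draws(const)
  expect_equal(s$median, 0.3)
  expect_equal(s$cri_lower, s$cri_upper)
  expect_error(summarize_draws(matrix(numeric(0), 0, 1)), "no draws")

  expect_true(covariate_effect_flag(data.frame(cri_lower = 0.306,
                                               cri_upper = 1.896)))
  expect_false(covariate_effect_flag(data.frame(cri_lower = -0.2,
                                                cri_upper = 0.4)))
  expect_false(covariate_effect_flag(data.frame(cri_lower = 0,
                                                cri_upper = 0.5)))

  # transform is applied per draw before summarizing
  set.seed(1)
  x <- matrix(rnorm(500), ncol = 1)
  s2 <- summarize_draws(x, transform = pnorm)
  expect_equal(s2$median, median(pnorm(x)))
  expect_equal(s2$cri_lower, unname(quantile(pnorm(x), 0.025)))
})
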