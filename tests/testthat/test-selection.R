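# hand-built posterior_draws object for criterion unit tests
fake_draws <- function(dataset, spec, delta_p, alpha_theta = NULL,
                       beta_psi = NULL, a = NULL, z = NULL) {
  idx <- occuDNA:::dataset_index(dataset)
  n <- nrow(delta_p)
  if (is.null(beta_psi)) beta_psi <- matrix(5, n, 1)
  if (is.null(alpha_theta)) alpha_theta <- matrix(5, n, 1)
  if (is.null(a)) a <- matrix(1L, n, idx$n_samples)
  if (is.null(z)) z <- matrix(1L, n, idx$n_sites)
  colnames(beta_psi) <- "(Intercept)"
  colnames(alpha_theta) <- "(Intercept)"
  colnames(delta_p) <- "(Intercept)"
  structure(list(beta_psi = beta_psi, alpha_theta = alpha_theta,
                 delta_p = delta_p, z = z, a = a, spec = spec,
                 config = mcmc_config(2, 1, seed = 1), n_draws = n),
            class = "posterior_draws")
}

test_that("WAIC collapses correctly for a degenerate point-mass posterior", {
  d <- survey_dataset(data.frame(site = "A", sample = "s1", replicate = 1,
                                 detection = 1))
  dr <- fake_draws(d, model_spec(), delta_p = matrix(qnorm(0.5), 200, 1))
  w <- suppressWarnings(waic(dr, d))
  # single Bernoulli y = 1 with certain latent presence and p = 0.5:
  # lppd = log 0.5, pWAIC = 0
  expect_equal(w$lppd, log(0.5), tolerance = 1e-9)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  expect_equal(w$criterion, -log(0.5), tolerance = 1e-9)
  w2 <- suppressWarnings(waic(dr, d, scale = "deviance"))
  expect_equal(w2$criterion, -2 * log(0.5), tolerance = 1e-9)
})

test_that("PPLC is zero for perfect point-mass predictions", {
  reps <- tiny_replicates(rep(1, 9))
  d <- survey_dataset(reps)
  dr <- fake_draws(d, model_spec(), delta_p = matrix(20, 150, 1))
  pl <- suppressWarnings(pplc(dr, d))
  expect_equal(pl$criterion, 0, tolerance = 1e-9)
  pl2 <- suppressWarnings(pplc(dr, d, unit = "replicate"))
  expect_equal(pl2$criterion, 0, tolerance = 1e-9)
})

test_that("PPLC matches closed-form Beta posterior moments", {
  # two observed replicates in one certainly-present sample, p ~ Beta(a, b):
  # per replicate m = E[p], predictive variance = m(1 - m)
  a_par <- 3; b_par <- 2
  set.seed(42)
  p_draws <- rbeta(200000, a_par, b_par)
  d <- survey_dataset(data.frame(site = "A", sample = "s1", replicate = 1:2,
                                 detection = c(1, 0)))
  dr <- fake_draws(d, model_spec(), delta_p = matrix(qnorm(p_draws), ncol = 1))
  m <- a_par / (a_par + b_par)
  pl <- pplc(dr, d, unit = "replicate")
  expect_equal(pl$gof, (1 - m)^2 + m^2, tolerance = 0.005)
  expect_equal(pl$p_var, 2 * m * (1 - m), tolerance = 0.005)
  # count version: d = 1 of 2, E[d_rep] = 2m, Var = 2E[p(1-p)] + 4Var(p)
  pl_count <- pplc(dr, d)
  ep1p <- m - (a_par * (a_par + 1)) / ((a_par + b_par) * (a_par + b_par + 1))
  vp <- a_par * b_par / ((a_par + b_par)^2 * (a_par + b_par + 1))
  expect_lt(abs(pl_count$gof - (1 - 2 * m)^2), 0.005)
  expect_lt(abs(pl_count$p_var - (2 * ep1p + 4 * vp)), 0.01)
})

test_that("criteria are invariant to the order of posterior draws", {
  d <- random_dataset(5, 3, reps = 3, seed = 20)
  dr <- sample_posterior(d, model_spec(theta = ~ density),
                         mcmc_config(1200, 200, seed = 6))
  o <- sample(dr$n_draws)
  dr2 <- dr
  for (f in c("beta_psi", "alpha_theta", "delta_p", "z", "a")) {
    dr2[[f]] <- dr[[f]][o, , drop = FALSE]
  }
  expect_equal(waic(dr, d)$criterion, waic(dr2, d)$criterion,
               tolerance = 1e-10)
  expect_equal(pplc(dr, d)$criterion, pplc(dr2, d)$criterion,
               tolerance = 1e-10)
  # finite whenever probabilities are interior
  expect_true(is.finite(waic(dr, d, method = "marginal")$criterion))
  expect_true(is.finite(waic(dr, d, unit = "site")$criterion))
})

test_that("a pure-noise covariate does not reduce the WAIC penalty on average", {
  set.seed(77)
  diffs <- replicate(12, {
    sim <- simulate_multiscale(sim_params(
      15, 4, 3, beta_psi = 1.3, alpha_theta = 0.45, delta_p = 1.2,
      covariates = list(noise = function(n) rnorm(n)),
      seed = sample.int(1e6, 1)))
    d <- sim$dataset
    cfg0 <- mcmc_config(1500, 500, seed = 11)
    dr0 <- sample_posterior(d, model_spec(), cfg0)
    dr1 <- sample_posterior(d, model_spec(theta = ~ noise), cfg0)
    waic(dr1, d)$p_waic - waic(dr0, d)$p_waic
  })
  expect_gt(mean(diffs), 0)
})

test_that("model ranking is stable, tie-broken, and permutation-invariant", {
  mk <- function(model, waic, pplc, n_coef) {
    structure(list(model = model, waic = waic, waic_pvar = 1,
                   pplc = pplc, pplc_pvar = 1, n_coef = n_coef,
                   spec = NULL), class = "model_score")
  }
  scores <- list(mk("big", 30.0, 26.0, 5), mk("small", 30.0, 26.5, 3),
                 mk("worst", 34.0, 28.0, 4), mk("best", 29.0, 25.0, 3))
  tab <- rank_models(scores)
  expect_equal(tab$model, c("best", "small", "big", "worst"))
  tab2 <- rank_models(rev(scores))
  expect_equal(tab2$model, tab$model)
  expect_equal(tab$pplc_rank[1], 1L)
  expect_error(rank_models(scores[1]), "at least two")
})
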