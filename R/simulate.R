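#' Parameters for simulating nested eDNA detection data
#'
#' Defines the generative three-level Bernoulli process: site occurrence
#' `z_i ~ Bern(psi_i)`, conditional per-sample presence
#' `a_ij | z_i ~ Bern(z_i * theta_ij)`, and conditional per-replicate
#' detection `y_ijk | a_ij ~ Bern(a_ij * p_ijk)`, with probit-linear
#' covariate effects. Coefficient vectors are named: the first element is the
#' intercept and subsequent elements are named after covariates supplied via
#' `covariates`. Covariates are generated per site, then scaled and centred
#' exactly as the analysis pipeline would, so simulated slopes are directly
#' comparable to fitted ones.
#'
#' @param n_sites Number of sites.
#' @param samples_per_site Scalar or length-`n_sites` vector of water samples
#'   per site (ragged designs supported).
#' @param replicates_per_sample Scalar or per-sample vector of qPCR
#'   replicates.
#' @param beta_psi,alpha_theta,delta_p Probit-scale coefficient vectors. A
#'   scalar is an intercept-only model; longer vectors must be named after
#'   the generated covariates (e.g. `c(0.45, density = 1.0)`).
#' @param covariates Named list of generator functions, each called with the
#'   number of sites and returning one value per site
#'   (e.g. `list(density = function(n) rlnorm(n, -0.7, 1))`).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_sites, samples_per_site, replicates_per_sample,
                       beta_psi, alpha_theta, delta_p,
                       covariates = list(), seed) {
  if (missing(seed)) stop("an explicit seed is required")
  samples_per_site <- rep_len(as.integer(samples_per_site), n_sites)
  n_samples <- sum(samples_per_site)
  replicates_per_sample <- rep_len(as.integer(replicates_per_sample), n_samples)
  check_names <- function(b, nm) {
    if (length(b) > 1) {
      extra <- names(b)[-1]
      if (is.null(extra) || any(!nzchar(extra)) ||
          !all(extra %in% names(covariates))) {
        stop(nm, " slopes must be named after generated covariates")
      }
    }
  }
  check_names(beta_psi, "beta_psi")
  check_names(alpha_theta, "alpha_theta")
  check_names(delta_p, "delta_p")
  structure(list(n_sites = as.integer(n_sites),
                 samples_per_site = samples_per_site,
                 replicates_per_sample = replicates_per_sample,
                 beta_psi = beta_psi, alpha_theta = alpha_theta,
                 delta_p = delta_p, covariates = covariates,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a nested eDNA survey dataset
#'
#' Draws one dataset from the three-level Bernoulli hierarchy described in
#' [sim_params()] and returns it together with the latent truth, for
#' parameter-recovery studies and tests. Two-level data are the special case
#' of one sample per site (or one replicate per sample).
#'
#' @param params A [sim_params()].
#' @return A list with `dataset` (a [survey_dataset()] with standardized
#'   site covariates), `truth` (list with latent `z`, `a`, the probability
#'   vectors `psi`, `theta`, `p`, and `params`).
#' @examples
#' ps <- sim_params(20, 6, 3, beta_psi = 1.28,
#'                  alpha_theta = c(0.45, density = 1),
#'                  delta_p = 1.17,
#'                  covariates = list(density = function(n) rlnorm(n, -0.7, 1)),
#'                  seed = 1)
#' sim <- simulate_multiscale(ps)
#' @export
simulate_multiscale <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_sites <- params$n_sites
  cov_vals <- lapply(params$covariates, function(g) {
    v <- g(n_sites)
    if (length(v) != n_sites || any(!is.finite(v))) {
      stop("covariate generator must return one finite value per site")
    }
    v
  })

  site_ids <- sprintf("site%03d", seq_len(n_sites))
  site_cov <- NULL
  if (length(cov_vals) > 0) {
    site_cov <- data.frame(site = site_ids, stringsAsFactors = FALSE)
    site_cov[names(cov_vals)] <- cov_vals
  }

  site_of_sample <- rep(seq_len(n_sites), params$samples_per_site)
  n_samples <- length(site_of_sample)
  sample_of_rep <- rep(seq_len(n_samples), params$replicates_per_sample)
  n_reps <- length(sample_of_rep)

  # standardized covariates enter the linear predictors, as in the analysis
  std <- lapply(cov_vals, function(v) (v - mean(v)) / stats::sd(v))
  linpred <- function(b, rows) {
    lp <- rep(b[1], length(rows))
    if (length(b) > 1) {
      for (nm in names(b)[-1]) lp <- lp + b[[nm]] * std[[nm]][rows]
    }
    lp
  }
  psi <- stats::pnorm(linpred(params$beta_psi, seq_len(n_sites)))
  theta <- stats::pnorm(linpred(params$alpha_theta, site_of_sample))
  p <- stats::pnorm(linpred(params$delta_p, site_of_sample[sample_of_rep]))

  z <- stats::rbinom(n_sites, 1, psi)
  a <- stats::rbinom(n_samples, 1, z[site_of_sample] * theta)
  y <- stats::rbinom(n_reps, 1, a[sample_of_rep] * p)

  rep_index <- sequence(params$replicates_per_sample)
  reps <- data.frame(
    site = site_ids[site_of_sample[sample_of_rep]],
    sample = sprintf("%s-s%02d", site_ids[site_of_sample[sample_of_rep]],
                     sequence(params$samples_per_site)[sample_of_rep]),
    replicate = rep_index,
    detection = y,
    stringsAsFactors = FALSE)

  dataset <- survey_dataset(reps, site_covariates = site_cov)
  if (length(cov_vals) > 0) {
    dataset <- standardize_covariates(dataset, names(cov_vals))
  }
  list(dataset = dataset,
       truth = list(z = z, a = a, psi = psi, theta = theta, p = p,
                    params = params))
}

#' Simulation preset mirroring the field-control study design
#'
#' Returns [sim_params()] for the layout of the ten-site field control:
#' nine sites with six 1 L water samples and one (the well site) with three,
#' three qPCR replicates per sample, and the observed salamander relative
#' densities as a fixed site covariate. Coefficients default to the top
#' model's posterior medians, so the preset simulates the fitted data
#' generating process at the study's own scale.
#'
#' @param beta_psi,alpha_theta,delta_p Probit-scale truth; defaults are the
#'   field-control top-model posterior medians.
#' @param seed Mandatory integer seed.
#' @return A [sim_params()] whose `density` covariate generator returns the
#'   ten observed relative densities (fixed, not random).
#' @export
field_design <- function(beta_psi = 1.542,
                         alpha_theta = c(0.452, density = 1.014),
                         delta_p = 1.185, seed) {
  dens <- field_sites()$density
  sim_params(n_sites = 10,
             samples_per_site = ifelse(field_sites()$site == "Cobbs Well", 3, 6),
             replicates_per_sample = 3,
             beta_psi = beta_psi, alpha_theta = alpha_theta,
             delta_p = delta_p,
             covariates = list(density = function(n) dens),
             seed = seed)
}
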