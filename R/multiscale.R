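#' Multiscale occupancy model specification
#'
#' Declares the covariates entering each level of the three-level multiscale
#' occupancy model as one-sided formulas: site occurrence `psi`, conditional
#' per-sample collection `theta`, and conditional per-replicate detection
#' `p`. Each linear predictor implicitly includes an intercept and is mapped
#' to a probability through the probit link. Covariates on `psi` resolve in
#' the site covariate table; covariates on `theta` and `p` resolve in the
#' sample-level table (site covariates broadcast to samples, plus any
#' sample-level covariates).
#'
#' @param psi,theta,p One-sided formulas, e.g. `theta = ~ density`.
#' @param name Optional label used in model-selection tables; defaults to the
#'   conventional `psi(.)theta(density)p(.)` notation.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(theta = ~ density)
#' @export
model_spec <- function(psi = ~ 1, theta = ~ 1, p = ~ 1, name = NULL) {
  spec <- structure(list(psi = stats::as.formula(psi),
                         theta = stats::as.formula(theta),
                         p = stats::as.formula(p)),
                    class = "model_spec")
  spec$name <- if (is.null(name)) spec_label(spec) else name
  spec
}

spec_label <- function(spec) {
  lab <- function(f) {
    v <- attr(stats::terms(f), "term.labels")
    if (length(v) == 0) "." else paste(v, collapse = " + ")
  }
  sprintf("psi(%s)theta(%s)p(%s)", lab(spec$psi), lab(spec$theta), lab(spec$p))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Multiscale occupancy model:", x$name, "\n")
  invisible(x)
}

#' MCMC configuration for the multiscale sampler
#'
#' @param iterations Total Gibbs iterations (default 50000).
#' @param burn_in Iterations discarded as burn-in (default 5000; must be
#'   smaller than `iterations`).
#' @param thin Thinning interval (default 1, i.e. no thinning).
#' @param seed Integer seed; mandatory so every run is reproducible.
#' @param prior_sd Standard deviation of the independent zero-mean normal
#'   priors on all probit-scale coefficients (default 1).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 50000, burn_in = 5000, thin = 1,
                        seed, prior_sd = 1) {
  if (missing(seed)) stop("an explicit seed is required")
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (burn_in < 0 || thin < 1) stop("invalid burn_in or thin")
  if (prior_sd <= 0) stop("prior_sd must be positive")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), prior_sd = prior_sd),
            class = "mcmc_config")
}

# Build probit design matrices for the three levels.
# psi: one row per site; theta: one row per sample; p: one row per replicate.
build_designs <- function(dataset, spec) {
  stopifnot(inherits(dataset, "survey_dataset"),
            inherits(spec, "model_spec"))
  site_tab <- dataset$site_covariates
  if (is.null(site_tab)) {
    site_tab <- data.frame(site = dataset$sites, stringsAsFactors = FALSE)
  }
  sample_tab <- site_tab[dataset$samples$site_idx, , drop = FALSE]
  sample_tab$sample <- dataset$samples$sample
  if (!is.null(dataset$sample_covariates)) {
    extra <- dataset$sample_covariates
    extra_cols <- setdiff(names(extra), c("site", "sample"))
    sample_tab[extra_cols] <- extra[extra_cols]
  }
  rep_tab <- sample_tab[dataset$replicates$sample_idx, , drop = FALSE]

  mm <- function(f, tab, level) {
    X <- tryCatch(stats::model.matrix(f, data = tab),
                  error = function(e) {
                    stop("cannot resolve ", level, " formula covariates: ",
                         conditionMessage(e), call. = FALSE)
                  })
    nonconst <- apply(X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE],
                      2, function(col) stats::sd(col) > 0)
    if (length(nonconst) > 0 && !all(nonconst)) {
      stop("degenerate (constant) covariate in ", level, " formula")
    }
    X
  }
  list(X_psi = mm(spec$psi, site_tab, "psi"),
       X_theta = mm(spec$theta, sample_tab, "theta"),
       X_p = mm(spec$p, rep_tab, "p"))
}

# Precomputed index structures used by the likelihood and the sampler
dataset_index <- function(dataset) {
  reps <- dataset$replicates
  obs <- !is.na(reps$detection)
  n_samples <- nrow(dataset$samples)
  n_sites <- length(dataset$sites)
  sample_of_rep <- reps$sample_idx[obs]
  y <- reps$detection[obs]
  d_sample <- as.integer(rowsum(y, factor(sample_of_rep, levels = seq_len(n_samples))))
  n_sample <- as.integer(table(factor(sample_of_rep, levels = seq_len(n_samples))))
  site_of_sample <- dataset$samples$site_idx
  d_site <- as.integer(rowsum(d_sample, factor(site_of_sample, levels = seq_len(n_sites))))
  list(obs = obs, y = y, sample_of_rep = sample_of_rep,
       site_of_sample = site_of_sample,
       d_sample = d_sample, n_sample = n_sample, d_site = d_site,
       n_sites = n_sites, n_samples = n_samples)
}

#' Marginal log-likelihood of the multiscale occupancy model
#'
#' Computes the observed-data log-likelihood with both latent layers (site
#' occurrence `z` and per-sample presence `a`) summed out analytically. Per
#' site `i`:
#' `log( psi_i * prod_j [ theta_ij * prod_k Bern(y_ijk; p_ijk) +
#' (1 - theta_ij) * 1{all y_ij. = 0} ] + (1 - psi_i) * 1{all y_i.. = 0} )`.
#' Missing replicates are skipped. Probabilities come from the probit link
#' applied to the linear predictors defined by `spec`.
#'
#' @param coefs Named list with numeric vectors `beta_psi`, `alpha_theta`,
#'   `delta_p` conforming to the design matrices implied by `spec`.
#' @param dataset A [survey_dataset()].
#' @param spec A [model_spec()].
#' @return The marginal log-likelihood.
#' @export
multiscale_loglik <- function(coefs, dataset, spec) {
  ds <- build_designs(dataset, spec)
  check_len <- function(b, X, nm) {
    if (length(b) != ncol(X)) {
      stop(sprintf("%s has length %d but design has %d columns",
                   nm, length(b), ncol(X)))
    }
  }
  check_len(coefs$beta_psi, ds$X_psi, "beta_psi")
  check_len(coefs$alpha_theta, ds$X_theta, "alpha_theta")
  check_len(coefs$delta_p, ds$X_p, "delta_p")
  idx <- dataset_index(dataset)
  psi <- stats::pnorm(drop(ds$X_psi %*% coefs$beta_psi))
  theta <- stats::pnorm(drop(ds$X_theta %*% coefs$alpha_theta))
  lin_p <- drop(ds$X_p %*% coefs$delta_p)[idx$obs]
  log_p <- stats::pnorm(lin_p, log.p = TRUE)
  log_q <- stats::pnorm(-lin_p, log.p = TRUE)
  f_sample <- as.numeric(rowsum(ifelse(idx$y == 1, log_p, log_q),
                                factor(idx$sample_of_rep,
                                       levels = seq_len(idx$n_samples))))
  zero_sample <- idx$d_sample == 0
  g <- theta * exp(f_sample) + (1 - theta) * zero_sample
  log_g_site <- as.numeric(rowsum(log(g),
                                  factor(idx$site_of_sample,
                                         levels = seq_len(idx$n_sites))))
  zero_site <- idx$d_site == 0
  sum(log(psi * exp(log_g_site) + (1 - psi) * zero_site))
}

# one truncated-normal draw per unit: u ~ N(mu, 1) constrained to the sign
# implied by the binary response (Albert-Chib augmentation)
rtruncnorm_sign <- function(mu, positive) {
  p0 <- stats::pnorm(-mu)             # P(u < 0)
  v <- stats::runif(length(mu))
  q <- ifelse(positive, p0 + v * (1 - p0), v * p0)
  q <- pmin(pmax(q, 1e-15), 1 - 1e-15)
  mu + stats::qnorm(q)
}

# conjugate draw of probit coefficients given latent utilities u and design X
draw_coefs <- function(X, u, prior_prec) {
  k <- ncol(X)
  V_inv <- crossprod(X) + diag(prior_prec, k)
  R <- chol(V_inv)
  mean_part <- backsolve(R, forwardsolve(t(R), crossprod(X, u)))
  mean_part + backsolve(R, stats::rnorm(k))
}

#' Draw from the posterior of the multiscale occupancy model
#'
#' Gibbs sampler for the three-level multiscale occupancy model with
#' probit-linear covariates and independent `N(0, prior_sd^2)` priors on all
#' coefficients. Each sweep updates (i) the per-sample presence indicators
#' `a` from their exact Bernoulli full conditionals, (ii) the site occurrence
#' indicators `z` likewise, and (iii) each coefficient block by Albert–Chib
#' truncated-normal data augmentation, which makes every update an exact
#' draw from its full conditional — no proposal tuning is involved. Runs are
#' bit-reproducible given `config$seed`.
#'
#' @param dataset A [survey_dataset()].
#' @param spec A [model_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `posterior_draws`: list with coefficient draw
#'   matrices `beta_psi`, `alpha_theta`, `delta_p` (one row per retained
#'   draw, columns named after design columns), latent draw matrices `z`
#'   (draws × sites) and `a` (draws × samples), plus `spec`, `config` and
#'   `n_draws`.
#' @export
sample_posterior <- function(dataset, spec, config) {
  stopifnot(inherits(config, "mcmc_config"))
  ds <- build_designs(dataset, spec)
  idx <- dataset_index(dataset)
  if (sum(idx$y) == 0) {
    warning("no detections anywhere: posterior is prior-dominated")
  }
  set.seed(config$seed)
  prior_prec <- 1 / config$prior_sd^2
  n_sites <- idx$n_sites
  n_samples <- idx$n_samples
  site_f <- factor(idx$site_of_sample, levels = seq_len(n_sites))

  # initial state: latent presence wherever there is a detection
  z <- as.integer(idx$d_site > 0 | TRUE)      # start all present
  a <- as.integer(idx$d_sample > 0 | TRUE)
  beta_psi <- numeric(ncol(ds$X_psi))
  alpha_theta <- numeric(ncol(ds$X_theta))
  delta_p <- numeric(ncol(ds$X_p))

  keep <- seq(config$burn_in + 1, config$iterations, by = config$thin)
  n_keep <- length(keep)
  out_bpsi <- matrix(NA_real_, n_keep, ncol(ds$X_psi),
                     dimnames = list(NULL, colnames(ds$X_psi)))
  out_ath <- matrix(NA_real_, n_keep, ncol(ds$X_theta),
                    dimnames = list(NULL, colnames(ds$X_theta)))
  out_dp <- matrix(NA_real_, n_keep, ncol(ds$X_p),
                   dimnames = list(NULL, colnames(ds$X_p)))
  out_z <- matrix(NA_integer_, n_keep, n_sites,
                  dimnames = list(NULL, dataset$sites))
  out_a <- matrix(NA_integer_, n_keep, n_samples)
  slot <- 0L

  lin_psi <- drop(ds$X_psi %*% beta_psi)
  lin_theta <- drop(ds$X_theta %*% alpha_theta)
  lin_p_all <- drop(ds$X_p %*% delta_p)
  obs_lin_p <- lin_p_all[idx$obs]
  forced_a <- idx$d_sample > 0
  forced_z <- idx$d_site > 0
  sample_f <- factor(idx$sample_of_rep, levels = seq_len(n_samples))
  Xp_obs <- ds$X_p[idx$obs, , drop = FALSE]

  for (it in seq_len(config$iterations)) {
    psi <- stats::pnorm(lin_psi)
    theta <- stats::pnorm(lin_theta)
    # P(all replicates of sample j negative | a_j = 1)
    log_q0 <- as.numeric(rowsum(stats::pnorm(-obs_lin_p, log.p = TRUE),
                                sample_f))
    q0 <- exp(log_q0)

    # a | z, y: forced 1 where the sample has a detection; 0 where z_site = 0
    pr_a <- theta * q0 / (theta * q0 + (1 - theta))
    a <- ifelse(forced_a, 1L,
                ifelse(z[idx$site_of_sample] == 1L,
                       as.integer(stats::runif(n_samples) < pr_a), 0L))

    # z | a: forced 1 where any a = 1 at the site
    any_a <- as.integer(rowsum(a, site_f)) > 0
    log_none <- as.numeric(rowsum(log1p(-theta), site_f))
    pr_z <- psi * exp(log_none) / (psi * exp(log_none) + (1 - psi))
    z <- ifelse(forced_z | any_a, 1L,
                as.integer(stats::runif(n_sites) < pr_z))

    # beta_psi | z  (probit regression over all sites)
    u <- rtruncnorm_sign(lin_psi, z == 1L)
    beta_psi <- draw_coefs(ds$X_psi, u, prior_prec)
    lin_psi <- drop(ds$X_psi %*% beta_psi)

    # alpha_theta | a, z  (probit regression over samples in occupied sites)
    rows <- which(z[idx$site_of_sample] == 1L)
    u <- rtruncnorm_sign(lin_theta[rows], a[rows] == 1L)
    alpha_theta <- draw_coefs(ds$X_theta[rows, , drop = FALSE], u, prior_prec)
    lin_theta <- drop(ds$X_theta %*% alpha_theta)

    # delta_p | y, a  (probit regression over replicates in present samples)
    rep_rows <- which(a[idx$sample_of_rep] == 1L)
    u <- rtruncnorm_sign(obs_lin_p[rep_rows], idx$y[rep_rows] == 1L)
    delta_p <- draw_coefs(Xp_obs[rep_rows, , drop = FALSE], u, prior_prec)
    lin_p_all <- drop(ds$X_p %*% delta_p)
    obs_lin_p <- lin_p_all[idx$obs]

    if (it > config$burn_in && (it - config$burn_in - 1L) %% config$thin == 0L) {
      slot <- slot + 1L
      out_bpsi[slot, ] <- beta_psi
      out_ath[slot, ] <- alpha_theta
      out_dp[slot, ] <- delta_p
      out_z[slot, ] <- z
      out_a[slot, ] <- a
    }
  }

  structure(list(beta_psi = out_bpsi, alpha_theta = out_ath, delta_p = out_dp,
                 z = out_z, a = out_a, spec = spec, config = config,
                 n_draws = n_keep),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", x$spec$name, "\n")
  cat(sprintf("  %d retained draws (%d iterations, burn-in %d, thin %d)\n",
              x$n_draws, x$config$iterations, x$config$burn_in,
              x$config$thin))
  invisible(x)
}

#' Derived probability draws at each level
#'
#' Maps coefficient draws through the probit link onto per-unit
#' probabilities: site-level occurrence `psi_i`, sample-level collection
#' `theta_ij`, or replicate-level detection `p_ijk`.
#'
#' @param draws A [sample_posterior()] result.
#' @param dataset The dataset the draws were fit to.
#' @param level `"psi"`, `"theta"` or `"p"`.
#' @return A matrix, draws × units at the requested level.
#' @export
derived_probabilities <- function(draws, dataset, level = c("psi", "theta", "p")) {
  level <- match.arg(level)
  ds <- build_designs(dataset, draws$spec)
  switch(level,
         psi = stats::pnorm(draws$beta_psi %*% t(ds$X_psi)),
         theta = stats::pnorm(draws$alpha_theta %*% t(ds$X_theta)),
         p = stats::pnorm(draws$delta_p %*% t(ds$X_p)))
}

#' Summarize posterior draws
#'
#' Posterior mean, median, equal-tailed 95% credible interval and Monte
#' Carlo standard error (batch means) per parameter, optionally after a
#' per-draw transform (e.g. `pnorm` to summarize probabilities instead of
#' probit-scale coefficients).
#'
#' @param draws A matrix (draws × parameters), numeric vector, or
#'   [sample_posterior()] result (all coefficient blocks are summarized).
#' @param transform Optional function applied to the draws first.
#' @return A data frame with columns `parameter`, `mean`, `median`,
#'   `cri_lower`, `cri_upper`, `mcse`.
#' @export
summarize_draws <- function(draws, transform = NULL) {
  if (inherits(draws, "posterior_draws")) {
    m <- cbind(beta_psi = draws$beta_psi, alpha_theta = draws$alpha_theta,
               delta_p = draws$delta_p)
    colnames(m) <- c(paste0("beta_psi:", colnames(draws$beta_psi)),
                     paste0("alpha_theta:", colnames(draws$alpha_theta)),
                     paste0("delta_p:", colnames(draws$delta_p)))
    draws <- m
  }
  if (is.vector(draws) && is.numeric(draws)) {
    draws <- matrix(draws, ncol = 1, dimnames = list(NULL, "value"))
  }
  if (nrow(draws) == 0) stop("no draws to summarize")
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  }
  if (!is.null(transform)) draws <- apply(draws, 2, transform)
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             median = q[2, ],
             cri_lower = q[1, ],
             cri_upper = q[3, ],
             mcse = apply(draws, 2, mcse_batch_means),
             row.names = NULL)
}

# Monte Carlo standard error of the posterior mean via batch means
mcse_batch_means <- function(x) {
  n <- length(x)
  nb <- max(2L, floor(sqrt(n)))
  size <- n %/% nb
  if (size < 1) return(NA_real_)
  bm <- colMeans(matrix(x[seq_len(nb * size)], nrow = size))
  stats::sd(bm) / sqrt(nb)
}

#' Export posterior coefficient draws as CSV
#'
#' Writes one row per retained iteration with one column per probit-scale
#' coefficient (named `beta_psi:...`, `alpha_theta:...`, `delta_p:...`),
#' for external convergence diagnostics.
#'
#' @param draws A [sample_posterior()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- cbind(draws$beta_psi, draws$alpha_theta, draws$delta_p)
  colnames(m) <- c(paste0("beta_psi:", colnames(draws$beta_psi)),
                   paste0("alpha_theta:", colnames(draws$alpha_theta)),
                   paste0("delta_p:", colnames(draws$delta_p)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Is a covariate effect supported?
#'
#' A slope is considered supported when its 95% credible interval excludes
#' zero; an interval with zero exactly on an endpoint is not support.
#'
#' @param summary One row of [summarize_draws()] output (or any list/data
#'   frame with `cri_lower` and `cri_upper`).
#' @return Logical.
#' @examples
#' covariate_effect_flag(data.frame(cri_lower = 0.306, cri_upper = 1.896))
#' @export
covariate_effect_flag <- function(summary) {
  lower <- summary$cri_lower
  upper <- summary$cri_upper
  unname(lower > 0 | upper < 0)
}
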