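# incidence matrix: units (rows) -> groups (cols)
incidence <- function(group, n_groups, weight = NULL) {
  M <- matrix(0, length(group), n_groups)
  w <- if (is.null(weight)) 1 else weight
  M[cbind(seq_along(group), group)] <- w
  M
}

# per-sample detection probability, draws x samples; requires (and checks)
# that p covariates do not vary within a sample
p_by_sample <- function(draws, ds, idx) {
  Xp_obs <- ds$X_p[idx$obs, , drop = FALSE]
  first <- match(seq_len(idx$n_samples), idx$sample_of_rep)
  first[is.na(first)] <- 1L  # fully-missing sample: dbinom(0, 0, p) = 1 anyway
  for (j in seq_len(idx$n_samples)) {
    rows <- which(idx$sample_of_rep == j)
    if (length(rows) > 1 &&
        max(abs(sweep(Xp_obs[rows, , drop = FALSE], 2, Xp_obs[rows[1], ]))) > 0) {
      stop("count-based criteria require p covariates constant within a sample")
    }
  }
  stats::pnorm(draws$delta_p %*% t(Xp_obs[first, , drop = FALSE]))
}

# Conditional pointwise likelihood matrix (draws x units): the detection
# count of each water sample given that draw's latent presence state.
# unit = "sample": L_j = a_j * dbinom(d_j; n_j, p_j) + (1 - a_j) * 1{d_j = 0}.
# unit = "site":   L_i = z_i * prod_j [theta_ij dbinom_j + (1-theta_ij) 1{d_j=0}]
#                        + (1 - z_i) * 1{site all zero}.
conditional_loglik <- function(draws, dataset, unit = c("sample", "site")) {
  unit <- match.arg(unit)
  ds <- build_designs(dataset, draws$spec)
  idx <- dataset_index(dataset)
  P <- p_by_sample(draws, ds, idx)
  n <- draws$n_draws
  DB <- matrix(NA_real_, n, idx$n_samples)
  for (j in seq_len(idx$n_samples)) {
    DB[, j] <- stats::dbinom(idx$d_sample[j], idx$n_sample[j], P[, j])
  }
  if (unit == "sample") {
    zero <- rep(as.numeric(idx$d_sample == 0), each = n)
    return(log(draws$a * DB + (1 - draws$a) * zero))
  }
  TH <- stats::pnorm(draws$alpha_theta %*% t(ds$X_theta))
  zero_s <- rep(as.numeric(idx$d_sample == 0), each = n)
  mix <- log(TH * DB + (1 - TH) * zero_s)
  Msite <- incidence(idx$site_of_sample, idx$n_sites)
  S <- mix %*% Msite
  zero_i <- rep(as.numeric(idx$d_site == 0), each = n)
  log(draws$z * exp(S) + (1 - draws$z) * zero_i)
}

# Marginal pointwise log-likelihood matrix (draws x units) with both latent
# layers summed out analytically (replicate-level Bernoulli detail).
# unit = "sample" apportions a site's occurrence factor evenly across its
# samples so the rows still sum to the full marginal log-likelihood.
marginal_loglik <- function(draws, dataset, unit = c("sample", "site"),
                            chunk = 2000L) {
  unit <- match.arg(unit)
  ds <- build_designs(dataset, draws$spec)
  idx <- dataset_index(dataset)
  Xp_obs <- ds$X_p[idx$obs, , drop = FALSE]
  # rep -> sample incidence, split by outcome
  My1 <- incidence(idx$sample_of_rep, idx$n_samples, weight = idx$y)
  My0 <- incidence(idx$sample_of_rep, idx$n_samples, weight = 1 - idx$y)
  Msite <- incidence(idx$site_of_sample, idx$n_sites)
  zero_sample <- as.numeric(idx$d_sample == 0)
  zero_site <- as.numeric(idx$d_site == 0)
  m_per_site <- as.integer(colSums(Msite))
  n <- draws$n_draws
  n_units <- if (unit == "sample") idx$n_samples else idx$n_sites
  out <- matrix(NA_real_, n, n_units)
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    LP <- draws$delta_p[rows, , drop = FALSE] %*% t(Xp_obs)
    F1 <- stats::pnorm(LP, log.p = TRUE) %*% My1 +
      stats::pnorm(-LP, log.p = TRUE) %*% My0
    TH <- stats::pnorm(draws$alpha_theta[rows, , drop = FALSE] %*% t(ds$X_theta))
    G <- TH * exp(F1) + (1 - TH) * rep(zero_sample, each = length(rows))
    logG <- log(G)
    S <- logG %*% Msite
    PSI <- stats::pnorm(draws$beta_psi[rows, , drop = FALSE] %*% t(ds$X_psi))
    L_site <- PSI * exp(S) + (1 - PSI) * rep(zero_site, each = length(rows))
    if (unit == "site") {
      out[rows, ] <- log(L_site)
    } else {
      share <- log(L_site) / rep(m_per_site, each = length(rows))
      adj <- log(PSI) / rep(m_per_site, each = length(rows))
      ll <- logG + adj[, idx$site_of_sample, drop = FALSE]
      # sites with no detection anywhere do not factor over samples:
      # spread the whole-site marginal term evenly instead
      for (i in which(zero_site == 1)) {
        cols <- which(idx$site_of_sample == i)
        ll[, cols] <- share[, i]
      }
      out[rows, ] <- ll
    }
  }
  out
}

#' Widely Applicable Information Criterion for a multiscale fit
#'
#' WAIC from the pointwise log predictive density:
#' `lppd = sum_u log mean_t L_u(t)` and the effective-parameter penalty
#' `pWAIC = sum_u var_t log L_u(t)`. By default the criterion is reported on
#' the log-predictive-density scale, `pWAIC - lppd` (lower is better), the
#' scale on which the field analyses report it; `scale = "deviance"` doubles
#' it.
#'
#' The default pointwise unit is the detection count of each water sample,
#' with the likelihood conditional on the draw's latent sample-presence
#' state: `L_j(t) = a_j(t) Binom(d_j; n_j, p_j(t)) + (1 - a_j(t)) 1{d_j = 0}`.
#' `method = "marginal"` instead uses replicate-level Bernoulli detail with
#' both latent layers summed out analytically (the site occurrence factor
#' apportioned evenly over the site's samples); `unit = "site"` aggregates
#' either version to whole-site contributions.
#'
#' @param draws A [sample_posterior()] result (latent states retained).
#' @param dataset The dataset the model was fit to.
#' @param unit Pointwise partition: `"sample"` (default) or `"site"`.
#' @param method `"conditional"` (default) or `"marginal"` latent-state
#'   treatment, as described above.
#' @param scale `"log"` (default) or `"deviance"`.
#' @return List with `criterion`, `p_waic`, `lppd`, `unit`, `method`,
#'   `scale`.
#' @export
waic <- function(draws, dataset, unit = c("sample", "site"),
                 method = c("conditional", "marginal"),
                 scale = c("log", "deviance")) {
  unit <- match.arg(unit)
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (draws$n_draws < 100) {
    warning("fewer than 100 draws: pWAIC variance estimate may be unstable")
  }
  ll <- switch(method,
               conditional = conditional_loglik(draws, dataset, unit),
               marginal = marginal_loglik(draws, dataset, unit))
  lppd <- sum(log(colMeans(exp(ll))))
  p_waic <- sum(apply(ll, 2, stats::var))
  crit <- p_waic - lppd
  if (scale == "deviance") crit <- 2 * crit
  list(criterion = crit, p_waic = p_waic, lppd = lppd, unit = unit,
       method = method, scale = scale)
}

#' Posterior-Predictive Loss Criterion for a multiscale fit
#'
#' Squared-error posterior-predictive loss in the infinite-weight limit,
#' `PPLC = G + P`. By default the predicted quantity is each water sample's
#' detection count, replicated conditional on the draw's latent presence
#' state: given draw `t`, `d_rep ~ a_j(t) * Binom(n_j, p_j(t))`, so the
#' goodness-of-fit term is `G = sum_j (d_j - m_j)^2` with `m_j` the
#' posterior predictive mean count and `P = sum_j Var(d_rep_j)` the
#' predictive-variance penalty. `unit = "replicate"` predicts each 0/1
#' replicate outcome instead (`q_t = a_t p_t`, `P = sum m(1-m)`).
#'
#' @param draws A [sample_posterior()] result.
#' @param dataset The dataset the model was fit to.
#' @param unit `"sample"` (counts, default) or `"replicate"` (binary).
#' @return List with `criterion` (G + P), `p_var` (P) and `gof` (G).
#' @export
pplc <- function(draws, dataset, unit = c("sample", "replicate")) {
  unit <- match.arg(unit)
  if (draws$n_draws < 100) {
    warning("fewer than 100 draws: predictive moments may be unstable")
  }
  ds <- build_designs(dataset, draws$spec)
  idx <- dataset_index(dataset)
  if (unit == "replicate") {
    Xp_obs <- ds$X_p[idx$obs, , drop = FALSE]
    P_rep <- stats::pnorm(draws$delta_p %*% t(Xp_obs))
    q <- draws$a[, idx$sample_of_rep, drop = FALSE] * P_rep
    m <- colMeans(q)
    G <- sum((idx$y - m)^2)
    P <- sum(m * (1 - m))
  } else {
    Pm <- p_by_sample(draws, ds, idx)
    n_j <- rep(idx$n_sample, each = draws$n_draws)
    mean_t <- draws$a * Pm * n_j                       # E[d_rep | draw]
    var_t <- draws$a * n_j * Pm * (1 - Pm)             # Var[d_rep | draw]
    m <- colMeans(mean_t)
    v <- colMeans(var_t + mean_t^2) - m^2              # total predictive var
    G <- sum((idx$d_sample - m)^2)
    P <- sum(v)
  }
  list(criterion = G + P, p_var = P, gof = G, unit = unit)
}

#' Score one fitted model with both selection criteria
#'
#' @param draws A [sample_posterior()] result.
#' @param dataset The dataset the model was fit to.
#' @param ... Passed on to [waic()] (e.g. `unit`, `method`).
#' @return An object of class `model_score` holding the spec label, WAIC and
#'   PPLC criteria with their predictive-variance terms, and the number of
#'   coefficients.
#' @export
score_model <- function(draws, dataset, ...) {
  w <- waic(draws, dataset, ...)
  pl <- pplc(draws, dataset)
  structure(list(model = draws$spec$name,
                 waic = w$criterion, waic_pvar = w$p_waic,
                 pplc = pl$criterion, pplc_pvar = pl$p_var,
                 n_coef = ncol(draws$beta_psi) + ncol(draws$alpha_theta) +
                   ncol(draws$delta_p),
                 spec = draws$spec),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("%s: WAIC %.2f (pvar %.2f), PPLC %.2f (pvar %.2f)\n",
              x$model, x$waic, x$waic_pvar, x$pplc, x$pplc_pvar))
  invisible(x)
}

#' Rank candidate models by WAIC
#'
#' Orders model scores by increasing WAIC (lower is better), breaking exact
#' ties by fewer coefficients and then by model name, and reports the PPLC
#' rank alongside. The ordering is invariant to the input order.
#'
#' @param scores A list of [score_model()] results.
#' @return A data frame, one row per model, ordered by WAIC.
#' @export
rank_models <- function(scores) {
  if (length(scores) < 2) stop("need at least two models to rank")
  tab <- do.call(rbind, lapply(scores, function(s) {
    data.frame(model = s$model, waic = s$waic, waic_pvar = s$waic_pvar,
               pplc = s$pplc, pplc_pvar = s$pplc_pvar, n_coef = s$n_coef)
  }))
  ord <- order(tab$waic, tab$n_coef, tab$model)
  tab <- tab[ord, ]
  tab$pplc_rank <- rank(tab$pplc, ties.method = "min")
  rownames(tab) <- NULL
  tab
}
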