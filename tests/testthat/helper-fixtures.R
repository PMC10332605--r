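# Small in-code fixtures shared across test files.

# a tiny balanced 3-level replicate table: 1 site x 3 samples x 3 replicates
tiny_replicates <- function(detections = c(1, 1, 0, 0, 0, 0, 1, 0, 1)) {
  data.frame(site = "A",
             sample = rep(c("s1", "s2", "s3"), each = 3),
             replicate = rep(1:3, 3),
             detection = detections,
             stringsAsFactors = FALSE)
}

# random ragged nested dataset with a site-level covariate
random_dataset <- function(n_sites, samples_per_site, reps, seed,
                           with_covariate = TRUE) {
  set.seed(seed)
  sps <- rep_len(samples_per_site, n_sites)
  site_ids <- sprintf("site%02d", seq_len(n_sites))
  rows <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    expand.grid(replicate = seq_len(reps), sample = sprintf("s%d", seq_len(sps[i])),
                site = site_ids[i], stringsAsFactors = FALSE)
  }))
  rows$detection <- rbinom(nrow(rows), 1, 0.4)
  cov <- if (with_covariate) {
    data.frame(site = site_ids, density = rlnorm(n_sites, -0.5, 1))
  }
  survey_dataset(rows[, c("site", "sample", "replicate", "detection")],
                 site_covariates = cov)
}

# exhaustive latent-state oracle for the multiscale marginal likelihood:
# sums the complete-data likelihood over every (z, a) configuration
enumerate_multiscale_loglik <- function(coefs, dataset, spec) {
  ds <- occuDNA:::build_designs(dataset, spec)
  idx <- occuDNA:::dataset_index(dataset)
  psi <- pnorm(drop(ds$X_psi %*% coefs$beta_psi))
  theta <- pnorm(drop(ds$X_theta %*% coefs$alpha_theta))
  p_rep <- pnorm(drop(ds$X_p %*% coefs$delta_p))[idx$obs]
  n_sites <- idx$n_sites
  n_samples <- idx$n_samples
  total <- 0
  for (i in seq_len(n_sites)) {
    sample_ids <- which(idx$site_of_sample == i)
    site_lik <- 0
    for (z in 0:1) {
      pz <- if (z == 1) psi[i] else 1 - psi[i]
      if (length(sample_ids) == 0) { site_lik <- site_lik + pz; next }
      lik_given_z <- 1
      for (j in sample_ids) {
        rep_rows <- which(idx$sample_of_rep == j)
        lik_j <- 0
        for (a in 0:1) {
          if (a == 1 && z == 0) next
          pa <- if (z == 0) as.numeric(a == 0) else if (a == 1) theta[j] else 1 - theta[j]
          q <- if (a == 1) p_rep[rep_rows] else rep(0, length(rep_rows))
          py <- prod(ifelse(idx$y[rep_rows] == 1, q, 1 - q))
          lik_j <- lik_j + pa * py
        }
        lik_given_z <- lik_given_z * lik_j
      }
      site_lik <- site_lik + pz * lik_given_z
    }
    total <- total + log(site_lik)
  }
  unname(total)
}

# brute-force two-level occupancy log-likelihood by enumerating occupancy
# states of every unit
enumerate_classic_loglik <- function(psi, p, histories) {
  d <- histories$detections
  t <- histories$trials
  sum(vapply(seq_along(d), function(i) {
    lik <- psi * choose(t[i], d[i]) * p^d[i] * (1 - p)^(t[i] - d[i]) +
      (1 - psi) * as.numeric(d[i] == 0)
    log(lik)
  }, numeric(1)))
}

# grid-search oracle for the two-level MLE
grid_classic_mle <- function(histories, n_grid = 2000) {
  g <- (seq_len(n_grid) - 0.5) / n_grid
  d <- histories$detections
  t <- histories$trials
  pos <- d > 0
  n_pos <- sum(pos)
  sum_d <- sum(d[pos])
  sum_t_pos <- sum(t[pos])
  t_zero <- t[!pos]
  best <- c(NA, NA)
  best_ll <- -Inf
  lcoef <- sum(lchoose(t[pos], d[pos]))
  for (psi in g) {
    ll <- lcoef + n_pos * log(psi) + sum_d * log(g) +
      (sum_t_pos - sum_d) * log(1 - g)
    for (tz in t_zero) ll <- ll + log(psi * (1 - g)^tz + (1 - psi))
    k <- which.max(ll)
    if (ll[k] > best_ll) {
      best_ll <- ll[k]
      best <- c(psi, g[k])
    }
  }
  list(psi = best[1], p = best[2], loglik = best_ll)
}
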