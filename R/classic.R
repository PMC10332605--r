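#' Two-level detection histories
#'
#' Sufficient representation of a two-level occupancy dataset: for each
#' sampling unit, the number of detections `d` out of `t` survey/replicate
#' trials. The constant model's likelihood depends on a unit only through
#' `(d, t)`, so ragged designs (2–4 trials per unit) are supported directly.
#'
#' @param detections Integer vector, detections per unit.
#' @param trials Integer vector (or scalar, recycled), trials per unit.
#' @return An object of class `classic_histories`.
#' @export
classic_histories <- function(detections, trials) {
  trials <- rep_len(as.integer(trials), length(detections))
  detections <- as.integer(detections)
  if (any(trials < 1)) stop("trials must be >= 1")
  if (any(detections < 0 | detections > trials)) {
    stop("detections must lie in [0, trials]")
  }
  structure(list(detections = detections, trials = trials),
            class = "classic_histories")
}

#' Log-likelihood of the constant two-level occupancy model
#'
#' For occupancy probability `psi` and per-trial detection probability `p`,
#' a unit with `d > 0` detections in `t` trials contributes
#' `log(psi C(t,d) p^d (1-p)^(t-d))` (the count form — trials within a unit
#' are exchangeable); an all-negative unit contributes
#' `log(psi (1-p)^t + (1-psi))`, the mixture of "occupied but missed" and
#' "not occupied". False positives are assumed absent. The binomial
#' coefficient is a data-dependent constant, so estimates and standard
#' errors are unaffected by it.
#'
#' @param psi,p Probabilities in \[0, 1\].
#' @param histories A [classic_histories()].
#' @return The log-likelihood (may be `-Inf` at boundary parameters).
#' @export
classic_loglik <- function(psi, p, histories) {
  stopifnot(inherits(histories, "classic_histories"))
  if (psi < 0 || psi > 1 || p < 0 || p > 1) {
    stop("psi and p must be probabilities")
  }
  d <- histories$detections
  t <- histories$trials
  pos <- d > 0
  ll <- numeric(length(d))
  ll[pos] <- lchoose(t[pos], d[pos]) + log(psi) + d[pos] * log(p) +
    (t[pos] - d[pos]) * log1p(-p)
  ll[!pos] <- log(psi * (1 - p)^t[!pos] + (1 - psi))
  sum(ll)
}

# negative log-likelihood on the logit scale, vectorized over units
classic_nll_logit <- function(par, d, t) {
  psi <- stats::plogis(par[1])
  p <- stats::plogis(par[2])
  pos <- d > 0
  ll_pos <- sum(lchoose(t[pos], d[pos])) + sum(d[pos]) * log(p) +
    sum(t[pos] - d[pos]) * log1p(-p) + sum(pos) * log(psi)
  ll_zero <- sum(log(psi * (1 - p)^t[!pos] + (1 - psi)))
  -(ll_pos + ll_zero)
}

#' Fit the constant two-level occupancy model by maximum likelihood
#'
#' Maximizes [classic_loglik()] numerically on the logit scale from a grid of
#' starting values (`psi, p` in `{0.25, 0.5, 0.75}^2`), and reports
#' asymptotic standard errors from the inverse observed information mapped to
#' the probability scale by the delta method. Estimates on the boundary
#' (e.g. every trial positive) are returned with `NA` standard errors and
#' `boundary = TRUE`; the fit is deterministic given the data.
#'
#' @param histories A [classic_histories()], or a [survey_dataset()] which is
#'   first collapsed with [collapse_histories()] at `unit`.
#' @param unit Collapsing level when `histories` is a `survey_dataset`.
#' @return An object of class `classic_fit`: list with `psi_hat`, `p_hat`,
#'   `psi_se`, `p_se`, `loglik`, `converged`, `boundary`, `n_units`, `vcov`
#'   (logit-scale covariance) and `histories`.
#' @examples
#' h <- classic_histories(c(3, 3, 2, 0), trials = 3)
#' fit_classic(h)
#' @export
fit_classic <- function(histories, unit = c("sample", "site")) {
  if (inherits(histories, "survey_dataset")) {
    histories <- collapse_histories(histories, unit = match.arg(unit))
  }
  stopifnot(inherits(histories, "classic_histories"))
  d <- histories$detections
  t <- histories$trials
  if (all(d == 0)) {
    warning("no detections: psi is not identifiable; reporting boundary fit")
    return(structure(list(psi_hat = 0, p_hat = NA_real_, psi_se = NA_real_,
                          p_se = NA_real_, loglik = 0, converged = TRUE,
                          boundary = TRUE, n_units = length(d), vcov = NULL,
                          histories = histories),
                     class = "classic_fit"))
  }
  starts <- as.matrix(expand.grid(stats::qlogis(c(0.25, 0.5, 0.75)),
                                  stats::qlogis(c(0.25, 0.5, 0.75))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], classic_nll_logit, d = d, t = t,
                   method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 5000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimization failed from every starting value")
  est_logit <- best$par
  est <- stats::plogis(est_logit)
  # boundary if the logit-scale optimum ran away (all-positive data etc.)
  boundary <- any(abs(est_logit) > 12)
  psi_se <- p_se <- NA_real_
  vcov <- NULL
  if (!boundary) {
    H <- stats::optimHess(est_logit, classic_nll_logit, d = d, t = t)
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov) && all(diag(vcov) > 0)) {
      grad <- est * (1 - est)  # d plogis / d logit
      psi_se <- unname(sqrt(vcov[1, 1]) * grad[1])
      p_se <- unname(sqrt(vcov[2, 2]) * grad[2])
    }
  } else {
    est <- round(est, 10)
  }
  structure(list(psi_hat = unname(est[1]), p_hat = unname(est[2]),
                 psi_se = psi_se, p_se = p_se,
                 loglik = -best$value,
                 converged = best$convergence == 0 || boundary,
                 boundary = boundary,
                 n_units = length(d), vcov = vcov,
                 histories = histories),
            class = "classic_fit")
}

#' @export
print.classic_fit <- function(x, ...) {
  cat("Constant occupancy model psi(.)p(.), maximum likelihood\n")
  cat(sprintf("  %d units, log-likelihood %.4f%s\n", x$n_units, x$loglik,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  psi = %.3f (SE = %s)\n", x$psi_hat, fmt_se(x$psi_se)))
  cat(sprintf("  p   = %.3f (SE = %s)\n", x$p_hat, fmt_se(x$p_se)))
  invisible(x)
}

fmt_se <- function(se) if (is.na(se)) "NA" else sprintf("%.3f", se)

#' Collapse a nested survey dataset to two levels
#'
#' With `unit = "sample"` each water sample becomes a unit and its qPCR
#' replicates the trials (missing replicates dropped). With `unit = "site"`
#' each site becomes a unit and each of its samples one trial, scored 1 if
#' any replicate in that sample was positive.
#'
#' @param dataset A [survey_dataset()].
#' @param unit `"sample"` or `"site"`.
#' @return A [classic_histories()].
#' @export
collapse_histories <- function(dataset, unit = c("sample", "site")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  unit <- match.arg(unit)
  reps <- dataset$replicates[!is.na(dataset$replicates$detection), ]
  n_samples <- nrow(dataset$samples)
  d_sample <- as.integer(rowsum(reps$detection,
                                factor(reps$sample_idx, levels = seq_len(n_samples))))
  t_sample <- as.integer(table(factor(reps$sample_idx, levels = seq_len(n_samples))))
  if (unit == "sample") {
    keep <- t_sample > 0
    return(classic_histories(d_sample[keep], t_sample[keep]))
  }
  n_sites <- length(dataset$sites)
  w <- as.integer(d_sample > 0)
  observed <- t_sample > 0
  site_of_sample <- dataset$samples$site_idx
  d_site <- as.integer(rowsum(w[observed],
                              factor(site_of_sample[observed], levels = seq_len(n_sites))))
  t_site <- as.integer(table(factor(site_of_sample[observed], levels = seq_len(n_sites))))
  keep <- t_site > 0
  classic_histories(d_site[keep], t_site[keep])
}
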