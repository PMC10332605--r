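#' Cumulative probability of at least one success
#'
#' The probability of collecting (or detecting) eDNA at least once in `n`
#' independent attempts with per-attempt probability `prob`:
#' `1 - (1 - prob)^n`. Used for the cumulative collection probability after
#' `j` water samples and the cumulative detection probability after `k` qPCR
#' replicates.
#'
#' @param prob Per-attempt probability in \[0, 1\]; vectorized.
#' @param n Number of attempts (integer >= 1); vectorized.
#' @return Cumulative probability.
#' @examples
#' cumulative_probability(0.371, 6)  # 0.938
#' @export
cumulative_probability <- function(prob, n) {
  if (any(prob < 0 | prob > 1)) stop("prob must be in [0, 1]")
  if (any(n < 1 | n != round(n))) stop("n must be an integer >= 1")
  1 - (1 - prob)^n
}

#' Minimum effort for a cumulative probability to exceed a target
#'
#' Smallest number of attempts `n` such that
#' `cumulative_probability(prob, n) > target` (strictly greater; an exact tie
#' at the target requires one more attempt). Closed form
#' `ceil(log(1 - target) / log(1 - prob))` with a strictness correction.
#'
#' @param prob Per-attempt probability, `0 < prob <= 1`.
#' @param target Cumulative probability to exceed, in (0, 1); default 0.95.
#' @return Integer number of attempts.
#' @examples
#' n_required(0.371)  # 7 water samples
#' n_required(0.882)  # 2 qPCR replicates
#' @export
n_required <- function(prob, target = 0.95) {
  if (any(target <= 0 | target >= 1)) stop("target must be in (0, 1)")
  if (any(prob <= 0)) stop("no finite effort can exceed the target when prob <= 0")
  if (any(prob > 1)) stop("prob must be a probability")
  one <- function(pr) {
    if (pr >= 1) return(1L)
    n <- ceiling(log1p(-target) / log1p(-pr))
    # strictness: at exact equality 1-(1-pr)^n == target, need one more
    while (cumulative_probability(pr, n) <= target) n <- n + 1
    as.integer(n)
  }
  vapply(prob, one, integer(1))
}

#' Posterior cumulative-probability curve
#'
#' Applies [cumulative_probability()] to each posterior draw of a base
#' probability (a site's theta, or p) over a grid of efforts, then
#' summarizes per effort with the posterior median and equal-tailed 95%
#' credible interval. Because the transform is applied per draw, the
#' intervals are exact under the posterior.
#'
#' @param draws Numeric vector of posterior draws of the base probability
#'   (at least 100).
#' @param efforts Integer grid of efforts (default `1:10`).
#' @return An object of class `cumulative_curve`: data frame with columns
#'   `effort`, `median`, `cri_lower`, `cri_upper`.
#' @export
posterior_cumulative <- function(draws, efforts = 1:10) {
  if (length(draws) < 100) stop("need at least 100 posterior draws")
  if (any(draws < 0 | draws > 1)) stop("draws must be probabilities")
  rows <- lapply(efforts, function(n) {
    cp <- cumulative_probability(draws, n)
    q <- stats::quantile(cp, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(effort = n, median = q[2], cri_lower = q[1], cri_upper = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' @export
plot.cumulative_curve <- function(x, target = 0.95,
                                  xlab = "effort (samples or replicates)",
                                  ylab = "cumulative probability", ...) {
  plot(x$effort, x$median, ylim = c(0, 1), pch = 16, xlab = xlab,
       ylab = ylab, ...)
  graphics::segments(x$effort, x$cri_lower, x$effort, x$cri_upper)
  graphics::abline(h = target, lty = 2)
  invisible(x)
}
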