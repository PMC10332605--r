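#' Call a qPCR replicate positive or negative
#'
#' A replicate is called positive (1) only if it crossed the fluorescence
#' threshold (`ct` present), did so at or below `ct_threshold` cycles, and its
#' amplification curve passed visual quality control (`curve_ok`). Everything
#' else — no amplification (`ct = NA`), late amplification
#' (`ct > ct_threshold`), or a non-exponential curve shape — is negative (0).
#' Curve-shape QC is a human judgement on the amplification plot, so it enters
#' as a boolean input rather than being re-derived from fluorescence data.
#'
#' @param ct Threshold cycle(s); `NA` if the reaction never crossed threshold.
#' @param curve_ok Logical; `FALSE` marks a reaction whose amplification curve
#'   failed visual QC (called negative regardless of `ct`). Recycled.
#' @param ct_threshold Largest threshold cycle still called positive
#'   (default 34 cycles; ties at the threshold are positive).
#' @return Integer vector of 0/1 detections.
#' @examples
#' call_replicate(c(33, 36, 33, NA), curve_ok = c(TRUE, TRUE, FALSE, TRUE))
#' @export
call_replicate <- function(ct, curve_ok = TRUE, ct_threshold = 34) {
  if (!is.numeric(ct_threshold) || length(ct_threshold) != 1 ||
      ct_threshold <= 0) {
    stop("ct_threshold must be a single positive number of cycles")
  }
  curve_ok <- rep_len(as.logical(curve_ok), length(ct))
  as.integer(!is.na(ct) & ct <= ct_threshold & curve_ok)
}

#' Fit a serial-dilution qPCR standard curve
#'
#' Least-squares fit of threshold cycle on log10(template concentration) for
#' a dilution series, with amplification efficiency derived from the slope as
#' `10^(-1/slope) - 1` (a slope of -3.32 cycles per tenfold dilution is 100%
#' efficiency).
#'
#' @param concentrations Template concentrations (e.g. gene-fragment
#'   copies/µL), strictly positive, at least two distinct values.
#' @param ct_values Observed threshold cycles, one per dilution point.
#' @return An object of class `standard_curve` with elements
#'   `concentrations`, `ct_values`, `slope` (cycles per log10 unit),
#'   `intercept` (cycles), `r_squared` and `efficiency`.
#' @export
fit_standard_curve <- function(concentrations, ct_values) {
  if (length(concentrations) != length(ct_values)) {
    stop("concentrations and ct_values must have equal length")
  }
  if (length(unique(concentrations)) < 2) {
    stop("need at least two distinct concentrations")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be positive")
  }
  logc <- log10(concentrations)
  fit <- stats::lm(ct_values ~ logc)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((ct_values - mean(ct_values))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(concentrations = concentrations,
                 ct_values = ct_values,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Ct = %.3f %+.3f * log10(copies/uL)\n", x$intercept, x$slope))
  cat(sprintf("  efficiency = %.1f%%, R^2 = %.4f, %d points\n",
              100 * x$efficiency, x$r_squared, length(x$ct_values)))
  invisible(x)
}

#' Predict template concentration from a threshold cycle
#'
#' Inverts the standard curve; useful for reporting what concentration a
#' calling threshold corresponds to (e.g. Ct 34 on this assay's curve).
#'
#' @param object A [fit_standard_curve()] result.
#' @param ct Threshold cycle(s).
#' @param ... Unused.
#' @return Concentrations in the curve's units.
#' @export
predict.standard_curve <- function(object, ct, ...) {
  10^((ct - object$intercept) / object$slope)
}

#' Assemble detection histories from raw qPCR results
#'
#' Applies the threshold-and-curve-quality calling rule to a replicate-level
#' table of threshold cycles and groups the calls into a nested
#' [survey_dataset()], preserving the replicate structure (each water
#' sample's qPCR results form its detection history).
#'
#' @param replicates Data frame with columns `site`, `sample`, `replicate`,
#'   `ct`, and optionally `location` and `quality_override` (logical; `TRUE`
#'   forces a negative call for a reaction whose curve failed QC).
#' @param ct_threshold Calling threshold in cycles (default 34).
#' @return A [survey_dataset()] whose `detection` column holds the calls; the
#'   `ct` and `quality_override` columns are retained.
#' @export
assemble_histories <- function(replicates, ct_threshold = 34) {
  replicates <- as.data.frame(replicates)
  if (!"ct" %in% names(replicates)) stop("need a 'ct' column")
  ok <- if ("quality_override" %in% names(replicates)) {
    !isTRUE_vec(replicates$quality_override)
  } else {
    TRUE
  }
  replicates$detection <- call_replicate(replicates$ct, curve_ok = ok,
                                         ct_threshold = ct_threshold)
  survey_dataset(replicates)
}
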