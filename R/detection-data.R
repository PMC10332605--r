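#' Nested eDNA survey dataset
#'
#' A `survey_dataset` holds detection/non-detection data from a three-level
#' nested eDNA survey design: qPCR replicates within water samples within
#' sites. The structure is ragged — sites may differ in their number of
#' samples and samples in their number of replicates — and a replicate's
#' outcome may be missing (`NA`), in which case all likelihood code skips it.
#'
#' @param replicates Data frame with one row per qPCR replicate. Required
#'   columns: `site`, `sample`, `replicate` (integer index, unique within a
#'   sample) and `detection` (0/1/`NA`). Optional columns: `location`
#'   (sampling location within a site, e.g. spring outlet vs downstream),
#'   `ct` (threshold cycle) and `quality_override` (logical; see
#'   [call_replicate()]).
#' @param site_covariates Optional data frame keyed by a `site` column, one
#'   row per site, remaining columns numeric site-level covariates.
#' @param sample_covariates Optional data frame keyed by `site` and `sample`,
#'   one row per sample, remaining columns numeric sample-level covariates.
#'
#' @return An object of class `survey_dataset`: a list with elements
#'   `replicates` (the validated long table with integer indices
#'   `site_idx`, `sample_idx` added), `sites` (site ids in order of first
#'   appearance), `samples` (one row per sample: `site`, `sample`,
#'   `site_idx`), `site_covariates`, `sample_covariates`, and `scaling`
#'   (standardization statistics recorded by [standardize_covariates()]).
#' @seealso [read_long_csv()], [standardize_covariates()], [collapse_histories()]
#' @export
survey_dataset <- function(replicates, site_covariates = NULL,
                           sample_covariates = NULL) {
  replicates <- as.data.frame(replicates)
  required <- c("site", "sample", "replicate", "detection")
  missing_cols <- setdiff(required, names(replicates))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"location" %in% names(replicates)) replicates$location <- "main"
  replicates$site <- as.character(replicates$site)
  replicates$sample <- as.character(replicates$sample)
  replicates$location <- as.character(replicates$location)
  replicates$replicate <- as.integer(replicates$replicate)
  if (anyNA(replicates$replicate) || any(replicates$replicate < 1)) {
    stop("replicate indices must be integers >= 1")
  }
  det <- replicates$detection
  if (!all(is.na(det) | det %in% c(0, 1))) {
    stop("detection values must be 0, 1 or NA")
  }
  replicates$detection <- as.integer(det)

  key <- paste(replicates$site, replicates$sample, replicates$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site, sample, replicate) rows")
  }

  sites <- unique(replicates$site)
  sample_key <- paste(replicates$site, replicates$sample, sep = "\r")
  first <- !duplicated(sample_key)
  samples <- data.frame(site = replicates$site[first],
                        sample = replicates$sample[first],
                        stringsAsFactors = FALSE)
  samples$site_idx <- match(samples$site, sites)
  replicates$site_idx <- match(replicates$site, sites)
  replicates$sample_idx <- match(sample_key, sample_key[first])

  if (!is.null(site_covariates)) {
    site_covariates <- as.data.frame(site_covariates)
    if (!"site" %in% names(site_covariates)) {
      stop("site_covariates must have a 'site' column")
    }
    site_covariates$site <- as.character(site_covariates$site)
    if (!all(sites %in% site_covariates$site)) {
      stop("site_covariates is missing rows for some sites")
    }
    site_covariates <-
      site_covariates[match(sites, site_covariates$site), , drop = FALSE]
    rownames(site_covariates) <- NULL
  }
  if (!is.null(sample_covariates)) {
    sample_covariates <- as.data.frame(sample_covariates)
    if (!all(c("site", "sample") %in% names(sample_covariates))) {
      stop("sample_covariates must have 'site' and 'sample' columns")
    }
    sample_covariates$site <- as.character(sample_covariates$site)
    sample_covariates$sample <- as.character(sample_covariates$sample)
    sk <- paste(sample_covariates$site, sample_covariates$sample, sep = "\r")
    dk <- paste(samples$site, samples$sample, sep = "\r")
    if (!all(dk %in% sk)) {
      stop("sample_covariates is missing rows for some samples")
    }
    sample_covariates <- sample_covariates[match(dk, sk), , drop = FALSE]
    rownames(sample_covariates) <- NULL
  }

  structure(list(replicates = replicates,
                 sites = sites,
                 samples = samples,
                 site_covariates = site_covariates,
                 sample_covariates = sample_covariates,
                 scaling = list()),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  n_det <- sum(x$replicates$detection, na.rm = TRUE)
  n_obs <- sum(!is.na(x$replicates$detection))
  cat("Nested eDNA survey dataset\n")
  cat(sprintf("  %d sites, %d samples, %d replicates (%d observed)\n",
              length(x$sites), nrow(x$samples), nrow(x$replicates), n_obs))
  cat(sprintf("  detections: %d of %d observed replicates\n", n_det, n_obs))
  if (!is.null(x$site_covariates)) {
    cat("  site covariates:",
        paste(setdiff(names(x$site_covariates), "site"), collapse = ", "), "\n")
  }
  if (!is.null(x$sample_covariates)) {
    cat("  sample covariates:",
        paste(setdiff(names(x$sample_covariates), c("site", "sample")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Counts of samples per site and replicates per sample
#'
#' @param dataset A [survey_dataset()].
#' @return A list with `samples_per_site` (named integer vector) and
#'   `replicates_per_sample` (integer vector in sample order).
#' @export
dataset_shape <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  sps <- as.integer(table(factor(dataset$samples$site_idx,
                                 levels = seq_along(dataset$sites))))
  names(sps) <- dataset$sites
  rps <- as.integer(table(factor(dataset$replicates$sample_idx,
                                 levels = seq_len(nrow(dataset$samples)))))
  list(samples_per_site = sps, replicates_per_sample = rps)
}

#' Read a long-format eDNA survey CSV
#'
#' Reads a long-format CSV with one row per qPCR replicate (columns
#' `site,sample,replicate` plus `detection` and/or `ct`; optional `location`
#' and `quality_override`) and optional covariate CSVs, returning a validated
#' [survey_dataset()]. When `detection` is absent but `ct` is present,
#' detections are called with [call_replicate()] at `ct_threshold`.
#'
#' @param path Path to the replicate-level CSV.
#' @param site_covariates,sample_covariates Optional paths to covariate CSVs
#'   (keyed by `site`, and by `site`+`sample`, respectively).
#' @param ct_threshold Threshold cycle used to call detections when only `ct`
#'   is present (default 34 cycles).
#' @return A [survey_dataset()].
#' @examples
#' read_long_csv(system.file("extdata", "example_long.csv",
#'                           package = "occuDNA"))
#' @export
read_long_csv <- function(path, site_covariates = NULL,
                          sample_covariates = NULL, ct_threshold = 34) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "sample", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"detection" %in% names(df)) {
    if (!"ct" %in% names(df)) {
      stop("need a 'detection' or 'ct' column")
    }
    ok <- if ("quality_override" %in% names(df)) {
      !isTRUE_vec(df$quality_override)
    } else {
      rep(TRUE, nrow(df))
    }
    df$detection <- call_replicate(df$ct, curve_ok = ok,
                                   ct_threshold = ct_threshold)
  }
  sc <- if (!is.null(site_covariates)) {
    utils::read.csv(site_covariates, stringsAsFactors = FALSE)
  }
  mc <- if (!is.null(sample_covariates)) {
    utils::read.csv(sample_covariates, stringsAsFactors = FALSE)
  }
  survey_dataset(df, site_covariates = sc, sample_covariates = mc)
}

# truthy interpretation of a CSV override column (TRUE/true/1/yes)
isTRUE_vec <- function(x) {
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a survey dataset back to long-format CSV
#'
#' Inverse of [read_long_csv()]: writes one row per replicate with the
#' standard header. Round-trips the detection array exactly.
#'
#' @param dataset A [survey_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cols <- intersect(c("site", "location", "sample", "replicate", "detection",
                      "ct", "quality_override"),
                    names(dataset$replicates))
  utils::write.csv(dataset$replicates[, cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Salamander relative density
#'
#' Visual-encounter detections per square metre of surveyed habitat,
#' uncorrected for imperfect detection.
#'
#' @param detections Number of salamander detections (integer >= 0); vectorized.
#' @param survey_area Surveyed area in square metres (> 0); vectorized.
#' @return Relative density in detections/m².
#' @examples
#' relative_density(3, 0.75)   # 4.0 detections/m2
#' @export
relative_density <- function(detections, survey_area) {
  if (any(!is.finite(survey_area)) || any(survey_area <= 0)) {
    stop("survey_area must be positive")
  }
  if (any(detections < 0)) stop("detections must be >= 0")
  detections / survey_area
}

#' Average repeated site-level measurements
#'
#' When water conditions were measured more than once at a site (e.g. at the
#' spring outlet and downstream), the site-level covariate is their
#' arithmetic mean.
#'
#' @param values Numeric vector with at least one finite value.
#' @return The mean of the finite values.
#' @export
aggregate_site_measurements <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite measurements to aggregate")
  mean(values)
}

#' Scale and center covariates
#'
#' Standardizes the named covariates to mean 0 and unit standard deviation
#' across the units of their level (sites for site covariates, samples for
#' sample covariates). The untransformed values are retained alongside as
#' `<name>.raw`, and the centring/scaling statistics are recorded in the
#' dataset's `scaling` element so fitted effects can be reported on the
#' natural scale.
#'
#' @param dataset A [survey_dataset()].
#' @param names Character vector of covariate names to standardize.
#' @return The dataset with the named covariates standardized.
#' @export
standardize_covariates <- function(dataset, names) {
  stopifnot(inherits(dataset, "survey_dataset"))
  for (nm in names) {
    level <- NULL
    if (!is.null(dataset$site_covariates) &&
        nm %in% colnames(dataset$site_covariates)) {
      level <- "site_covariates"
    } else if (!is.null(dataset$sample_covariates) &&
               nm %in% colnames(dataset$sample_covariates)) {
      level <- "sample_covariates"
    } else {
      stop("covariate not found: ", nm)
    }
    x <- dataset[[level]][[nm]]
    if (!is.numeric(x)) stop("covariate is not numeric: ", nm)
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("covariate has zero or undefined spread: ", nm)
    }
    raw_name <- paste0(nm, ".raw")
    if (!raw_name %in% colnames(dataset[[level]])) {
      dataset[[level]][[raw_name]] <- x
    }
    dataset[[level]][[nm]] <- (x - m) / s
    dataset$scaling[[nm]] <- c(mean = m, sd = s)
  }
  dataset
}
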