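#' Field-control site summary
#'
#' Per-site results of the ten-site field control for the central Texas
#' *Eurycea* (Septentriomolge) eDNA assay: visual-encounter survey area and
#' salamander detections, the derived relative density (detections/m²), and
#' the eDNA survey totals (positive water samples out of samples collected,
#' positive qPCR replicates out of reactions run; three replicates per
#' sample, six 1 L samples per site except three at the well site).
#'
#' @return A data frame with columns `site`, `taxon`, `area_m2`,
#'   `detections`, `density`, `n_samples`, `pos_samples`, `n_reps`,
#'   `pos_reps`.
#' @export
field_sites <- function() {
  tab <- data.frame(
    site = c("Avery Deer Spring", "Avery Springhouse Spring",
             "Brushy Creek Spring", "Cobbs Spring", "Cobbs Well",
             "Cowan Spring", "Hill Marsh Spring", "PC Spring",
             "Swinbank Spring", "Twin Springs"),
    taxon = c("E. tonkawae", "E. tonkawae", "E. tonkawae",
              "E. chisholmensis", "E. chisholmensis", "E. chisholmensis",
              "E. tonkawae", "E. tonkawae", "E. naufragia",
              "E. chisholmensis"),
    area_m2 = c(15.0, 32.5, 25.0, 28.25, 0.75, 10.0, 58.0, 3.0, 41.75, 9.0),
    detections = c(8L, 16L, 0L, 29L, 3L, 8L, 12L, 1L, 60L, 1L),
    n_samples = c(6L, 6L, 6L, 6L, 3L, 6L, 6L, 6L, 6L, 6L),
    pos_samples = c(4L, 2L, 2L, 6L, 3L, 2L, 2L, 5L, 5L, 2L),
    n_reps = c(18L, 18L, 18L, 18L, 9L, 18L, 18L, 18L, 18L, 18L),
    pos_reps = c(11L, 6L, 6L, 17L, 9L, 2L, 6L, 11L, 14L, 6L),
    stringsAsFactors = FALSE)
  tab$density <- relative_density(tab$detections, tab$area_m2)
  tab[, c("site", "taxon", "area_m2", "detections", "density",
          "n_samples", "pos_samples", "n_reps", "pos_reps")]
}

# Deterministically spread r positive replicates over k positive samples
# (three replicates per sample): fill the earliest samples first.
spread_positives <- function(r, k, reps_per_sample = 3L) {
  counts <- rep(1L, k)
  extra <- r - k
  i <- 1L
  while (extra > 0L) {
    add <- min(extra, reps_per_sample - 1L)
    counts[i] <- counts[i] + add
    extra <- extra - add
    i <- i + 1L
  }
  counts
}

#' Reconstructed field-control detection histories
#'
#' Expands the per-site totals of [field_sites()] into a replicate-level
#' long table (one row per qPCR replicate). The within-site arrangement of
#' positives across samples is a deterministic convention (positive samples
#' first, filled three-at-a-time): every candidate model uses site-level
#' covariates only, so the full three-level likelihood depends on the data
#' only through the per-site totals, and any arrangement consistent with
#' them gives identical inference (the tests assert this sufficiency).
#'
#' @return A data frame with columns `site`, `sample`, `replicate`,
#'   `detection`.
#' @export
field_detections <- function() {
  tab <- field_sites()
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    n_s <- tab$n_samples[i]
    k <- tab$pos_samples[i]
    d <- integer(n_s)
    if (k > 0) d[seq_len(k)] <- spread_positives(tab$pos_reps[i], k)
    data.frame(site = tab$site[i],
               sample = sprintf("S%d", seq_len(n_s)),
               d = d,
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  reps <- samples[rep(seq_len(nrow(samples)), each = 3), ]
  reps$replicate <- rep(1:3, nrow(samples))
  reps$detection <- as.integer(reps$replicate <= reps$d)
  rownames(reps) <- NULL
  reps[, c("site", "sample", "replicate", "detection")]
}

#' Field-control dataset ready for model fitting
#'
#' Bundles [field_detections()] with the site covariates used in the
#' candidate models. Salamander relative density is observed (from
#' [field_sites()]). The per-site water-condition covariates (temperature,
#' dissolved oxygen, specific conductance, flow velocity) were not published
#' per site; when `synthetic_water = TRUE` the dataset includes synthetic
#' stand-ins drawn to match the published across-site mean and SD of each
#' variable (see [synthetic_water_conditions()]). All covariates are scaled
#' and centred.
#'
#' @param synthetic_water Include synthetic water-condition covariates?
#' @param seed Seed for the synthetic water conditions (required when
#'   `synthetic_water = TRUE`).
#' @return A [survey_dataset()] with standardized site covariates.
#' @export
field_dataset <- function(synthetic_water = FALSE, seed = NULL) {
  cov <- field_sites()[, c("site", "density")]
  if (synthetic_water) {
    if (is.null(seed)) stop("a seed is required for synthetic water conditions")
    cov <- merge(cov, synthetic_water_conditions(seed), by = "site",
                 sort = FALSE)
  }
  dataset <- survey_dataset(field_detections(), site_covariates = cov)
  standardize_covariates(dataset, setdiff(names(cov), "site"))
}

#' Synthetic per-site water conditions
#'
#' The field study measured water temperature, dissolved oxygen (DO),
#' specific conductance (SC) and flow velocity at each site but published
#' only their across-site summaries (temperature mean 15.5, SD 2.01 °C; DO
#' 6.2, 1.60 mg/L; SC 755.7, 100.3 µS/cm; flow 0.085, 0.093 m/s). This
#' helper draws one synthetic value per site from normal distributions with
#' those moments (flow truncated at a small positive value), for use as
#' stand-in covariates in the water-condition candidate models. These values
#' are synthetic: effects estimated for them are exercises of the machinery,
#' not estimates about the real sites.
#'
#' @param seed Integer seed.
#' @return A data frame with columns `site`, `temperature`, `DO`, `SC`,
#'   `flow`.
#' @export
synthetic_water_conditions <- function(seed) {
  set.seed(seed)
  sites <- field_sites()$site
  n <- length(sites)
  data.frame(site = sites,
             temperature = stats::rnorm(n, 15.5, 2.01),
             DO = stats::rnorm(n, 6.2, 1.60),
             SC = stats::rnorm(n, 755.7, 100.3),
             flow = pmax(stats::rnorm(n, 0.085, 0.093), 0.002),
             stringsAsFactors = FALSE)
}

#' Salamander-positive control detection histories
#'
#' Two-level histories for the 53 salamander-positive water samples: eDNA
#' was detected in 52 of 53 samples and in 153 of 159 qPCR replicates (three
#' per sample). The constant model's likelihood depends only on these
#' sufficient statistics, so the detected samples are represented as 49
#' samples with 3/3 positives and 3 with 2/3, plus the single all-negative
#' sample.
#'
#' @return A [classic_histories()] with 53 units of 3 trials.
#' @export
positive_control_histories <- function() {
  classic_histories(c(rep(3L, 49), rep(2L, 3), 0L), trials = 3L)
}

#' Visual-encounter survey detection histories
#'
#' Two-level histories for the visual-encounter surveys at the ten
#' field-control sites (2–4 temporal replicates per site under demographic
#' closure): salamanders were seen on every survey at eight sites (24
#' surveys in total, represented as three per site by sufficiency), on two
#' of four surveys at one site, and on zero of two surveys at one site —
#' 26 detections in 30 surveys.
#'
#' @return A [classic_histories()] with 10 units.
#' @export
visual_survey_histories <- function() {
  classic_histories(c(rep(3L, 8), 2L, 0L), trials = c(rep(3L, 8), 4L, 2L))
}

#' The eight candidate model specifications of the field analysis
#'
#' The null model, the density model, six combinations of density and
#' water-condition covariates on theta with or without specific conductance
#' on p, and the full model — the candidate set compared by WAIC/PPLC in
#' the field-control analysis.
#'
#' @return A named list of [model_spec()] objects.
#' @export
field_model_set <- function() {
  list(
    model_spec(theta = ~ density),
    model_spec(),
    model_spec(theta = ~ density + temperature + DO + SC + flow),
    model_spec(theta = ~ density, p = ~ SC),
    model_spec(theta = ~ temperature + DO + SC + flow),
    model_spec(p = ~ SC),
    model_spec(theta = ~ density + temperature + DO + SC + flow, p = ~ SC),
    model_spec(theta = ~ temperature + DO + SC + flow, p = ~ SC)
  )
}
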