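---
title: "Multiscale occupancy models for nested eDNA surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale occupancy models for nested eDNA surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuDNA)
```

## The inference problem

Environmental DNA (eDNA) surveys detect a species from trace DNA in water
rather than from sightings. A detection can fail at three nested stages:
the DNA may not occur at the site at all, a particular 1 L water sample may
fail to capture it even though it is present at the site, and a particular
qPCR replicate may fail to amplify it even though it is present in the
sample. occuDNA implements the hierarchical models that separate these
stages for data organised as qPCR replicates within water samples within
sites, together with the qPCR calling step that produces the binary
histories, selection criteria for competing covariate structures, and
survey-effort calculators derived from the fitted probabilities. The
built-in datasets are the control surveys of an assay validation for the
central Texas *Eurycea* salamanders (the *Septentriomolge* clade), which we
use as the running example.

## From threshold cycles to detection histories

A qPCR reaction is called positive only when it crossed the fluorescence
threshold at or below a calling threshold (default Ct 34 cycles, the point
that corresponds to roughly 80 gene-fragment copies/µL on this assay's
standard curve) *and* its amplification curve passed visual quality
control. Curve-shape QC is a human judgement about the amplification plot,
so `call_replicate()` takes it as a boolean input (`curve_ok`) rather than
re-deriving it from fluorescence data; ties exactly at the threshold are
positive. `fit_standard_curve()` fits the serial-dilution line of Ct on
log10(concentration) by ordinary least squares and reports amplification
efficiency `10^(-1/slope) - 1`.

```{r qpcr}
conc <- 8e6 / 10^(0:5)
fit_standard_curve(conc, 38 - 3.4 * log10(conc) + rnorm(6, 0, 0.1))
```

## The two-level model

For the salamander-positive control (53 water samples, each with three
qPCR replicates) the site layer is absent and the classic constant
occupancy model applies: occurrence probability $\psi$ and per-replicate
detection probability $p$, with likelihood contribution
$\psi \binom{t}{d} p^d (1-p)^{t-d}$ for a unit with $d>0$ detections in $t$
trials and $\psi(1-p)^t + (1-\psi)$ for an all-negative unit. False
positives are assumed absent, which the study's negative controls support.
`fit_classic()` maximises this likelihood numerically on the logit scale
from a 3×3 grid of starting values ($\psi, p \in \{0.25, 0.5, 0.75\}$) to
avoid the ridge that appears when detections are sparse, and reports
asymptotic standard errors from the inverse observed information mapped by
the delta method. Boundary fits (every trial positive, or no detections)
are flagged and returned without standard errors rather than with
meaningless ones. Because the likelihood depends on each unit only through
$(d, t)$, any arrangement of the same sufficient statistics gives the same
fit — this is why the built-in control histories can be reconstructed
exactly from published totals.

```{r classic}
fit_classic(positive_control_histories())
fit_classic(visual_survey_histories())
```

## The three-level model and its sampler

The field control has ten occupied spring sites, six 1 L samples per site
(three at the well site), and three qPCR replicates per sample. The
multiscale model adds latent layers: site occurrence
$z_i \sim \mathrm{Bern}(\psi_i)$, conditional sample-level presence
$a_{ij} \mid z_i \sim \mathrm{Bern}(z_i \theta_{ij})$, and replicate
detection $y_{ijk} \mid a_{ij} \sim \mathrm{Bern}(a_{ij} p_{ijk})$.
Covariates enter each level through a **probit** link,
$\psi_i = \Phi(x_i^\top \beta_\psi)$ and likewise for $\theta$ and $p$,
with independent standard-normal priors on all coefficients
(`prior_sd = 1`, configurable). The probit link and unit-variance priors
are what make the sampler fully conjugate, and they reproduce the published
posterior summaries of the original field analysis; a weakly informative
N(0,1) prior on the probit scale corresponds to a near-uniform implied
prior on the probability scale.

`sample_posterior()` is a Gibbs sampler in which every update is an exact
draw from a full conditional: the latent indicators $a$ and $z$ have
Bernoulli full conditionals ($z$ is forced on at any site with an observed
detection, $a$ at any detected sample), and each coefficient block is
updated by Albert–Chib truncated-normal data augmentation, i.e. a
conjugate Bayesian probit regression of $z$ on the site design, of $a$ on
the sample design over currently-occupied sites, and of $y$ on the
replicate design over currently-present samples. No proposal tuning or
adaptation is involved, and runs are bit-reproducible given the seed. The
default run length follows the original analysis: 50,000 iterations with a
burn-in of 5,000 and no thinning. On this dataset that takes on the order
of twenty seconds; the retained latent-state draws are kept because the
selection criteria condition on them.

Missing replicates are coded `NA` and skipped by all likelihood code —
never recoded as 0, which would be a claimed non-detection. Covariates are
scaled and centred before entering the linear predictors
(`standardize_covariates()` stores the statistics so effects can be
reported on the natural scale), and a covariate that is constant across
its level is a hard error rather than a silent drop. A covariate effect is
called "supported" when the equal-tailed 95% credible interval of its
slope excludes zero (an endpoint exactly at zero does not count).

```{r multiscale, eval = FALSE}
d <- field_dataset()
draws <- sample_posterior(d, model_spec(theta = ~ density),
                          mcmc_config(50000, 5000, seed = 1))
summarize_draws(draws)
median(derived_probabilities(draws, d, "psi")[, 1])   # ~0.94
median(derived_probabilities(draws, d, "p")[, 1])     # ~0.88
```

## Reconstructed data and synthetic covariates

The replicate-level field histories were published only as per-site totals
(positive samples out of samples, positive replicates out of reactions).
Because every candidate model uses site-level covariates only, the full
three-level likelihood depends on the data only through those totals, so
`field_detections()` expands them with a fixed within-site arrangement and
the tests assert the sufficiency explicitly. The per-site water-condition
measurements (temperature, DO, specific conductance, flow velocity) were
published only as across-site summaries; `synthetic_water_conditions()`
draws synthetic stand-ins matching those moments so the six
water-condition candidate models can be exercised. Conclusions about
density and the detection probabilities rest entirely on observed data;
the synthetic covariates only fill out the candidate set.

## Model selection

`waic()` and `pplc()` score fitted models the way the original field
analysis did. The pointwise unit is each water sample's detection count,
with the likelihood conditional on the sampled latent presence state:
$L_j(t) = a_j(t)\,\mathrm{Bin}(d_j; n_j, p_j(t)) + (1-a_j(t))\,1\{d_j=0\}$.
WAIC is reported on the log predictive density scale,
$\mathrm{pWAIC} - \mathrm{lppd}$ (lower is better), with
`scale = "deviance"` available for the conventional $-2(\cdot)$ form. The
PPLC is the squared-error posterior-predictive loss in the infinite-weight
limit, $G + P$, predicting each sample's count conditional on the sampled
latent state. Both criteria therefore measure predictive quality for new
samples at the surveyed sites given the latent history, which is the
design question the study asked (how many samples and replicates to take
at an occupied site). A fully marginal pointwise likelihood — latent
layers summed out analytically, at sample or site level — is available via
`waic(..., method = "marginal")` for users who prefer scoring predictions
for entirely new sites; rankings rather than absolute values are what the
criteria are for, and the tie-break in `rank_models()` (fewer coefficients
first, then name) only matters for exact ties.

## Survey effort

With $\theta$ and $p$ from the top model, the cumulative probability of at
least one success in $n$ tries is $1-(1-\theta)^n$ (and likewise for $p$),
and `n_required()` returns the smallest effort whose cumulative
probability strictly exceeds a target (default 0.95; an exact tie requires
one more unit, per the strict reading of "exceed"). Credible bands for the
cumulative curves are computed by applying the formula to every posterior
draw and then taking per-effort quantiles, which is exact under the
posterior rather than an approximation from the interval endpoints.

```{r effort}
cumulative_probability(0.371, 6)
n_required(0.371)   # water samples at the lowest-theta site
n_required(0.882)   # qPCR replicates
```

## The synthetic-data generator

`simulate_multiscale()` draws data from exactly the hierarchy the model
assumes: covariates per site from declared generators, standardized the
same way the analysis pipeline standardizes them (so simulated slopes are
comparable to fitted ones), then $z$, $a$, $y$ from the three Bernoulli
layers. `field_design()` is a preset with the study's layout — ten sites,
six samples each (three at the well), three replicates, the observed
relative densities as a fixed covariate — and the top model's posterior
medians as default truth. The default density generator in examples,
lognormal with median 0.5 detections/m², mimics the observed right-skewed
0–4 detections/m² range. What the generator does *not* emulate: spatial
or temporal correlation between samples, PCR inhibition, false positives,
or abundance-driven variation in p — so passing recovery tests show the
estimator is correct under the model's assumptions, not that real surveys
satisfy them.

Parameter-recovery checks at 200 sites × 6 samples × 3 replicates (50
seeded replicates, 3,000 iterations each, a size chosen to make the
Monte Carlo coverage estimate reasonably tight) give ~95% credible-interval
coverage for all four generating coefficients.

## Numerical choices and limitations

- Truncated-normal draws use inverse-CDF sampling with the uniform
  clamped to `[1e-15, 1 - 1e-15]`; linear predictors of modest magnitude
  (|x| < 8) keep this exact to machine precision.
- The marginal likelihood computes per-sample factors in log space and
  mixes them on the natural scale; with the probability magnitudes of
  these designs underflow is not reachable, and the exhaustive-enumeration
  tests confirm agreement to 1e-10.
- The two-level optimiser uses `reltol = 1e-14`; against a 2000×2000 grid
  oracle the MLE agrees to 1e-3 on random datasets.
- `fit_classic()` treats |logit| > 12 as a boundary estimate; standard
  errors are then reported `NA` with `boundary = TRUE`.
- One chain is run by default, matching the original analysis; for new
  applications multiple seeds should be compared (the draws are plain
  matrices, so any diagnostic toolkit applies).
- The models assume no false positives; a two-error model is out of scope,
  as are abundance estimation from eDNA quantity and transport/decay
  mechanisms.
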