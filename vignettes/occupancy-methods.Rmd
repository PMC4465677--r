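---
title: "Occupancy models for camera-trap detection histories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy models for camera-trap detection histories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuCam)
```

## The problem

Camera traps record *detections*, not *presence*. A deer can use a site all
season and never walk in front of the lens in a given week; a naive map of
photograph locations conflates habitat use with photographic luck and with
activity level. Site-occupancy models resolve this by treating occupancy as
a latent state and modelling weekly detection conditional on it, so habitat
covariates can act on the two processes separately. occuCam implements this
for the data a typical deer camera-grid study produces: a 25-camera grid
visited over two winters and two summers, with every image classified to
species, age class and sex.

## From images to detection histories

Consecutive images of the same species at the same camera within 5 minutes
are one behavioural event; `filterIndependentImages()` keeps the first
image of each event, anchored to the last *retained* image of the
(site, species) stream. The anchored rule is deterministic and
conservative: a burst at minutes 0, 4, 8 keeps the images at 0 and 8,
because 4 falls within the window of the retained anchor while 8 does not.
Individual identity cannot be resolved from the data, so the stream is the
finest defensible unit.

`aggregateWeekly()` collapses records to site-week codes on a shared
calendar: weeks are 7-day blocks counted from each season's first day
(common to all sites), and a trailing short block keeps its true effort
rather than being discarded. Weeks in which the camera was never active are
structurally missing (code −1). Weeks with 1–6 active days are kept as
observations — discarding them would waste data and bias detection
downward — and the number of active days ("Number") is offered to the
detection model as a covariate instead, entering the logit linearly and
unstandardised (the fit is invariant to affine rescaling of a linear
term). For the multistate history, a week with any adult-male image is
coded 2 regardless of other images, because the male state subsumes the
species state.

## The three likelihood families

All parameters are probabilities on the logit scale. A two-level seasonal
factor (winter/summer) is present on occupancy and detection in every
model; years share parameters by level, since no between-year differences
are modelled beyond what covariates explain.

**Multiseason, implicit dynamics.** Each season is an independent primary
period: the site's occupancy state is redrawn between seasons, so the model
has no colonisation/extinction parameters and between-season change is
treated as random. Per site-season,

$$L = \psi \prod_w p_w^{y_w}(1-p_w)^{1-y_w} + (1-\psi)\,\mathbf{1}[\text{all } y_w = 0],$$

with the product over non-missing weeks. This is the right default when
seasonal movement in and out of a small study area is plausible, as it is
for deer.

**Multistate.** States are (1) absent, (2) present without adult males, (3)
adult males present. Occupancy splits into overall occupancy ψ and
conditional male occupancy R; detection splits into p1 (state 2), p2
(state 3) and the conditional detection δ, the probability that a detection
week at a male-occupied site includes a male. δ is defined per week — given
the species was detected in a week, was a male among the detections — which
matches how the weekly codes are constructed. A history containing a code-2
week puts zero mass on states 1 and 2 by structure. The candidate grid
(2×3×2 = 12 models) varies R, the state structure of detection, and δ;
effort is not carried in this family's grid, whose published parameter
counts (8–10) leave no room for it.

**Two-species.** One season, paired weekly codes. Latent states
both/A-only/B-only/neither have probabilities built from ψ_A, ψ_B and a
log-scale co-occurrence parameter η, with
ψ_AB = ψ_A ψ_B e^η and η = 0 meaning independence. η is *fixed at 0 by
default*: the published candidate sets list only species-factor occupancy
terms, and the top-model parameter count (K = 7 for
`psi(Species) p(Species × Direct + Number)`: 2 occupancy + 5 detection)
is only consistent with no interaction parameter. Setting `etaFree = TRUE`
estimates it; values of η that push ψ_AB outside the Fréchet bounds
[max(0, ψ_A+ψ_B−1), min(ψ_A, ψ_B)] are clamped and quadratically
penalised rather than crashing the optimiser.

## Covariates

Solar radiation (direct, diffuse, total; per season) is square-root
transformed — some sites receive zero direct winter sun, and a log with an
arbitrary offset is undesirable — and soil fertility covariates (C:N, pH,
available P) are log transformed; both damp the leverage of sparse large
values. Totals satisfy total = direct + diffuse, so prediction grids hold
that identity (a model in "total" evaluated along a "direct" grid uses
grid + median diffuse). Each candidate model carries at most one habitat
covariate, additively or interacting with the season (or species) factor;
the candidate sets per covariate group are 3×8+1 = 25 (solar), 25 (soil)
and 1×8+1 = 9 (plant composition), the factor-only null model counting
once per group, 59 models in all per family.

## Fitting and inference

`fitOccu()` minimises −2LL with BFGS from one data-driven start (intercepts
at logits of crude frequencies) plus seeded random starts (default 10);
the lowest value wins, earlier start on ties. The covariance of the
estimates is twice the inverse numerical Hessian of the −2LL surface;
singular Hessians are flagged rather than inverted. Estimates with
|logit| > 15 are reported with a boundary flag and not penalised — a species
detected at essentially every site legitimately drives ψ̂ to 1. Gradient
norms at the optimum are recorded. Seasons with no detections at all
trigger an identifiability warning (season-level detection parameters then
sit on the boundary).

AIC ranking uses weights normalised over the compared set, so tables
assembled from subsets renormalise transparently. Model averaging operates
on predicted probabilities, not coefficients — averaged coefficients from
different link structures have no consistent interpretation — with the
unconditional variance Σ w_m [var_m + (p̂_m − p̄)²] carrying
model-selection uncertainty. Intervals are normal on the probability scale
(clamped to [0,1]) by default, matching how averaged prediction curves are
usually drawn; a logit-scale variant is available. Per-model intervals are
delta-method on the logit scale, back-transformed, which keeps them inside
(0,1) and agrees with a parametric bootstrap to ~0.02 on the toy fits in
the test suite.

## The vegetation pipeline

Cover-abundance classes use fixed midpoints {0.5, 3, 15.5, 38, 63, 88}% —
the open class "<1%" is set to 0.5 and the others to arithmetic midpoints
of their ranges. Importance values (midpoints summed over the seven height
tiers) are standardised by site totals to proportions, then fourth-root
transformed; standardising first makes the result invariant to site
sampling volume. Bray–Curtis similarity and UPGMA clustering are computed
via vegan/stats with deterministic tie behaviour; merge heights are checked
against a brute-force linkage oracle in the tests. SIMPER is implemented
directly from its definition (per-species terms of the Bray–Curtis sum,
averaged over cross-pairs) so that contributions sum *exactly* to the
average between-group dissimilarity — a stricter contract than summary
output of existing implementations.

NMDS is implemented in the package: Kruskal stress-1 with isotonic
regression (primary/weak tie treatment: ties in the input dissimilarities
are free), minimised by BFGS over the configuration, best of 10 seeded
random starts plus a classical-scaling start, iteration cap 500, tolerance
1e-6, ties between restarts broken by stress then restart index. The
returned configuration is centred and rotated to principal axes so Axis 1
is the dominant compositional gradient. Implementing the algorithm (rather
than delegating) lets an independent implementation (vegan's engine,
restarted) act as a cross-check; on toy matrices the two agree in stress to
better than 1e-3. The number of clusters is the caller's choice: community
counts are a property of a particular data set, not of the method.

## The synthetic-data generator

`simulationConfig()` fixes the study conditions the generator emulates: 25
sites, four 13-week seasons (two winters, two summers), covariates drawn
from truncated normal distributions whose *truncated* means are calibrated
by root-finding to the published summary values (winter direct solar
0.0–5.0 with mean 0.7 mols m⁻² day⁻¹; diffuse 0.2–2.4, mean 0.6; summer
direct 0.3–9.5, mean 1.9; C:N 11–24, mean 14.9; pH 5.4–6.9, mean 6.2;
available P 3–41, mean 13.5 µg g⁻¹), standard deviations set from the
published standard errors (SE×√25), and total solar equal to direct +
diffuse by construction. Effort is 7 days minus rare per-day outages
(probability 0.012/day) with occasional whole-week failures (0.003),
mirroring SD-card and maintenance losses; these rates put per-season
camera-day totals in the study's observed 2200–2760 envelope. True
occupancy and detection parameters are logit-scale defaults chosen so
naive occupancies and detection frequencies are of the same order as the
study's: the focal species common in all seasons with a positive direct-sun
effect on both ψ and p, the second species nearly absent in winter
(season-specific ψ ≈ 0.005/0.03) and common in the final summer, and a
multistate configuration with higher male conditional detection in winter
(δ 0.5 vs 0.25). The two-species fixture is assembled from the two
independent single-species simulations, so independence (η = 0) holds by
construction.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring cameras, animal movement and home ranges (states are drawn
directly), individual detection heterogeneity, and year effects. Passing
tests therefore demonstrate estimator correctness under the model's own
assumptions, not robustness to their violation in real data.

## Numerical choices and problem sizes

Likelihood terms are clamped at 1e-300 before logs; probabilities come
through `plogis`, so linear predictors of ±40 represent structural 0/1 in
tests. The test and acceptance suites use deliberately small enumerations
(one site, ≤4 weeks, complete outcome spaces of ≤81 histories) to verify
that each family's likelihood sums to exactly 1; a 3-site toy against a
0.001-step (ψ, p) grid search; and a 200-replicate, 500-site recovery study
at ψ = 0.7, p = 0.4 — sizes chosen to give tight Monte Carlo error while
keeping the whole suite in tens of seconds.

## Known limitations

- The PAO-style file format is this package's documented plain-text
  dialect, designed for bit-exact round-trips; it does not parse binary
  files written by other occupancy software.
- The multiseason family is implicit-dynamics only; colonisation/extinction
  parameters are out of scope by design.
- No Bayesian estimation, no spatial models, no goodness-of-fit bootstrap.
- Boundary estimates (naive occupancy near 1) make season-level occupancy
  contrasts weakly identified at 25 sites; the boundary flag and the
  identifiability warning surface this, but small-grid inference remains
  intrinsically imprecise.
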