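---
title: "Methods: thermal plasticity, range position, and landscape heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal plasticity, range position, and landscape heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoplast)
```

## The scientific problem

Populations of a species do not respond identically to temperature. Grown
side by side under several temperature treatments, each population traces a
*reaction norm* — here taken as linear in temperature — and the magnitude of
its slope measures its thermal phenotypic plasticity. Two classes of
hypotheses predict where plastic populations should sit: near the range
edge or climatic niche edge (range-position hypotheses), and in
fine-grained, heterogeneous landscapes where microclimates vary over
dispersal-relevant distances (heterogeneity hypotheses). This package
implements the full chain from raw trait records to a formal comparison of
those hypotheses, together with a synthetic generator that makes the whole
chain testable against known ground truth.

## Quantifying plasticity: the random-regression model

`fit_reaction_norm()` fits, per species × trait,

$$ y_{ijk} = (\beta_0 + u_{0k}) + (\beta_1 + u_{1k})\,T^{(s)}_{ij} + r_j + \varepsilon_{ij}, $$

where $T^{(s)}$ is the treatment temperature z-scaled over the observation
rows (sample mean 0, SD 1 — the scaling a back-transformation must invert;
per-°C values are obtained by dividing scaled-unit slopes by the
temperature SD in °C), $(u_{0k}, u_{1k})$ is a population-level random
intercept/slope pair with an unstructured 2×2 covariance, and $r_j$ is a
replicate-chamber random intercept. Continuous traits use a Gaussian error
with identity link; germination uses a binomial error with logit link on
dish-level (germinated, viable − germinated) counts, with the marginal
likelihood by Laplace approximation (a 2-D random effect per population
makes adaptive quadrature impractical). Gaussian fits maximize the full ML
objective rather than REML so that AIC comparisons across random-effect
structures share a common likelihood.

Population-specific plasticity is $|\beta_1 + u_{1k}|$ with $u_{1k}$ the
conditional mode (BLUP) at the fitted variance parameters: the fixed slope
plus the deviation, not the deviation alone, since the population-level
minimum/maximum responses straddle the average response. The absolute value
is taken on the per-°C scale; since the two scales differ by a positive
constant, orderings are identical on either.

Support for among-population slope variation uses
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\text{intercept-only}} -
\mathrm{AIC}_{\text{intercept+slope}}$, oriented so that values above 2
indicate support for the random-slope component.

Numerical conventions:

* **Degenerate data.** If the Gaussian residual variance is numerically
  zero, the exact per-population least-squares solution is returned with
  variance parameters at the boundary rather than pushing an optimizer
  through a flat deviance. A random term whose grouping factor has one
  level is dropped, so a single-population fit reproduces OLS exactly.
* **Singular fits.** A random-slope SD estimated at 0 is returned with a
  `boundary` flag, not an error; plasticity extraction proceeds with zero
  deviations.
* **Wald inference.** Coefficient p-values are two-sided normal (Wald);
  for the balanced designs targeted here these are effectively equivalent
  to t-based intervals.

Logit-scale slopes are converted to an interpretable scale by
`logit_slope_to_percentage_points()`: the probability change for a +1 °C
step evaluated at the intercept, $100[p(\eta_0) - p(\eta_0 - \beta_1)]$
with $p(\eta) = e^\eta/(1+e^\eta)$. The derivative form
$100\,p(1-p)\beta_1$ is the documented small-slope approximation; the two
agree to two decimals at typical germination estimates.

## Trait preparation

`count_viable_seeds()` implements the cut-test rule that only empty and
infested seeds are non-viable — germinated, full, *and moldy* seeds count as
viable. Germination proportion is germinated/viable per dish; phenology
values are census days (7/14/21/28 after sowing) — interval censoring within
a week is not modeled. The population inclusion filter is strict:
populations enter the germination analyses only if their pooled proportion
exceeds 5% (exactly 5% is excluded); the filter pools dishes by default,
with a per-treatment variant available. Flower abundance is square-root
transformed before fitting.

## Range position

**DRE** is the planar distance (km) from a site to the nearer of the
northern and southern portions of the range boundary. The boundary is split
at the site's latitude: segments (or pieces of segments, split where they
cross the east–west line through the site) north of the line form the
northern edge, those south of it the southern edge, and DRE is the minimum
point-to-segment distance over the two sets. Splitting at the latitude —
rather than classifying whole segments by their vertices — keeps the metric
continuous in the site location and makes it verifiable against dense
boundary sampling. Coordinates are assumed planar/projected; real data must
be projected before use, and no geodesy is attempted.

**DCE** uses a PCA of the climate variables over range cells, z-scored with
cell-derived means and SDs that are also applied to the site climates (so
sites are projected into the *range's* climate space). Loadings are
oriented so each component's largest-magnitude loading is positive, a pure
reporting convention. The niche is the convex hull of cell scores in
PC1–PC2, and DCE is the minimum distance to a hull *edge segment* (not
vertex — edges are strictly closer or equal). Sites outside the hull (a
possibility with real data against a digitized range) are flagged
`exterior` rather than given signed distances, since no sign convention is
established for this metric.

## Landscape heterogeneity

All three metrics are computed in a square buffer extending 500 m from the
site in every direction (1,000 m side), extracting whole cells whose
centers fall in the closed square — with 10-m rasters, a 100×100-cell
window. Conventions, chosen to match standard landscape-metrics practice
and stated here because they are genuine dialect choices:

* **SHDI** $= -\sum_i p_i \ln p_i$ over class proportions by cell count.
* **Patches** are connected components of equal-class cells under
  8-neighbor adjacency by default (4-neighbor selectable), labeled
  deterministically in scan order.
* **PAR** is the arithmetic mean over patches of perimeter/area (1/m),
  with perimeter counting cell sides adjacent to a different class *or to
  the buffer boundary* (patches truncated by the buffer are closed at its
  edge, keeping the metric deterministic).
* **ARE** is the Sa average roughness: mean absolute deviation of cell
  elevation from the buffer mean, in meters, without detrending by default
  (planar detrending is available as an option).

## The driver analysis

Per-population plasticity values are joined to the five site metrics, each
freshly z-scaled across the included populations (re-scaled after any row
exclusion). The candidate set is the Cartesian product of one
range-position metric (DRE or DCE) × one heterogeneity metric (SHDI, PAR,
or ARE) × with/without their interaction — 12 models per trait, each with
at most two main effects and their product. Models are fitted by OLS and
ranked by AIC computed from the Gaussian log-likelihood with the residual
variance counted as a parameter; ties within ΔAIC ≤ 2 of the best are
reported as additional supported models, and the selection tie-break is
lowest AIC then fewest parameters. A Spearman correlation screen across
the five metrics flags pairs with |ρ| ≥ 0.7 as potentially collinear.

LMG relative importance decomposes the selected model's R²: each regressor
column receives the average of its sequential R² increment over all
orderings of the columns, computed via the subset formulation with weights
$|S|!\,(t-1-|S|)!/t!$ (identical to full permutation enumeration, at
$2^t$ rather than $t!$ cost; enumeration above 10 regressors is refused).
The interaction column is treated as an ordinary regressor — its share is
reported separately, without marginality constraints, which is a documented
dialect choice. Shares are expressed against *total* variance, so shares
plus the unexplained component $1 - R^2$ sum to one.

## The synthetic generator

The generator emulates the study design rather than any particular
dataset: 3 species × ~8–18 populations, four daytime treatments
(16/20/24/28 °C), two replicate chambers, up to 10 plants per population ×
treatment, and 25-seed germination dishes whose cut-test categories (empty
≈ 5%, moldy ≈ 4%, infested ≈ 3% of sown seeds) exercise the viability
rules. Ranges are star-shaped noisy ellipses (~500 × 300 km) in planar km
coordinates; climate variables follow a monotone north–south gradient plus
independent noise so a climatic niche exists. Landscapes are smoothed
Gaussian random fields thresholded into equal-probability classes: the
smoothing length shrinks geometrically with the heterogeneity knob (so the
buffer is dominated by one class at low knob and finely mixed at knob 1),
and elevation amplitude grows linearly with the knob — both expected SHDI
and expected ARE are therefore non-decreasing in it, with knob 0 yielding
exactly one class on flat terrain.

Trait data follow the fitted model's own structure. Two slope models are
provided and auto-selected:

* **plain** — $b_k = \beta_1 + e_k$, $e_k \sim N(0, \sigma_b)$: the
  classic random-regression generating model, used when no driver
  coefficient is set; this is the model under which variance-recovery
  experiments are calibrated.
* **driven** — $b_k = s_k \max\{0,\ |\beta_1| + \gamma_{rp}RP_k +
  \gamma_{eh}EH_k + \gamma_{int}RP_kEH_k + e_k\}$ with a random sign
  $s_k \in \{-1, +1\}$: plasticity (an absolute value) is the driven
  quantity while both response directions occur, matching the structure of
  the driver analysis. The magnitude floor at 0 keeps $|b_k|$ well-defined
  and is a documented generator convention. Note the realised SD of signed
  slopes under this model is $\approx\sqrt{\beta_1^2 + \sigma_b^2}$, not
  $\sigma_b$ — which is why recovery experiments use the plain model.

Within-replicate errors are independent Gaussians on top of a shared
replicate intercept; the real error structure of chambers is unknown, and
this independence is an assumption. The generator makes no attempt at
spatially autocorrelated gene flow, seed dormancy physiology, or real
geodesy — so passing tests demonstrate the *estimators* behave correctly
under the stated model, not that the model captures every feature of real
common-garden data.

## Problem sizes and verification

The test suite verifies each metric against an independent naive
implementation (nested loops, label propagation, permutation enumeration,
dense boundary sampling at 10⁴–2×10⁴ points), and the estimators by
Monte-Carlo: parameter recovery at 20 populations × 4 treatments × 2
replicates × 10 individuals over 50 replicates (mean truth–estimate slope
correlation ≥ 0.8; mean random-slope SD estimate within [0.15, 0.45] for a
true 0.3); AIC selection of a true (DCE, ARE) interaction model at 60
populations in ≥ 70% of 100 replicates; interaction-test size ≤ 14% at
nominal 5% over 200 null replicates; and random-slope ΔAIC support in
≥ 90% of replicates when the slope SD is 1.0 (residual SD 0.5, 5
individuals) and ≤ 20% when it is 0. These sizes keep the full suite
within a couple of minutes on one core while leaving the Monte-Carlo
margins wide.

## Known limitations

* Reaction norms are linear only; quadratic or spline norms are out of
  scope, as are Bayesian fits and species-as-random-effect driver models.
* Driver models pool species; phylogenetic or species-level
  non-independence is not modeled.
* No geodesy: all geometry is planar, and rasters are not reprojected or
  resampled; no-data cells are an error, not a handled case.
* The 5% germination filter's pooled-vs-per-treatment scope is not settled
  by the design it mirrors; pooled is the default, per-treatment an option.
* Whether plasticity should be fixed+BLUP or BLUP-only is a genuine
  ambiguity; fixed+BLUP is adopted (population min/max responses straddle
  the fixed estimate), and only the absolute value is used downstream.
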