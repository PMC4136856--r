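---
title: "Methods: occupancy-based corridor planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy-based corridor planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corridorscape)
```

`corridorscape` chains three analyses that are usually scattered across
field-ecology scripts and desktop GIS: estimating a species-environment
relationship from imperfect detection data, translating it into a movement
cost surface with least-cost and circuit corridors, and stress-testing
management options on that surface. This vignette explains the models, the
defaults and why they were chosen, what the synthetic generator does and
does not emulate, and the numerical conventions that make results
reproducible.

## The occupancy model

The statistical core is the single-season (closed) occupancy model. Each
site $i$ has a latent state $z_i \sim \mathrm{Bernoulli}(\psi_i)$; each
survey occasion $t$ yields $y_{it} \sim \mathrm{Bernoulli}(z_i\,p_{it})$.
Marginalising $z_i$ gives the zero-inflated binomial likelihood

$$L_i = \psi_i \prod_t p_{it}^{\,y_{it}} (1-p_{it})^{1-y_{it}}
      + (1-\psi_i)\,\mathbb{1}[\textstyle\sum_t y_{it} = 0],$$

with missing occasions skipped. Both $\psi$ and $p$ are logit-linear:
$\psi$ in site covariates (elevation, slope class, forest age and
composition, bamboo presence, reserve class, distances to roads,
residences and cropland), $p$ in occasion covariates (scent lure applied;
temperature class cut at 5 °C and 15 °C; camera view open/limited).

Assumptions worth stating plainly: occupancy is closed within the season
(the generator draws $z$ once per site, no turnover); detections are
independent across occasions given $z$; detection covariates are constant
within a deployment (lure and view are set at deployment, temperature
comes from the deployment's month). Detection histories are built by
cutting each deployment into consecutive 5-day segments from its start
day; a trailing partial segment is dropped so every occasion represents
equal effort — keeping it would require an effort covariate the data model
does not carry. A 38-day deployment therefore yields 7 occasions.

### Fitting

`fit_occupancy()` minimises the negative log-likelihood by BFGS with an
analytic gradient, from the zero vector plus deterministically jittered
extra starts (5 by default; the jitter is a fixed sinusoidal offset, not
RNG, so fits are bit-reproducible). Continuous covariates are z-scored
internally — this stabilises the optimisation — and the standardisation
constants are stored in the fit, so predictions and back-transformations
to the raw scale are exact. Estimates are capped at $|\mathrm{logit}| =
15$ with a `boundary` flag so degenerate inputs (e.g. all-detected data)
terminate cleanly instead of diverging.

### Selection and averaging

The selection protocol is two-stage. First, with *all* candidate occupancy
covariates in the model, every subset of the detection covariate pool is
fitted and the minimal-AIC subset is kept (ties go to fewer terms, then
lexicographic order). Second, holding those detection terms fixed, every
subset of the occupancy pool is fitted and ranked by AIC with
$\Delta$AIC, Akaike weights and cumulative weight.

Model averaging takes the $\Delta\mathrm{AIC} \le 2$ set, renormalises its
weights, and averages coefficients with **zero substitution**: a model
that omits a term contributes zero to that term's average. We chose zero
substitution (over conditional averaging) because it makes the averaged
coefficient and the importance weight — the summed renormalised weight of
the models containing the covariate — mutually consistent: a covariate
with importance 0.5 is shrunk by half. The renormalisation itself is a
convention; nothing in the averaged map depends on it beyond the top set.

Two behaviours of this machinery are worth knowing. (1) Plain AIC subset
selection admits a spurious one-parameter covariate with probability
$P(\chi^2_1 > 2) \approx 0.16$, so "exact true subset selected" tops out
around 70 % even with strong effects — the package's tests assert the
modal subset, not an unachievable exact-recovery rate. (2) Zero
substitution biases weakly supported coefficients toward zero by design;
with strong effects the top set contains the terms and the bias is
negligible, which the 100-replicate recovery test demonstrates.

### Functional forms and collinearity

`select_covariate_form()` compares raw $x$, $\log(x+1)$ and $x + x^2$ for
each continuous covariate in single-covariate models with null detection,
keeping the smallest AIC (ties prefer the simpler form, in that order).
The $+1$ tolerates the zero distances that occur exactly at features.
`screen_collinearity()` enforces pairwise $|r| < 0.7$ by greedy
elimination: of the worst pair, drop the member with the larger mean
absolute correlation to everything else; ties break by a caller-supplied
priority order, then alphabetically. Greedy mean-|r| elimination is the
common convention; the explicit tie order makes it deterministic and
idempotent.

## Validation

The suitability map $\hat\psi$ is validated against independent transect
segments. A segment is a presence if sign was found on it; an *absence*
only if no sign was found there **and** no sign-bearing segment lies
within 1 km — sign-free segments near sign are ambiguous and dropped
rather than labelled (labelling them absent would contaminate the
negative class; nothing justifies calling them present). AUC is computed
by the rank (Mann–Whitney) statistic with midrank ties, which is exact
and tie-robust, rather than by integrating a thresholded curve.

## Cost surfaces and least-cost corridors

"Inverse of suitability" is ambiguous, so the default cost surface is the
affine inversion $c = c_{\min} + S(1-\psi)$ with $c_{\min} = 1$, $S = 99$
(range 1–100): strictly positive, bounded, and the dominant convention in
connectivity work. A reciprocal option ($1/\max(\psi, 10^{-3})$) is kept
for sensitivity analysis. Absolute cost values are therefore
scale-conventional; only orderings and relative differences carry
meaning.

Least-cost machinery runs Dijkstra on the 8-neighbour raster graph with
edge weight $\tfrac{1}{2}(c_a + c_b)\,d$, $d$ the cell size (orthogonal)
or $\sqrt2$ times it (diagonal) — the usual GIS cost-distance semantics.
The kernel is compiled (Rcpp) with a fixed neighbour visit order
(N, NE, E, …) so tie-breaking, and hence the backlink raster (predecessor
compass codes 0–8), is deterministic. Nodata cells are impassable
everywhere. `enumerate_pathways()` produces one least-cost path per
source × sink pair — five points per valley side gives the 25-pathway
set, the cheapest flagged optimal — and each pathway carries a
cost-per-100-m index, $100\,C/L$, so pathways of different lengths are
comparable.

## Circuit model

The same cost surface doubles as a resistor network (edge resistance =
least-cost edge weight), so the two connectivity models are directly
comparable. `solve_pairwise()` fixes the ground set at 0 V, removes those
rows/columns, and solves the reduced sparse Kirchhoff system by Cholesky;
effective resistance is the mean source potential per unit injected
current, and per-cell current density is half the summed absolute branch
currents. Interior Kirchhoff balance is checked to $10^{-8}$ relative.
The omnidirectional map pads the surface with a uniform-cost buffer
(width 5 cells by default, cost = mean passable cost), spaces focal nodes
evenly on the buffer perimeter (16 by default), solves all — or a seeded
subsample of — focal pairs with one shared factorisation (one fixed
ground node; each pair injects $+I/-I$), sums the current maps, and crops
the buffer. The buffering removes the edge bias of focal placement; the
node count and subsample trade accuracy for time and are recorded in the
run manifest.

Corridor *width* has no canonical estimator; `measure_corridor_width()`
is an explicit artifact convention: along a straight transect, the
longest contiguous run of cells strictly above the transect's q-quantile
(default 0.75) of current, times the cell size.

## Scenarios and their statistics

`apply_scenario()` supports three edits, applied in declared order:
restore forest (inside a polygon: forest age → primary, bamboo →
present), remove residences (by size class, optionally within a region),
and tunnel (remove a chainage interval of a road — the abandoned roadbed
is treated as passable; no tunnel-mouth disturbance is modelled, as there
is no parameter to support one). Only the derived layers whose inputs
changed are recomputed; everything else is returned bit-identical, and a
locality test asserts it.

`scenario_costs()` re-predicts $\psi$ with the *same* averaged equation,
re-inverts, and re-evaluates the **fixed** baseline path geometries —
the question is how the identified pathways fare under each option, not
where new pathways would go. The comparison is a two-factor ANOVA
without interaction (scenario + pathway; with one observation per cell an
interaction would leave no residual degrees of freedom — 25 pathways ×
4 scenarios give df 3, 24 and 72) followed by paired t-tests with Holm's
step-down adjustment, $p^{holm}_{(i)} = \max_{j\le i}(m-j+1)p_{(j)}$
capped at 1, at family-wise $\alpha = 0.05$. Identical columns yield an
undefined t and are reported with adjusted p = 1 rather than dropped.

## The synthetic generator

`generate_landscape()` emulates a single north–south river valley between
two mountainside reserve blocks: a Gaussian valley elevation profile
(floor 1000 m, relief 1200 m, half-width 2 km) plus smooth FFT-filtered
noise; a provincial road meandering along the valley axis; residences
clustered along the road (large ones, ≥ 3 households, hugging it);
cropland rectangles on the floor; bamboo concentrated in a 1600 ± 400 m
elevation band; patchy forest age and composition fields (1.5-km
correlation length). All distance layers are computed from the features;
with no matching feature they take a finite cap (the grid diagonal) so
covariates never become infinite. Everything is deterministic given the
seed. The default working resolution is 100 m, a typical choice for
camera-grid studies of a few hundred km².

The generating ("true") occupancy model uses elevation (−1.2), bamboo
presence (+1.2) and secondary forest (−1.2) on the population-standardised
scale, with detection improved by lure (+1.0) and degraded by warm
weather (−0.4 / −0.9) and unaffected by camera view. Two deliberate
choices: the effects are strong because the generator's role is a
well-powered recovery study (importance weights near 1 for the true
terms), and the generating covariates are a *screened* set — in a valley
template every human-infrastructure distance is nearly collinear with
elevation (pilot correlations 0.91–0.98), so a generating model containing
both would be statistically unidentifiable; the collinearity screen
exists precisely for such landscapes. Truth-versus-estimate comparisons
are made on the raw covariate scale, where they are invariant to either
side's standardisation.

What the generator does **not** emulate: real terrain hydrology, animal
movement (no telemetry-like data), spatial autocorrelation of detections
beyond what the smooth covariates induce, observer heterogeneity, and
seasonal turnover. Passing tests therefore certify the estimators and the
pipeline plumbing, not the ecological fidelity of any particular map.

## The valley demonstration fixture

`valley_demo_fixture()` is a fully *constructed* scenario testbed — its
predictive equation (`constructed_barrier_model()`) has chosen, not
fitted, effect sizes: a strong road-avoidance term (+3.5 standardised), a
large-residence term (+2.0), moderate bamboo/forest terms (±0.4), a mild
elevation term (−0.3), and distance covariates saturated at a 1-km
influence radius (`saturate_distances()`), so edits act locally. Its
landscape keeps one stretch of the valley free of residences; all 25
pathways funnel through that settlement-free gap, the tunnel is placed
under the optimal corridor's road crossing, and the restoration polygon
is the valley band. These constructions encode the mechanism being
demonstrated: the road toll dominates every crossing, residences add to
it only where they stand (not in the corridor), and habitat restoration
helps everywhere a path runs but cannot remove the toll. The resulting
comparison — tunnel and restoration significantly below baseline,
relocation indistinguishable from it, tunnel below restoration — is a
property of the constructed fixture, verified by the test suite, not an
estimate from data.

## Numerical conventions and problem sizes

* Rasters are row-1-north matrices in planar metres; cell centres carry
  values; I/O is the plain-text ESRI ASCII grid dialect; features travel
  as GeoJSON, tables as CSV.
* The likelihood floors $L_i$ at $10^{-300}$ before logging; the
  optimiser uses `reltol` $10^{-10}$, 300 iterations.
* Dijkstra ties resolve by the fixed neighbour order; the circuit solver
  is exact sparse Cholesky (no iterative tolerance).
* Per-stage seeds in `run_pipeline()` derive from the global seed and a
  stage-name hash, so stages re-run in isolation reproduce exactly.
* Test and recovery studies use a 120 × 120-cell landscape, 250 sites ×
  8 occasions, 100 Monte-Carlo replicates, 216 validation segments, and
  an 80 × 80 scenario fixture with 25 pathways — sizes chosen so the
  whole suite exercises every stage at meaningful power while remaining
  comfortable on a single CPU.
* Detection coefficients at these sizes carry the ordinary $O(1/n)$
  logistic-MLE bias (~0.05), visible against a Monte-Carlo standard
  error of ~0.02; the recovery criterion is therefore stated for the
  occupancy coefficients, and detection estimates are held to an
  absolute bias bound instead.

## Known limitations

Planar geometry only (no projections or datums); single season (no
dynamic occupancy); no spatial random effects or autocorrelation
diagnostics; no standard errors for averaged coefficients (a bootstrap
would be the honest route); corridor width is a reporting convention, not
an estimator; and the circuit solver targets grids up to a few hundred
cells on a side, not continental rasters.
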