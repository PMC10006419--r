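---
title: "Linking regional land-use diversity to avian taxonomic and functional richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional land-use diversity to avian taxonomic and functional richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviland)
```

## The analysis this package implements

`aviland` implements, end to end, a macroecological analysis that asks
whether the *diversity of land-use types* within a region predicts how many
bird species live there (taxonomic richness) and how much trait variety
those species span (functional richness). The analysis operates on an
equal-area grid of roughly one-degree cells. Each cell carries:

* a **land-use Shannon index** `H = -sum(p_c * log(p_c))`, where `p_c` are
  the proportions of categorical land-cover classes (up to 22, after the
  Copernicus-style legend) among the fine-resolution pixels inside the cell,
  in nats (natural log, no evenness normalization);
* **taxonomic richness**, the count of species whose ranges reach the cell;
* **functional richness (FRic)**, the volume of the convex hull enclosing
  the cell's species in a five-axis functional trait space;
* a productivity proxy (mean NDVI per cell, "NPP") and median environmental
  covariates (elevation, temperature, precipitation, human footprint);
* a biogeographic realm label.

The statistical core regresses log richness on smooth functions of the
land-use Shannon index, cell coordinates and NPP, compares nested model
variants by AIC and deviance explained, measures variable importance by a
leave-one-out jackknife, and summarizes per-realm effects as partial linear
slopes with 95% confidence intervals.

Because the global range polygons and land-cover extractions behind the real
analysis are gated or impractically large, the package pairs the analysis
chain with a *first-class synthetic-world generator* whose ground truth is
known exactly. Every downstream stage is validated against that truth (or
against independent oracles), so the pipeline is fully testable offline.

## The functional space

The trait table reduces eleven raw variables to six:

1. `PCA1m`, `PCA2m`: the first two axes of a PCA of log10 body mass, tarsus
   length, wing length and tail length (correlation matrix, i.e.
   standardized columns). The first axis is anchored so body mass loads
   positively; it reads as overall size, the second as body shape.
2. `PCA1b`: the first axis of a PCA of the four beak measurements after
   *size correction* — each log10 beak trait is regressed (OLS) on log10
   body mass and replaced by its residual, which is exactly orthogonal to
   mass.
3. `HWI`: the hand-wing index, entered raw (it is weakly related to the
   other traits, and Gower's range normalization makes its scale
   irrelevant).
4. Trophic niche (10 levels) and primary lifestyle (5 levels) as categorical
   variables.

Pairwise species dissimilarity is the **Gower distance**: range-normalized
absolute difference for quantitative variables, simple mismatch for
categorical ones, combined as a weighted mean with equal weights (1/6). The
additive structure gives an exact decomposition of the mean distance into
per-trait contributions (`trait_contributions()`), which sum to 1 by
construction; matrix correlations between each per-trait distance matrix
and the global one are reported as a secondary diagnostic.

A principal coordinates analysis (classical scaling via `stats::cmdscale`)
of the Gower matrix yields the functional space; the first five axes are
retained, scaled by the square root of their eigenvalues. Gower distances on
mixed data are typically non-Euclidean, so some eigenvalues are negative;
they are reported but not corrected (no Cailliez/Lingoes adjustment), and
variance explained is taken over the positive eigenvalues only. Axis signs
are fixed deterministically (largest-magnitude coordinate positive) so score
files reproduce bit-identically across platforms.

FRic for a cell is the hull volume of its species' five-axis coordinates,
computed by an incremental (beneath-beyond) convex-hull construction in
`src/`. Assemblages whose points are affinely degenerate in five dimensions
get `NA` with a flag rather than zero — a zero would silently distort the
log-scale model fits, whereas flagged cells are excluded from the
functional-richness models only. Tests check the hull against closed forms
(simplex, hypercube), an exact combinatorial enumeration for small clouds, a
Monte-Carlo rejection estimator, and the qhull implementation available
through the system Python.

## The synthetic world

`world_config()` fixes the study conditions; `generate_world()` produces a
world from named random substreams of one master seed, so identical configs
are bit-identical and any stage can be regenerated alone.

* **Land cover.** Each cell draws a Dirichlet concentration parameter
  log-uniformly, then class weights from that Dirichlet; pixels are sampled
  in 2x2 blocks for within-cell spatial grain. This directly produces the
  target gradient of realized per-cell Shannon diversity, from
  near-monodominant (H near 0) to near-uniform (H above 2) cells. A smooth
  sea mask turns trailing pixels of low-land cells into no-data so land
  fraction varies and the <10% land filter has work to do.
* **Productivity.** Cell NPP is a standardized mixture
  `w * H_std + sqrt(1 - w^2) * G` of realized Shannon diversity and an
  independent smooth Gaussian field, mapped linearly onto an NDVI-like 0-1
  scale. The mixing weight `w` (default 0.49) equals the target correlation
  in expectation; on a 20x20 grid the smooth field has a modest effective
  sample size, so realized correlations fluctuate around, and average a few
  hundredths below, the weight (mean ~0.485 over 100 worlds). An earlier
  variant that orthogonalized `G` against `H` in-sample pinned the
  correlation exactly but made NPP an exact linear function of the focal
  regressor, which measurably distorted partial-slope inference; the
  independent-field mixture is used instead.
* **Species pool.** Log-normal morphometrics with a configurable allometric
  correlation (default 0.7 on the log scale) to body mass; a shared
  beak-shape factor; raw hand-wing index; non-degenerate categorical
  frequencies. Habitat affinities give every land-cover class a dedicated
  specialist subpool, plus a generalist fraction (default 20%) with affinity
  for all classes.
* **Occupancy.** A species can only occupy a cell that contains at least one
  of its affinity classes. Conditional on that gate, the occupancy
  probability is *log-linear*:
  `p = p0 * exp(f(H) + effect_npp * (npp - 0.5)) * clump`, capped at 0.95.
  With the default baseline `p0 = 0.05` the cap never binds, so in a
  generalist-only world the slope of log expected richness on H is exactly
  `effect_lu_diversity` — this is what makes parameter-recovery tests sharp.
  (A logistic link was considered and rejected: it attenuates the
  log-richness slope by a factor of roughly `1 - p`, so the configured
  effect would no longer be the recoverable truth.) `f` is linear by
  default; the `"saturating"` option, `effect * 1.25 * (1 - exp(-2H))`,
  matches the linear slope at the origin and plateaus above H of about 1.5,
  providing a known curved truth for shape-recovery checks.
* **Range cohesion.** No dispersal model is implied by the analysis itself,
  so clumping is a free design choice: each species gets a range center and
  a toroidal Gaussian kernel (sd 15% of the domain) mixed with a constant
  floor (`clump = 0.5 + 0.5 * kernel`). The torus keeps the expected kernel
  mass identical for every cell, so clumping adds realistic spatial
  structure to ranges without making expected richness depend on position.
* **Realms** are contiguous longitudinal blocks — the simplest partition
  that supports by-realm smooths and per-realm slopes.
* **Covariates** (elevation, temperature, precipitation, human footprint)
  are smooth fields independent of everything else; their true effect is
  zero, which the model-comparison and jackknife null checks rely on.

The generator returns the exact expected-richness surface alongside the
Bernoulli draw, so tests can assert against the truth rather than against
another estimate.

What the synthetic world does *not* emulate: real bird biogeography or
phylogeny, realistic range-size distributions, spatial autocorrelation in
the land-cover classes between neighbouring cells, observation error in
range maps, or the semantics of the individual land-cover classes. Passing
tests therefore demonstrate that the estimators recover known effects under
controlled conditions — not that the real-world effect sizes are correct.

## Grid assembly and filters

Real-mode range records (GeoJSON polygons with seasonality and origin codes)
are filtered to resident or breeding-season records of native or
reintroduced origin; introduced-origin records are dropped, and unknown
codes are dropped with a warning and logged. Rasterization uses the
*any-overlap* rule — a species is present in a cell if any retained polygon
intersects any part of the cell — with no minimum-coverage threshold, the
common default for gridding expert range maps. The implementation is a
direct geometric test (vertices in cell, cell corners in polygon, edge
crossings) validated against a fine-lattice point-sampling oracle.

Cells are excluded when land fraction is below 10% or fewer than six
species remain — six points being the minimum to span a five-dimensional
hull. Both boundaries are inclusive on the keep side (`>= 0.10`, `>= 6`)
because the exclusions are stated as strict inequalities. The land filter
runs first and the richness filter on the survivors; since both are
per-cell predicates the order cannot change the result, but it is logged
with per-cell reasons. Synthetic mode bypasses polygons entirely and takes
occupancy from the generator.

## Models

All additive models are Gaussian on the log response (natural log of the
max-standardized metric; standardizing rescales the intercept only), with
thin-plate *shrinkage* smooths (`bs = "ts"`) of basis dimension `k = 3` for
every term, fitted by `mgcv::gam` with REML smoothing-parameter selection.
REML is a package decision (robust default for Gaussian additive models)
and is recorded in every fit object. The shrinkage basis lets the penalty
remove a term entirely, which is what makes the nested model comparison and
the null simulations behave sensibly at `k = 3`. No small constant is added
before the log: cells with zero or undefined functional richness are
excluded upstream rather than patched with a pseudo-count.

* `fit_model_suite()` fits the five nested specifications per response —
  coordinates; + NPP; + land-use diversity; + both; + both + median
  elevation — and reports AIC (effective-degrees-of-freedom based, so
  smooth and linear terms are comparable), the AIC gap to the
  best model, and deviance explained, in fixed row order. Deviance explained
  is non-decreasing along the nested chain by construction; the suite
  asserts it.
* `fit_additive()` exposes the global mixed configuration: a realm random
  intercept plus a realm random slope on the Shannon term, both as
  `bs = "re"` smooths. (Realm-specific smooth deviations would be the
  alternative reading of "random slopes"; the random-effect-on-the-linear-
  term reading is the configured default.)
* `fit_realmwise()` fits one model with a by-realm smooth of the Shannon
  index plus global coordinate smooths, optionally an NPP smooth and
  optionally a smooth of log taxonomic richness (to ask whether functional
  richness responds beyond what taxonomic richness implies). Realms with
  fewer than 30 cells (configurable) are skipped and logged.
* `jackknife_importance()` refits the full model leaving each candidate out;
  importance is the drop in deviance explained, with the AIC increase
  alongside. Near-duplicate predictors mask each other — by design this is
  reported, not "corrected".
* `partial_slopes()` is the standardization step: per realm and metric, an
  ordinary linear model of the log response on the Shannon index with
  longitude, latitude and NPP as covariates; the Shannon coefficient with a
  two-sided 95% CI, flagged significant when the interval excludes zero. No
  multiple-testing correction is applied across realms (slopes are reported
  per realm as estimates, not as a family of hypothesis tests); readers
  comparing many realms should bear that in mind.
* `residual_diagnostics()` screens residuals against both coordinates
  (Pearson r with p; pass when |r| < 0.05) and checks normality
  (Shapiro-Wilk up to n = 5000, a moment-based test above).
* `sensitivity_k()` reruns the realm-wise fits at `k = 3` and `k = 4` and
  reports per-realm sign and significance agreement.

## Numerical choices and degenerate inputs

* Log base: log10 for trait transforms (scale only; PCA geometry is
  unaffected), natural log for responses and the Shannon index.
* PCAs on correlation matrices; deterministic sign conventions throughout.
* Zero-range quantitative trait, constant PCA column, zero-variance body
  mass: errors naming the offender, since each silently breaks a
  normalization.
* Hull tolerance: visibility threshold 1e-10 after centering and scaling
  each coordinate to unit range; points within tolerance of the boundary
  are treated as interior, which cannot change the volume beyond that
  tolerance.
* Cells with zero classified pixels get `NA` Shannon values and are flagged;
  no-data pixels are excluded from the proportion denominator, and all
  analysis classes (including water classes of the legend) count when
  present.
* Ties in `standardize_to_max`: every maximal cell maps to exactly 1.

## Problem sizes and calibration evidence

The default synthetic study is a 20x20 grid (8x8 pixels per cell, 22
classes), 500 species, six realms — large enough that every estimator is in
its working regime and small enough that a replicate world fits in about a
second. The packaged checks compute, over 100 seeded worlds each: coverage
of the generating land-use slope by the partial-slope CI (target >= 90%,
observed 89-93% across seed blocks); the rate at which fully null worlds
are flagged non-significant (observed 94-98%, nominal 95%); the rate at
which the model comparison selects the specification containing both true
drivers (observed 100%); and the rate at which the jackknife ranks the
single true driver first under orthogonal predictors (observed 100%).

Two calibration caveats are worth stating plainly. First, the coverage and
null-calibration checks run on generalist-only worlds: with habitat gating
active, class presence itself responds to land-use diversity, so the
configured coefficient is no longer the whole truth and CI coverage of that
single number is not the right question. Second, the null-calibration check
uses fully null worlds. When a strong productivity effect is present, cell
means — and therefore log-scale variances — vary several-fold across cells,
and the unweighted linear model is measurably anticonservative for the
Shannon slope (about 7% type-I over 500 replicates instead of 5%). That is
a property of the plain-`lm` slope structure itself; users comparing
borderline per-realm significance should treat it as such.

## Using the pipeline

```{r, eval = FALSE}
cfg <- run_config(world = world_config(seed = 1))
run_dir <- run_pipeline(cfg, outdir = "aviland_run")
make_report(run_dir)
```

The run directory contains the world (rasters as TSV, tables as CSV, config
as YAML), the exclusion log, the per-cell metrics table, the model
comparison, per-realm partial-effect curves, the slope table, jackknife
importances, residual diagnostics, the k-sensitivity report, and a manifest
with MD5 hashes of every output; rerunning with the same config reproduces
every file bit-identically. A thin command-line wrapper with the same
options ships in `inst/cli/aviland.R`. Real-data mode expects
pre-extracted CSV inputs (trait table, long-format occupancy, grid
attributes, per-cell land-use table) and validates their paths at startup;
the geospatial extraction itself (Earth-engine zonal statistics, global
polygon processing) is out of scope.

## Known limitations

* The convex-hull FRic scales poorly with richness in principle; the
  incremental construction is comfortable for assemblages up to a few
  thousand species in five dimensions, which covers realistic grid cells.
* Coordinates-as-smooths is the only spatial control, as in the analysis
  this package implements; no autoregressive error structure is offered.
* Presence-only data: no abundance weighting, no rarefaction, no null-model
  standardized effect sizes.
* The synthetic generator's realized NPP-diversity correlation is exact only
  in expectation (see above).
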