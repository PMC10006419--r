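# aviland

Does a region with more kinds of land cover hold more bird species, and a
wider variety of bird ecologies? `aviland` is an R package for that
question: a tested, reproducible pipeline linking regional **land-use
diversity** to avian **taxonomic** and **functional richness** on an
equal-area grid. It is aimed at macroecologists and biodiversity
informaticians who want the full analysis chain — grid assembly, functional
trait space, diversity and land-use metrics, and the competing-model
comparison — runnable and verifiable on a desktop, with a synthetic-world
generator standing in for gated global datasets.

## The quantities at the core

For each grid cell with land-cover class proportions `p_c` among its
fine-resolution pixels, land-use diversity is the Shannon index in nats:

    H = - sum_c p_c * ln(p_c)

(0 for a homogeneous cell, unbounded as classes proliferate). Taxonomic
richness `S` is the count of species present. Functional richness (FRic) is
the volume of the convex hull of the cell's species in a 5-axis functional
space built as: trait PCAs (log10 body traits; size-corrected beak
residuals) + raw hand-wing index + trophic niche + lifestyle → Gower
distances (equal weights) → principal coordinates analysis, keeping five
axes. The statistical layer fits Gaussian additive models of
`ln(S)` or `ln(FRic)` (max-standardized) on shrinkage thin-plate smooths
(`k = 3`, REML) of `H`, coordinates, and productivity (mean NDVI, "NPP"),
compares the nested suite by AIC and deviance explained, ranks variables by
leave-one-out jackknife, and reports per-realm partial linear slopes of the
log response on `H` (±95% CI) after adjusting for coordinates and NPP.

A seeded synthetic-world generator (`world_config()`, `generate_world()`)
produces categorical land-cover rasters with a wide per-cell Shannon
gradient, an NPP surface with tunable correlation to `H`, a trait-complete
species pool, and habitat-gated occupancies whose expected richness is
log-linear in `H` with a known coefficient — so every estimator in the
package is tested against exact ground truth. See the methods vignette
(`vignettes/landuse-diversity-bird-richness.Rmd`) for the model, its
assumptions, and the design decisions.

## Worked example

A complete synthetic study — simulate a 20x20-cell world with 500 species,
build the functional space, compute per-cell metrics, and fit the model
suite — is one call:

```r
library(aviland)
cfg <- run_config(world = world_config(seed = 1))
run_dir <- run_pipeline(cfg, outdir = "aviland_run")
read.csv(file.path(run_dir, "model_comparison.csv"))
```

The comparison table for this seed (taxonomic suite shown):

```
 model_code                                       variables      aic delta_aic deviance_explained
     Mod_T1                            Latitude + Longitude   526.73    650.2             0.187
     Mod_T2                      Latitude + Longitude + NPP   341.56    465.0             0.512
     Mod_T3       Latitude + Longitude + Land-use diversity    41.92    165.4             0.783
     Mod_T4 Latitude + Longitude + NPP + Land-use diversity  -123.44      0.0             0.861
     Mod_T5                                      ... + ME    -123.44      0.0             0.861
```

The model containing both true drivers (NPP and land-use diversity) wins
decisively; adding median elevation — which has no effect in the generator —
changes nothing because the shrinkage penalty removes the term. The
jackknife tells the same story (importance = drop in deviance explained
when the variable is removed):

```
         variable importance delta_aic rank
  landuse_shannon   3.29e-01   4.5e+02    1
              npp   6.58e-02   1.5e+02    2
 median_elevation  -1.51e-10  -8.9e-05    3
```

Per-realm partial slopes of log taxonomic richness on the Shannon index
(adjusted for coordinates and NPP) are all positive and significant in this
world:

```
  realm    metric  beta ci_low ci_high significant  n
 realm1 taxonomic 0.962  0.552   1.373        TRUE 58
 realm2 taxonomic 0.864  0.593   1.135        TRUE 78
 ...
 realm6 taxonomic 1.039  0.812   1.266        TRUE 55
```

These sit above the configured log-linear coefficient (0.5) because, with
habitat-affinity gating active, cells with more land-cover classes also
admit more specialist subpools — the gating mechanism itself is part of the
land-use diversity effect. In generalist-only worlds the slopes recover the
configured coefficient exactly within their confidence intervals (that is
the packaged calibration check).

`make_report(run_dir)` renders the tables and per-realm partial-effect
curves into `report.md` and `report_figures.pdf`. A command-line wrapper
with the same options lives at `inst/cli/aviland.R`:

```sh
Rscript inst/cli/aviland.R run --mode synthetic --seed 1 --outdir aviland_run
```

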