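# betascape

Landscape-scale analysis of how **habitat amount**, **habitat
fragmentation**, **spatial distance** and **regional climate** shape the
beta diversity and endemism of tree communities.

`betascape` is aimed at landscape/community ecologists who work with
replicated landscape designs: forest inventories grouped into 100-km²
hexagonal landscape units, fragmentation metrics computed from binary
habitat rasters, and per-landscape biodiversity responses modelled against
standardized landscape predictors. Because the inventory databases and
land-cover products behind such studies are rarely redistributable, the
package includes a fully tested synthetic-study generator, so the entire
pipeline runs — and is validated — without any external data.

## What it computes

For every landscape (a 100-km² hexagon holding ≥ 2 inventories):

* **Predictors** — habitat cover (%), number of patches and mean patch size
  (queen-connectivity components of the binary habitat raster), mean
  Euclidean nearest-neighbour distance between patches (ENN_MN, m), mean
  pairwise geographic distance among inventories (km), and four zonal
  climate means.
* **Responses**
  * *Total beta diversity*: the abundance-based multiple-site Bray–Curtis
    partition
    \(\beta_{tot} = (\sum\min + \sum\max) / (2\sum A + \sum\min + \sum\max)\),
    decomposed into balanced-variation and abundance-gradient components
    (\(\beta_{tot} = \beta_{bal} + \beta_{grad}\) to machine precision).
  * *Raup–Crick beta diversity*: a null model preserving each inventory's
    richness and total abundance;
    \(rc = 2[(\#\{d^*<d\} + \tfrac12\#\{d^*=d\})/n_{reps}] - 1 \in [-1,1]\),
    rescaled to \([0,1]\).
  * *Endemism level*: community-weighted mean of integer endemism scores
    (exotic −1 … local endemic 3), averaged over the landscape's
    communities.
* **Inference** — Pearson screening (drop one of each pair with
  \(|r| > 0.70\)), PCA of the environmental space, beta regression (logit
  link, ML) for the two beta responses and Gaussian OLS for endemism,
  dredge-style all-subsets selection ranked by AIC with the ΔAIC ≤ 2 best
  set, a habitat-cover × patch-count interaction under marginality, and VIF
  / Moran's I diagnostics.

See `vignettes/betascape-methods.Rmd` for the model details, conventions and
the synthetic world's generating mechanisms.

## Worked example

```r
library(betascape)

cfg <- pipeline_config(
  sim       = simulation_config(n_landscapes = 12, seed = 7),
  n_reps    = 199,
  responses = c("beta_total", "endemism"),
  seed      = 7
)
run_pipeline(cfg, "run")
summarize_run("run")
```

prints (output of the code above, verbatim):

```
betascape run summary
=====================
landscapes: 12
inventories: 83 (per landscape mean 6.92, min 2, max 11)
habitat cover range: 2.0% - 98.0%
seed: 7 | null reps: 199 | thresholds: effort >= 0.1 ha, dbh >= 5 cm, r <= 0.7, dAIC <= 2, >= 2 inventories

best models for beta_total (dAIC <= 2): 1 of 5
  #1 AIC -45.92 dAIC 0.00 R2 0.86: habitat_cover + habitat_cover:n_patches + n_patches
  rank-1 effects: habitat_cover -0.20 (p=7.22e-07); n_patches +0.03 (p=0.444); habitat_cover:n_patches -0.18 (p=4.33e-07)

best models for endemism (dAIC <= 2): 4 of 5
  #1 AIC -15.60 dAIC 0.00 R2 0.11: habitat_cover
  #2 AIC -15.10 dAIC 0.49 R2 -0.00: (intercept)
  #3 AIC -14.14 dAIC 1.46 R2 -0.01: n_patches
  #4 AIC -13.60 dAIC 2.00 R2 0.01: habitat_cover + n_patches
  rank-1 effects: habitat_cover +0.05 (p=0.16)
```

Reading it: 12 synthetic landscapes span the full 2–98% habitat-cover
gradient. For total beta diversity the AIC-best model carries a negative
standardized habitat-cover effect (−0.20, i.e. biotic homogenization with
increasing habitat amount in this small world), and for endemism the best
model carries a positive cover effect. At this toy size (12 landscapes) most
climate terms are screened or never selected and p-values are weak; the
full-scale behaviour (95 landscapes, ≥ 90% sign recovery of the generating
+distance / −patches / −cover structure) is exercised in
`tests/testthat/test-acceptance.R`. Every run directory contains per-stage
CSV tables (`design/`, `metrics/`, `beta/`, `endemism/`, `model/`), a
`manifest.csv` of md5 checksums, and `run_info.csv` with the seed and
thresholds; reruns with the same config are byte-identical.

A command-line wrapper with the verbs `simulate`, `design`, `metrics`,
`beta`, `endemism`, `model`, `all` and `report` lives at
`inst/cli/betascape.R`:

```sh
Rscript inst/cli/betascape.R all --n-landscapes 20 --reps 199 --seed 7 --out run
Rscript inst/cli/betascape.R report --out run
```

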