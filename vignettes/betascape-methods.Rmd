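---
title: "Methods: landscape-scale drivers of tree beta diversity and endemism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape-scale drivers of tree beta diversity and endemism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In human-modified tropical forest regions, three distinct processes shape how
tree community composition varies among nearby forest inventories: loss of
habitat amount, fragmentation of the remaining habitat into more and smaller
patches, and plain geographic distance between the inventories. Disentangling
them requires replicated landscapes spanning a full habitat-cover gradient,
with fragmentation measured at fixed habitat amount. `betascape` implements
that design as a reusable pipeline: landscapes are 100-km² hexagons holding at
least two forest inventories; each landscape is scored for habitat amount,
fragmentation, within-landscape spatial distance and regional climate; the
responses are abundance-based beta diversity (total and null-model
standardized) and a community-weighted endemism level; and the drivers are
identified by all-subsets regression with AIC ranking.

Because the inventory databases and land-cover products such analyses rest on
are not redistributable, the package ships a synthetic-study generator whose
statistical structure matches the assumptions of the analysis. Every stage of
the pipeline is therefore testable end to end with no external data.

## Study design

Inventories pass three filters before analysis: sampling effort ≥ 0.10 ha, a
DBH inclusion cutoff ≥ 5 cm (a metadata test on the survey's stated
threshold, not per-stem truncation), and complete species/abundance data.
Dropped inventories carry one machine-readable reason code, assigned in the
fixed order effort → dbh → completeness.

Landscapes are pointy-top regular hexagons of area $A$ (default 100 km²,
edge $a = \sqrt{2A/3\sqrt{3}} = 6.2040$ km), laid out on the standard offset
lattice anchored at the extent's minimum corner. Orientation and origin are
conventions fixed for reproducibility; points are assigned to the hexagon
with the nearest centre, which for a hexagonal lattice is exact containment,
with ties broken deterministically (a half-open edge convention, so the
assignment is a partition). Hexagons with fewer than two member inventories
are discarded; a landscape's reference year is the *oldest* member inventory
year and selects the habitat raster of matching (or nearest earlier) year.

## Landscape variables

On a binary habitat raster (30-m cells by default; ESRI ASCII grid on disk,
since no GeoTIFF reader is guaranteed in the runtime environment):

* **Habitat cover** — percent of valid cells that are habitat, cell-centre
  clipped to the landscape polygon.
* **Number of patches / mean patch size** — connected components under queen
  (8-neighbour) connectivity by default (the FRAGSTATS/landscapemetrics
  convention; rook available via a flag). Mean patch size is habitat area
  divided by patch count, in hectares, so the product recovers habitat area
  exactly.
* **ENN_MN** — for each patch the minimum Euclidean distance between its
  border-cell centres and another patch's border-cell centres, averaged over
  patches. Undefined (missing, not an error) with fewer than two patches;
  model rows with missing values in any candidate predictor are dropped with
  a logged count.
* **Mean spatial distance** — mean over all unordered inventory pairs;
  planar Euclidean in km for the synthetic world, haversine on a sphere of
  radius 6371 km for lon/lat input.
* **Climate** — per-variable zonal means (annual mean temperature °C,
  temperature seasonality °C, annual precipitation mm, precipitation
  seasonality %), nodata excluded.

## Beta diversity

Total beta diversity is the abundance-based multiple-site Bray–Curtis
partition. For sites $j,k$ with $A_{jk} = \sum_i \min(x_{ij}, x_{ik})$ and
abundance surpluses $b_{jk}, b_{kj}$,

$$\beta_{\mathrm{BC}} =
  \frac{\sum_{j<k} \left[\min(b_{jk},b_{kj}) + \max(b_{jk},b_{kj})\right]}
       {2\sum_{j<k} A_{jk} + \sum_{j<k}\min + \sum_{j<k}\max},$$

with the balanced-variation component
$\sum \min / (\sum A + \sum \min)$ and the abundance-gradient component
their difference. For two sites this reduces exactly to pairwise
Bray–Curtis, and total = balanced + gradient holds to machine precision.

The Raup–Crick index compares the observed Bray–Curtis dissimilarity of a
pair to a null model that preserves each inventory's richness and total
abundance: each null community draws its observed richness of species
without replacement with probability proportional to occurrence frequency,
then distributes its observed total among them with probability proportional
to relative abundance. With $n_{\mathrm{reps}}$ replicates,

$$\mathrm{rc}_{\mathrm{raw}} = 2\,\frac{\#\{d^* < d\} + \tfrac12 \#\{d^* = d\}}
  {n_{\mathrm{reps}}} - 1 \in [-1, 1], \qquad
  \mathrm{rc}_{\mathrm{rescaled}} = (\mathrm{rc}_{\mathrm{raw}}+1)/2 .$$

Design choices, where the field's conventions leave room:

* The landscape-level value is the mean of the pairwise indices, with the
  null pool built from the landscape's own inventories (occurrence frequency
  = share of inventories holding the species; relative abundance = pooled
  counts). A study-wide pool can be supplied explicitly.
* The batched engine draws **one null community per inventory per replicate**
  and lets all pairwise null dissimilarities of that replicate share the
  draws — the matrix-per-permutation convention of null-model dissimilarity
  tools. Each pair's index is marginally identical to fully independent
  per-pair draws (the slower reference engine, kept as `raup_crick_pair()`
  and cross-checked in the tests); only the correlation among pairs differs,
  which leaves the landscape mean unbiased and makes the default
  999-replicate run tractable.
* Ties are weighted ½ (the formula above). A consequence worth knowing: for
  a pair of species-disjoint communities the index approaches +1 only when
  the null pool makes overlapping null draws likely — which the
  landscape-own pool does, since only observed species carry occurrence
  weight.
* The observed-vs-null comparison uses plain Bray–Curtis, not the partition
  components, and the null conditions on *realized* richness.

## Endemism

Each species carries an integer endemism score: exotic −1; not endemic with
pantropical/neotropical distribution 0; not endemic with South American
distribution 1; regional endemic 2; local endemic 3. A community's endemism
level is the abundance-weighted mean score (CWM), invariant to rescaling
abundances and bounded by the scores present; a landscape's level is the
unweighted mean over its communities. Unclassified species are an error in
strict mode; lenient mode excludes them from numerator and denominator and
reports the count.

## Inference

Candidate predictors are screened by Pearson correlation: while any pair has
$|r| > 0.70$, one member of the worst pair is dropped — the member named
earliest in a drop-priority list (default: `mean_patch_size`, the
conventional sacrifice in favour of habitat cover), otherwise the later
column. Retained predictors are standardized to zero mean and unit variance,
so all reported effects are standardized effect sizes; responses stay on
their natural scale. A PCA of the standardized predictor table summarizes
the environmental space (variance explained reported over all axes,
zero-variance axes as 0%).

Beta-diversity responses in $[0,1]$ are squeezed to the open interval with
the Smithson–Verkuilen transform $y' = (y(n-1)+0.5)/n$ and modelled by beta
regression: logit link, mean–precision parameterization, maximum likelihood
by BFGS on $(\beta, \log\phi)$ with analytic gradients, Wald-z p-values,
AIC counting $\phi$, and pseudo-R² defined as the squared Pearson
correlation between the linear predictor and $\mathrm{logit}(y)$ (this
convention can differ from other pseudo-R² definitions by a few hundredths).
The endemism response is Gaussian OLS with t-based p-values and adjusted R².

Model selection is dredge-style: every subset of the candidate predictors
(intercept always included), plus — under marginality — each subset holding
both members of the habitat-cover × patch-count interaction with the
interaction term. Models are ranked by AIC (ties broken by fewer parameters,
then lexicographic term order), and the best set is ΔAIC ≤ 2. Model rows are
complete cases over *all* candidate predictors so AIC values compare like
with like. Diagnostics per selected model: VIF ($1/(1-R^2_j)$, infinite
under perfect collinearity) and Moran's I on residuals with inverse-distance
weights ($w_{ij} = 1/d_{ij}$, row-unnormalized; expectation $-1/(n-1)$;
variance under the normality assumption; two-sided normal-approximation p;
coincident points perturbed by $10^{-6}\times$ the maximum pairwise
distance). No AICc, model averaging or spatial-error models.

## The synthetic world

`simulation_config()` states the world the tests run in; its defaults are
fixed once and not tuned per test:

* **Scale** — 95 landscapes of 100 km² at 30-m resolution; 2–12 inventories
  per landscape placed uniformly inside the hexagon (within-landscape
  placement is unspecified in the underlying design, so uniform placement is
  an explicit assumption); 300 individuals per inventory, a realistic stem
  count for 0.1–1-ha tropical plots at a 5-cm DBH cutoff.
* **Habitat rasters** — a seeded-growth cluster process: nuclei are placed
  and random habitat-adjacent cells converted until exactly
  $\lfloor \mathrm{cover} \times n_{\mathrm{cells}} \rfloor$ cells are
  habitat, so cover is controlled to one cell and expected patch count rises
  with the nuclei count. Target covers form an evenly spaced, randomly
  permuted gradient over the configured range (default 2–98%).
* **Fragmentation** — each landscape draws a fragmentation propensity
  $F \sim U(0,1)$; the realized nuclei count follows a percolation-like hump
  $n \propto F \cdot 4c(1-c)$ in cover $c$ (few distinct remnants near 0%
  and 100% cover). This keeps the cover–patch-count correlation at
  realistic, sub-screening levels; with nuclei drawn independently of cover
  the two collide near the $|r| = 0.7$ screen and patch count is
  intermittently screened out.
* **Species pool** — 400 species; geometric-series abundance profile whose
  ratio is solved so the expected inventory richness matches `alpha_mean`
  (default 60); endemism categories drawn from a five-way mix (3% exotic,
  37% pantropical/neotropical, 25% South American, 20% regional, 15% local).
* **Community assembly** — per-species log-weights combine: the geometric
  profile; a generalist-dominance tilt and a damping of site-level
  heterogeneity, both scaled by
  $h = \texttt{homogenization\_strength}\cdot F +
  \texttt{cover\_homogenization}\cdot c$ (field damped by $\sqrt{e^{-h}}$,
  noise by $e^{-h}$) — this is the generating mechanism for lower beta
  diversity in fragmented and high-cover landscapes; an endemic boost
  $1 + \texttt{endemism\_cover\_coupling}\cdot c$ on species scoring ≥ 2 —
  the generating mechanism for endemism rising with habitat amount; a
  spatially autocorrelated suitability field (one random-phase cosine
  process per species, frequency sd = `distance_decay_rate` per km,
  amplitude 0.8–1.2 internal constant 1.2) producing distance decay of
  similarity; and multiplicative log-normal site noise (sd 0.3). Counts are
  multinomial. The `cover_homogenization` field is an addition to the
  minimal field list: without a cover-linked homogenization term the world
  cannot generate the negative cover effect on beta diversity that the
  recovery tests require.
* **Climate** — realistic independent draws (temperature ≈ N(19, 2) °C,
  and so on) with *no* generating effect on the responses: climate acts as
  the control covariate set, and the recovery tests assert nothing about
  climate signs.
* **Reproducibility** — one master seed; per-landscape substreams derived by
  a stable string hash of the landscape id, so adding landscapes never
  perturbs existing ones. The Monte-Carlo null engine seeds a fast internal
  xoshiro256++ stream from R's RNG, so everything is reproducible under
  `set.seed()`.

What a green test does and does not establish: the generator reproduces the
*qualitative* structure the analysis assumes — distance decay, fragmentation-
and cover-driven homogenization, endemism–cover coupling, a full cover
gradient — with standardized effect sizes of roughly the magnitude real
studies report (|effects| ≈ 0.1–0.3). It does not mimic real floristic
composition, MapBiomas class taxonomy, observational error in coordinates or
effort, or temporal land-cover change (one raster per landscape, carrying a
year attribute).

## Numerical choices and degenerate inputs

* Cover 0 and 1 are exact (all/no habitat); zero-habitat landscapes have 0
  patches and undefined mean patch size; single-patch landscapes have
  undefined ENN_MN.
* Beta regression refuses responses on the boundary (squeeze first), flags
  non-convergence rather than failing silently, and excludes failed fits
  from rankings with a log.
* `raup_crick_pair()` errors when a community's richness exceeds the pool's
  species count rather than silently sampling with replacement.
* The Fenwick-tree sampler in the batched null engine restores removed
  weights after each draw; sampling probabilities were validated against
  R's `sample()` marginals and the slow reference engine.
* Pipeline outputs are plain CSV; coordinates are generated at fixed
  decimal precision so a written-and-reread study reproduces byte-identical
  downstream outputs (the stage-isolation contract).

## Known limitations

* The hexagon grid is planar; geographic (lon/lat) input must be projected
  to an equal-area plane before tessellation. The haversine path is used
  only for pairwise distances.
* The landscape Raup–Crick aggregation (mean of pairs, landscape-own pool)
  is one of several defensible conventions; the replicate count and pool
  choice are exposed.
* With many landscapes near full cover, ENN_MN is undefined and those rows
  leave the model table; a strong cover–ENN association can therefore be
  partly truncated.
* AIC selection with noise covariates admits spurious terms at the known
  $P(\chi^2_1 > 2) \approx 0.157$ rate per covariate; recovery tests
  therefore check that the true drivers are *contained* with correct signs,
  not that the rank-1 model equals the true set (which plain AIC cannot
  deliver).
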