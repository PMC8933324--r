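# beescape

Spatially explicit community simulation of solitary wild bees in
agricultural landscapes, built for scenario analysis of **agricultural
buffer zones (ABZs)** — strips of former arable land at the border to
grassland or forest that are left undisturbed and enriched in floral
resources. The package is aimed at landscape ecologists and conservation
modellers who want to ask: *what fraction of the eligible field borders
must be converted before a bee community measurably recovers?*

## The model in brief

Bee species are collapsed into **functional types** (FTs) defined by five
traits — foraging distance, diet breadth, flying period, nesting
preference, parasite-host status — and every demographic parameter derives
from the trait profile through a fixed lookup table: growth rate *R*
(2.5–5 yr⁻¹), competition factor *c* (0–5, lower = stronger), land-use
suitabilities for foraging and nesting, a dispersal kernel
(N(100–600 m, sd = mean/10), truncated at 0), and a disturbance
susceptibility (0.3 cavity nesters, 0.9 soil nesters).

Populations (one per type and cell) follow Maynard Smith–Slatkin growth
with interspecific competition for food and nesting sites:

    β_j   = Σ_i (1 + (c_j − c_i)/C_total) · N_i        (overlapping flying periods)
    N_t+1 = N_t · R · weather · mean(uptake) / (1 + (R−1) ((N_t + β_j^nest)/K)^b)

with resource uptake averaged over the type's foraging disk, a stochastic
yearly weather multiplier (N(1, 0.15), truncated at 0), density-dependent
emigration with semidirected settlement search, and land-use-specific
disturbance regimes (arable patches disturbed every year, grassland 80%,
forest 30%, bare/urban 70%). ABZ cells gain nesting capacity and resource
suitability and are never disturbed. Community outcomes are summarized as
functional richness, Shannon diversity, quasi-extinction risk (the
fraction of repetitions dipping below an area-scaled threshold of 10,000
individuals per 9 km² in the last 10 years), community-weighted trait
means and feeding-intensity maps.

Landscapes are ESRI ASCII rasters with a patch table; a seeded
region-growing generator ships three documented archetypes (study-region
composition, heterogeneous, arable-dominated) so everything runs without
proprietary data. A one-at-a-time sensitivity harness perturbs all 16
uncertain parameters (±10%, ±25%, ±50% type spreads, categorical
reversals).

## Worked example

```r
library(beescape)
ls  <- generate_synthetic_landscape(
  archetype_config("study_region", n_rows = 50, n_cols = 50, seed = 11))
com <- default_community(28)
cfg <- sim_config(years = 50, repetitions = 10, base_seed = 100)
scen <- run_scenarios(ls, com, cfg, fractions = c(0, 0.25, 1))
for (f in c("0", "0.25", "1")) {
  run <- scen$runs[[1]][[f]]
  fin <- run$totals[, 51, ]
  cat(sprintf("fraction %-4s richness %4.1f  shannon %5.3f  qe_risk %4.2f\n",
    f, mean(apply(fin, 1, ft_richness)),
    mean(apply(fin, 1, shannon)),
    mean(run_qe_risk(run))))
}
```

prints

```
fraction 0    richness  3.0  shannon 0.389  qe_risk 0.94
fraction 0.25 richness  7.8  shannon 0.715  qe_risk 0.93
fraction 1    richness 10.7  shannon 1.243  qe_risk 0.84
```

Reading: on a 1 km² study-region mosaic, only 3 of 28 functional types
survive 50 years without buffer zones — the annual arable disturbance and
the 80%-per-year grassland disturbance leave forest-nesting, bivoltine
types as the only refugees. Converting 25% of the eligible arable border
cells more than doubles persisting richness and raises Shannon diversity;
full conversion roughly triples richness and begins to pull the mean
quasi-extinction risk down. The direction of every effect — richness and
diversity up, extinction risk down with ABZ fraction — is what the
acceptance suite verifies; absolute levels depend on the capacity scale
and landscape geometry (see the methods vignette,
`vignettes/community-simulation.Rmd`).

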