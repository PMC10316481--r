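# nicheshift

Quantify how an introduced species' realized environmental niche differs
between its reference ("international") and introduced ranges, and map
where it could spread next.

Invasive species regularly come to occupy environmental conditions absent
from the ranges they were introduced from. Whether that has happened — and
how far it has gone — decides whether a habitat-suitability forecast can be
trusted. `nicheshift` implements the full analysis chain used in
contemporary invasion ecology for this question, motivated by the six deer
species (chital, fallow, hog, red, rusa, sambar) with established wild
populations in Australia. It is aimed at spatial ecologists and wildlife
managers who have occurrence tables and gridded environmental covariates
and want reproducible niche-shift and invasion-risk numbers.

## What it computes

**Niche overlap in environmental space.** A PCA calibrated on the pooled
backgrounds of both ranges defines a two-axis environmental space; each
range's occurrences become a kernel-smoothed density `z` on a 100×100 grid
(availability-corrected by default). The package reports

- Schoener's overlap `D = 1 − ½ Σ |z₁ − z₂|` ∈ [0, 1]
  (0 = completely disjoint niches, 1 = identical),
- niche **expansion** (introduced density mass outside the reference
  occupancy), **stability** (= 1 − expansion), and **unfilled** (reference
  mass not occupied in the introduced range),
- a randomization **similarity test** (default 1000 replicates), with both
  a range-shift null and an exchangeable point-resampling null.

**Habitat suitability.** A presence-background maximum-entropy (Gibbs)
model with linear/quadratic/product/hinge features, default per-class L1
regularization, target-group backgrounds, 10-fold cross-validated AUC, and
permutation-importance variable selection (> 1% retained). Output as raw,
cumulative, or a [0, 1] logistic-style index; suitable habitat via the
permissive "fixed cumulative value 10" threshold.

**Environmental novelty.** MESS surfaces against the reference-range
occurrence environments (negative = outside the reference envelope).

**Invasion risk.** Accumulated least-cost distance from occupied cells over
a suitability-derived conductance surface, down-weighting suitability into
a [0, 1] risk map; α-hull (α = 1.5) present-range polygons; occupied vs
uninvaded-suitable area accounting in km².

**Virtual species.** A simulator of autocorrelated landscapes and
Gaussian-niche species with *known* overlap/expansion truth (by numeric
integration), so the whole pipeline is testable without any downloads.

## A worked example

Simulate a species whose introduced niche centroid moved by 2 standardized
environmental units, then run the niche-overlap analysis:

```r
library(nicheshift)

scn <- make_shift_scenario(seed = 1, delta = 2, n_per_range = 300)
scn
#> <shift_scenario> delta = 2 (env shift 0), 300 presences/range; truth D = 0.480, expansion = 0.001

ov <- scenario_overlap(scn, n_rand = 199, seed = 1, correct = FALSE)
tidy(ov)
#> # A tibble: 1 × 5
#>       D similarity_p expansion stability unfilled
#>   <dbl>        <dbl>     <dbl>     <dbl>    <dbl>
#> 1 0.490        0.045    0.0475     0.952  0.00385
```

The estimated overlap (D = 0.490) recovers the integrated truth
(D = 0.480); the niches overlap only partially, but the introduced range
has barely expanded beyond the reference occupancy (expansion 0.048,
stability 0.952) — the species has moved *within* conditions its reference
range already occupied, and the similarity test (shift null, 199
randomizations) finds the two niches more similar than randomly placed
ones (p = 0.045). `correct = FALSE` compares plain occurrence densities,
the quantity the simulator's truth integrates; the default compares
availability-corrected occupancies.

The geographic half works the same way from tibbles and `env_stack`
rasters: `fit_maxent()` + `predict(..., type = "cumulative")` +
`threshold_cumulative()` for suitable habitat, `mess_map()` for novelty,
`accumulated_cost()` + `risk_map()` for risk, and
`alpha_hull_range(occ, alpha = 1.5)` for the present range, e.g.

```r
hull <- alpha_hull_range(scn$invaded$occ, alpha = 1.5)
hull
#> <range_polygon> alpha = 1.5 (mean_edge): 430 triangles over 300 points, 3745 km2
```

`run_pipeline()` chains every stage from a YAML config (see
`default_config()`; `write_demo_inputs()` writes a ready-to-run synthetic
bundle), producing per-species overlap, climate-profile, model-evaluation
and range-area tables plus raster/GeoJSON artefacts via `write_report()`.
Every result type has `tidy()`/`glance()` methods and `autoplot()`
ggplots. The bundled tibble `deer_range_areas` carries the published
present/uninvaded area accounting for the six Australian deer species.

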