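---
title: "Methods: gap analysis of site-network coverage of Area of Habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap analysis of site-network coverage of Area of Habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbagap)
```

## The analysis

`kbagap` measures how completely a network of conservation sites — in the
motivating application, Key Biodiversity Areas (KBAs) — represents species'
**Area of Habitat** (AOH): the binary raster of suitable habitat within a
species' range, one map per species-season. The analysis proceeds in five
stages, each a module of the package:

1. **Site preprocessing** (`repair_geometries()`, `dissolve_sites()`).
   Site polygons are validated against a simple-features-style predicate.
   A ring with exactly one proper self-crossing (the classic digitisation
   "bowtie") is deterministically split at the crossing into its two simple
   lobes; anything worse is dropped into an auditable ledger with a reason
   (`invalid-geometry`, `empty`, `no-boundary`). Retained sites are then
   *dissolved*: overlapping polygons are merged into one union so habitat
   under two overlapping sites is never counted twice. Overlap percentages
   against the dissolved union are therefore guaranteed to lie in [0, 100],
   whereas per-site percentages can sum past 100.
2. **Overlap engine** (`mask_area()`, `build_overlap_matrix()`,
   `summarize_maps()`). All layers share one planar equal-area frame (km
   units), so area = suitable-cell count x cell area. A suitable cell lies
   inside a polygon iff its *centre* does — the unbiased cell-centre zonal
   rule; there is no sub-cell apportionment. The species-map x site
   cross-product is accounted for in full (`count_combinations()`), but
   only pairs with positive overlap are materialised: the analyses consume
   nonzero overlaps plus per-map totals, and the full matrix at global
   scale (hundreds of millions of pairs) would be hostile to hold as rows.
3. **Representation classification** (`classify_overlap()`,
   `rollup_species()`). Thresholds are strict: a map is *under-represented*
   below 8% and *very under-represented* below 5%, with exact zero
   additionally classed `no_overlap`. The classes nest (every 0% map also
   counts below 5% and 8%; use `count_below()` for nested tallies). The 8
   default documents its provenance: the global KBA network covers 8.01% of
   Earth's land, so a species placed independently of sites would expect
   about 8% coverage. Species-level flags take the worst season ("under
   -represented in at least one seasonal range") and flagged species
   partition into four seasonal patterns. Because published counts mix map
   and species units, every rollup here is explicit about its unit.
4. **Bias null models** (`draw_null_counts()`, `null_model_bias()`). To ask
   whether under-represented maps are biased toward particular orders,
   families, habitats or Red List categories, the observed number of
   below-threshold maps per group is compared with S = 1000 random samples
   of the same number of maps drawn *without replacement* from the full map
   set. The effect size is the signed percent difference
   `D = 100 * (null mean - observed) / group size`: negative means the
   group holds more under-represented maps than chance (worse represented).
   A group is *significant* when the central 95% interval of per-sample
   differences excludes 0; an exact binomial tail probability with
   `p = m / N` is reported alongside (the hypergeometric tail — exact for
   sampling without replacement — is available via `method =
   "hypergeometric"`). No multiple-testing correction is applied, matching
   the original analysis.
5. **Gridding and reporting** (`stack_to_grid()`, `gap_grids()`,
   `centroid_points()`, `overlap_histogram()`). Species richness,
   under-represented counts and proportions, and trigger-species counts are
   aggregated on a coarse equal-area grid (default 100 km cells for 10 km
   rasters); the worst-covered maps are reduced to area-weighted centroids;
   the distribution of per-map percentages is binned left-closed with the
   final bin closed at 100.

## Design choices that were genuinely open

* **Cell-inclusion rule.** Cell-centre-in-polygon rather than
  "all-touched": the centre rule is the standard unbiased zonal estimator,
  and it makes split-invariance exact — cutting a site into two abutting
  halves cannot move a cell centre across the union boundary because the
  even-odd ray-cast assigns a boundary point to exactly one side.
* **Union vs summed overlaps.** Per-map headline percentages use the
  dissolved union, capped at 100, because the dissolve step exists
  precisely to remove double counting; the per-site matrix retains the raw
  per-site percentages.
* **Repair policy.** One deterministic node-and-split attempt, then drop
  and ledger. Unsolved geometries are excluded entirely (their attribute
  rows go to the ledger, not the records).
* **Significance reading.** "The interval does not cross 0" is read as the
  central 95% quantile interval of the per-sample differences, not the
  full range of samples: the min/max of 1000 draws is noise-dominated, and
  the accompanying binomial probabilities imply a conventional alpha of
  0.05. On coarse counts (groups of tens of maps) the discrete null makes
  this rule conservative — it fires below 5% under the null; at the scale
  the method is meant for (thousands of maps, groups of hundreds to
  thousands) it attains its nominal level. The package's calibration check
  therefore runs at that scale: 11,985 maps of which 2,190 flagged, twelve
  groups of roughly a thousand.
* **Two-sided tails.** The binomial probability is two-sided by default
  (`min(1, 2 * min(lower, upper))` from exact tail sums); one-sided tails
  are available via `alternative`.
* **Percent difference baseline.** `D` uses the null-distribution mean;
  averaging observed-vs-each-sample differences gives the same value, so
  the cheaper form is used.

## What the synthetic generator emulates

Real inputs (global AOH rasters, site shapefiles, attribute tables) are
proprietary, so the package ships a generator whose outputs have the
statistical structure the analysis assumes. Its defaults are the study
conditions used throughout the tests and the acceptance script; they were
chosen once to reproduce, qualitatively, the regime reported for the global
bird KBA analysis — most maps with modest but nonzero overlap (published
values: 18.3% of maps below 8%, 0.24% of species with no overlap, mean
overlap around 22–24%, sites about 1.3x as numerous as maps) — rather than
any particular output number.

* **Landscape** (`generate_landscape()`): a rows x cols equal-area grid
  (default 120 x 120 cells of 10 km). Land (55% of cells, hit exactly) is
  the top of a smoothed Gaussian field, giving blocky continents; a few
  small island components are reserved with a sea buffer for island
  endemics. The same smooth field, standardised, becomes a **core
  gradient**: richness in real data is strongly spatially clustered, and
  species start cells are drawn with weight `exp(clustering * core)`
  (default `clustering = 1`). Habitat classes tile the land as Voronoi
  patches of ~25 seeds labelled from a fixed two-level code table
  (forest/savanna/shrubland/grassland/wetland/desert level-1 classes). The
  **widespread habitat** (default code 1.1, the boreal-forest analogue) is
  assigned at least three patches and always the *lowest-core* (peripheral)
  ones — boreal forest is the largest biome and sits away from richness
  cores — and its species are wide-ranging (one log-unit larger ranges)
  and never threatened, mirroring the reported absence of threatened
  boreal-only specialists.
* **Species** (`generate_species_maps()`): ranges are compact patches grown
  by seeded random accretion (AOH maps are contiguous-ish); sizes are
  log-normal on the cell scale. The real global range-size distribution is
  not quantitatively described in the sources this package emulates, so
  `range_meanlog`/`range_sdlog` are placeholders — right-skewed with a
  long tail — and should be treated as such. Threatened species (VU/EN/CR,
  drawn from configurable Red List marginals) get ranges shifted smaller
  by 1.5 log units. Migratory species (15%) contribute separate breeding
  and nonbreeding maps. Each species' "major" habitat is the modal habitat
  of its patch; 80% have exactly one major habitat (the
  single-important-habitat construct used by the habitat bias tests).
  Trigger status (a site exists for the species) is more likely for
  threatened species (0.9 vs 0.35).
* **Sites** (`generate_sites()`): rectangles with log-normal sizes. In
  `targeted` mode each site is identified *for* a trigger species: a
  trigger species is drawn (threatened species weighted 5x) and the site
  centre lands uniformly inside that species' range. This is deliberately
  per-species rather than a richness-field rule: one site inside a vast
  range contributes a negligible share of it, so wide-ranging species gain
  little per site while small-range threatened species gain a lot — which
  is how real site networks produce both a modest overall trigger
  advantage and strong under-representation of widespread-habitat species.
  A single global size factor is then calibrated by bisection until the
  dissolved union covers the target fraction of land (default 8.01%,
  tolerance 0.5 percentage points) measured with the same cell-centre rule
  as the overlap engine. Exactly `n_invalid_sites` self-intersecting
  pentagram polygons are injected; having five crossings each, they resist
  the one-shot repair and exercise the dropped-geometry path end to end.

What passing tests on this world do *not* show: nothing here reproduces
real biogeography (no latitudinal gradients, no real taxonomy, no
habitat/elevation clipping), the published global numbers are not
recoverable at desk scale, and the directional bias patterns
(trigger > non-trigger, threatened better and widespread-habitat species
worse than chance) are emergent and stochastic — they held in 13 of 14
independently seeded worlds during design, not by construction in every
world. The fixed-seed scenarios in the test-suite are single draws from
that ensemble.

## Numerical choices and degenerate inputs

* Geometry is hand-rolled planar computation in km: shoelace areas,
  even-odd ray-cast containment (strict inequalities give half-open
  boundary behaviour, hence exact split invariance), orientation-test
  segment crossings, and an exact slab-sweep union area (x axis cut at
  every vertex and pairwise crossing; within a slab the union is a stack
  of trapezoids). Tolerances in the invariants are 1e-9 relative;
  rectangle fixtures are exact.
* Zero-area species maps are flagged `unusable`, excluded from
  percentages with a warning (the real analysis likewise set aside 158
  unusable maps).
* Empty site inputs yield an empty `site_set`, not an error; `NA` group
  labels stay in the null-model sampling frame but count toward no group;
  groups below 10 maps are reported but flagged `small_sample` (echoing
  groups of 3–6 maps being too thin for meaningful assessment).
* Problem sizes in tests and the acceptance script (worlds of 120 x 120
  cells, 400–520 species, 60–300 sites, S = 500–1000 null samples, and the
  calibration run at 11,985 maps) are the package's chosen study
  conditions: large enough for the statistical properties being checked,
  small enough to run comfortably on a laptop core.

## Known limitations

* Polygons are rings without holes; site boundaries in practice are
  dissolved before anything depends on topology, but a genuine multi-ring
  polygon with holes would need the geometry layer extended.
* The binomial probability treats draws as independent although sampling
  is without replacement; that is faithful to the stated method, and the
  exact hypergeometric alternative is one argument away.
* Coverage calibration matches the *dissolved union* to the target; with
  very few sites the discrete cell count can make the 0.5 pp tolerance
  unreachable, which raises an error rather than silently missing.
* Species counts deduplicate by species id within a threshold; the
  published map-vs-species count discrepancies cannot be resolved from the
  outside, so every output table carries an explicit unit.
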