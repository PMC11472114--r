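---
title: "Methods: hierarchical vulnerability indexing and climate-hazard risk matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical vulnerability indexing and climate-hazard risk matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnmap)
```

## The problem

Local public-health teams increasingly need small-area maps that answer a
joint question: *where are the people most susceptible to harm from a climate
hazard, and where is the hazard itself worst?* `vulnmap` implements that
pipeline for census-style statistical geographies (in England, Lower Layer
Super Output Areas of roughly 1,000-3,000 residents): a hierarchical
social-vulnerability index on one axis, per-area flood and heat exposure on
the other, and a 3x3 vulnerability-by-hazard risk matrix as the map product.

## The vulnerability index

The index follows the rank-transform-and-weight methodology familiar from
the English Indices of Multiple Deprivation and from the hierarchical
index-construction literature in hazards research. Three levels are
aggregated: 33 metrics into 9 sub-domains, the sub-domains into 4 domains
(sensitivity, adaptive capacity, health, living environment), the domains
into one 0-100 index.

For a metric $m$ with polarity $s_m \in \{+1, -1\}$ ($+1$: larger proportion
means more vulnerable), each area's proportion is converted to a normalised
mean rank $R \in (0, 1]$ ($R = \text{mean rank}/N$, ties sharing their mean
rank). Sub-domain aggregation is then

$$x_a = \sum_m w_m R_{am}, \qquad
  \text{score}_a = T\!\left(\mathrm{rank}(x_a)/N\right),$$

where the exponential transformation

$$T(R) = -s \,\log\!\left(1 - R\left(1 - e^{-100/s}\right)\right),
  \qquad s = 23$$

maps ranks onto $(0, 100]$ while spreading the vulnerable tail, exactly as in
the deprivation-index convention; $T(1) = 100$ identically. Domain scores
are weighted means of their sub-domain scores; the overall index
rank-normalises each domain, applies $T$ again, and combines with the domain
weights. The second transform mirrors deprivation-index practice of
transforming domain ranks before combination; it is switchable
(`second_transform = FALSE`) because reasonable implementations differ on
whether the outer level is transformed, and the choice changes the scale but
not which areas top the index.

Numerical details worth knowing:

* $T$ is computed as $-s\log((1-R) + R e^{-100/s})$; the regrouping keeps the
  logarithm's argument positive in floating point even for very small $s$.
* Decile and tercile classes use $\lceil k R \rceil$ on mean ranks. This is
  deterministic, independent of input order, and gives tied areas the same
  class; with all values tied the class is the middle one
  ($R \approx 0.5$).
* Missing metrics are dropped from a sub-domain with weights renormalised
  over what remains; an area missing an entire sub-domain (hence a domain)
  carries a missing index and no tercile, and is reported rather than
  silently dropped.

### The metric hierarchy

The shipped registry (`default_registry()`, also
`inst/extdata/default_registry.yaml`) groups census-2021-style counts and
2019-deprivation-style income components: age structure (under-5s; over-65s
and over-85s), English-language proficiency, education and the seven income
deprivation components, unpaid-care bands, general health and disability,
car access and one-person households (the census's two categories: aged 66+
and other), tenure, and modelled poor housing condition. Two further
metrics — % female and population density — are deliberately kept *outside*
the index ("separate metrics") and travel as standalone map layers, since no
defensible polarity or weight exists for them at index level.

Weights default to equal at every level and are renormalised to sum to one
within each sibling group; any other weighting can be supplied through the
YAML registry. Person-based metrics use the resident population as
denominator, household-based metrics the household count — recorded per
metric in the registry, since published tables rarely state the base
explicitly.

## Hazard exposure

**Flood.** Input is a depth grid (metres) per scenario — a "typical"
planning scenario (1-in-100-year, RCP 8.5, 2050) and a "disaster" scenario
(1-in-1000-year, same projection) — plus building point locations. A
building's depth is the value of the grid cell containing it (half-open cell
ownership $[x, x+c) \times [y, y+c)$, so every point has exactly one cell);
no-data cells count as dry, the usual convention for flood grids that omit
dry land. A building is flooded when its depth **strictly exceeds 0.10 m**;
the per-area exposure is the proportion of its buildings flooded, ranked
into deciles (10 = most exposed). Areas without buildings get a missing
proportion and are excluded from ranking but reported.

**Heat.** Inputs are daily maximum and daily mean temperature grids. Two
per-cell metrics are reduced over the June-August season of 2015-2019 by
default: the mean of daily maxima, and the fraction of days whose daily mean
**strictly exceeds 15 °C** — a regional mortality-risk threshold consumed
here as a plain parameter. Per-area values are building-weighted means
(cell weights = number of the area's buildings in the cell), which is
equivalent to building-*density* weighting on any equal-area grid; areas
with no buildings fall back to the unweighted mean over intersecting cells,
flagged in the output. Both metrics are decile-ranked; the mean summer
maximum feeds the risk matrix by default (`heat_metric = "exceedance"`
switches).

## The risk matrix

Vulnerability terciles (from the overall index) are crossed with hazard
terciles to give a cell code $(v-1) \cdot 3 + h$ and label `V{v}-H{h}`.
Hazard terciles are computed from the *continuous* exposure metric, not by
collapsing deciles — ten bins do not partition into three equal groups, and
re-ranking the underlying metric avoids an arbitrary 3/3/4 split; deciles
remain available as display layers. Terciles are area-count-based;
population-weighted terciles would be a reasonable extension but are not
implemented. Note that heavily tied hazard metrics (e.g. flooded proportion
exactly 0 in most areas) produce legitimately uneven tercile margins: tied
areas must share a class.

## The synthetic study region

`generate_region(n_side, seed)` builds an $n \times n$ lattice of 1 km
square areas on a planar metric coordinate system, with populations drawn
uniformly in 1,000-3,000 (the size band of the real statistical
geographies), households at the typical 2.4 persons per household, and one
building point per household placed uniformly within its area. A latent
vulnerability factor $L$ is an iid Gaussian field smoothed with a 3x3
binomial kernel and re-standardised, giving positive spatial
autocorrelation.

* **Census counts** are $\mathrm{Binomial}(n_a, p_{ma})$ with
  $\mathrm{logit}(p_{ma}) = \mathrm{logit}(p_{0m}) + \beta s_m L_a$,
  baseline prevalences $p_{0m} \sim U(0.02, 0.4)$, and effect size
  $\beta = 1$ as the default planted-signal condition ($\beta = 0$ is the
  null).
* **Flood depths** decay linearly from a straight mid-region channel:
  $\max(0, H_0 - \gamma d) $ plus zero-mean Gaussian noise applied only
  where the deterministic part is positive, floored at zero — so the reach
  $H_0/\gamma$ is exact. Defaults $H_0 = 1.2$ m (typical) and $2.0$ m
  (disaster) with $\gamma = 2 \times 10^{-4}$ per metre give a flood belt a
  few kilometres wide, and the noise field depends only on the seed and
  grid, so the disaster grid dominates the typical grid cell by cell at the
  same seed.
* **Temperatures** are a seasonal baseline (16 °C daily mean) plus an
  urban-heat-island term `uhi_strength` x normalised building density of
  the cell (default 3 °C, a realistic city-scale amplitude), a shared
  day-to-day offset (sd 2 °C), small per-cell noise, and a non-negative
  diurnal gap for the daily maximum — guaranteeing
  $T_{\max} \ge T_{\text{mean}}$ for every cell-day.

Every generator derives independent sub-seeds from the master seed, so runs
are exactly reproducible and components can be regenerated independently.
The `truth` records keep all parameters and planted values alongside the
outputs.

**What the generator does not emulate:** real boundary irregularity,
coastline and river-network geometry, spatially correlated census
non-response, building footprints (points stand in for them at grid
resolution), multi-source flooding components, or climate trends within the
temperature record. Passing recovery tests therefore demonstrates that the
pipeline's statistical machinery is sound — not that any particular real
region's map is right.

## Problem sizes and verification

The package's simulation experiments use a 20 x 20 region (400 areas, about
340,000 buildings, a 50 m flood grid and a 500 m daily temperature grid over
five summers): at these sizes the full planted-truth recovery — Spearman
correlation of index with $L$, of heat decile with building density, and of
flood decile with channel distance — runs in seconds and is highly stable
across seeds (correlations around 0.99, 0.99 and -0.95 respectively, with
null-case correlations near zero). The null-independence check of the risk
matrix uses 100 seeds at 10 x 10 with one summer of temperatures. The
brute-force oracle for decile/tercile binning recomputes classes by direct
counting and edge search for all inputs of size up to 30.

## Coordinate systems and file formats

All computation assumes a projected planar system in metres; the GeoJSON
reader refuses layers in geographic coordinates (plain GeoJSON without a
`crs` member is WGS84 by specification) with a reprojection hint. Polygons
and joined results are exchanged as GeoJSON, grids as ESRI ASCII rasters,
tables as CSV, configuration as YAML, and the run manifest (config hash,
seed, row counts, warning counts, output checksums) as JSON. These plain
formats keep runs diffable and byte-reproducible — the pipeline's
determinism contract is that two runs with the same seed and configuration
produce identical tables.

## Known limitations

* Weights, and the level at which the exponential transform applies, are
  conventions of the deprivation-index family rather than settled facts;
  both are configurable and the defaults (equal weights, transform at both
  levels) should be revisited when calibrating to a real region.
* Hazard scenarios are consumed, not modelled: no hydrodynamics, no
  defended/undefended distinction, no temperature downscaling.
* The tool ranks areas relative to the study region only; scores are not
  comparable across separately ranked regions.
* Uncertainty in the index (sampling noise in small-area counts) is not
  propagated; treat tercile boundaries as soft.
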