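---
title: "Validating modelled accessibility against perceived accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating modelled accessibility against perceived accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfaccess)
```

## The problem

Health planners routinely map *modelled accessibility* (MA) to health
facilities — a per-cell estimate of how hard it is to reach care — but these
maps are approximations, and it is rarely checked how well they track what
the population itself experiences. Household surveys such as the DHS offer a
complementary signal: the proportion of women in a sampling cluster who say
that distance to the health facility is an obstacle to obtaining medical
care. We call that cluster-level proportion *perceived accessibility* (PA).

`hfaccess` implements a complete validation study of four standard MA
models against PA, exercised end-to-end on synthetic data with known ground
truth. On real survey microdata the same functions apply unchanged; the
synthetic generator exists so that every stage of the pipeline is testable
without restricted data.

## The four accessibility models

All four operate on a georeferenced raster grid (`raster_grid`), with the
cell-center convention that cell $(r, c)$ is centred at
$(x_0 + (c - \tfrac12)s,\; y_0 - (r - \tfrac12)s)$ for origin $(x_0, y_0)$
(outer corner of the top-left cell) and cell size $s$. Cells own the
half-open intervals $[\text{left}, \text{right}) \times (\text{bottom},
\text{top}]$, so a point on an interior boundary belongs to the cell with
the larger index; the convention is arbitrary but must be fixed once for
point extraction to be reproducible.

1. **Euclidean distance (ED, meters).** Distance from each cell center to
   the closest facility point, at exact facility coordinates. On geographic
   grids the haversine great-circle distance is used (Earth radius
   6,371,009 m); planar and geodesic variants are both supported because
   ~1 km global friction and population grids are distributed in
   longitude/latitude.

2. **Cost-distance, motorized and walking (CD-M / CD-W, minutes).**
   Accumulated least travel time from the facility set over the raster
   graph of a *friction surface* — a grid whose cells hold traversal time
   per meter (0.012 min/m is walking at 5 km/h; 0.0012 min/m is 50 km/h on
   a road). Adjacent cells $a, b$ are connected with edge weight
   $d(a,b)\,\frac{f_a + f_b}{2}$: inter-center distance times the
   arithmetic mean of the two frictions. This discretization matches the
   behaviour documented for the standard GIS accumulated-cost tools.
   Facilities snap to their containing cell (they are graph sources);
   impassable cells (infinite friction) sever their edges, and cells cut
   off from every facility are reported as `Inf`. The default neighbourhood
   is 8-connected (queen moves); 16-connectivity (adding knight moves) is
   available and reduces the worst-case raster-metric elongation from
   ~8.2% to ~2.8%.

3. **Kernel density (KD, dimensionless).** The only model that rewards
   having *several* facilities nearby:
   $\mathrm{KD}(c) = \sum_i \exp(-d_i^2 / 2\sigma^2)\,[d_i \le \tau]$, with
   truncation $\tau$ = 15 km and the convention that values *increase* with
   accessibility, opposite in sign to ED/CD. The kernel is unnormalized
   ($k(0) = 1$), which keeps summed values in the low single digits for
   realistic facility densities. The bandwidth is not pinned down by the
   source methodology beyond the truncation radius; we default to
   $\sigma = \tau/3$ (5 km), under which a facility's influence has
   essentially vanished (.011) at the truncation edge, and expose it as a
   parameter.

Surfaces are resampled to the population grid by nearest-neighbour lookup
at template cell centers (`resample_to`). Nearest-neighbour is chosen over
bilinear deliberately: it never manufactures values between a reachable and
an unreachable cell, at the cost of blockiness when upsampling.

## The survey side

A cluster record carries respondent counts, yes-counts, and counts for the
motorized subgroup (households owning a car or motorcycle). `perceived_access`
is the yes-proportion, overall or within the motorized / non-motorized
subgroups. Because PA is a cluster-level proportion while motorization is a
respondent-level trait, stratifying "by motorization" is ambiguous; we
compute each subgroup's own PA from subgroup yes-counts and correlate it
with the cluster-level MA (the `subgroup_pa = FALSE` switch instead
classifies whole clusters by majority motorization).

Association is measured with Spearman's $r_s$ — the Pearson correlation of
mid-ranks — because the PA–MA relationship is monotone but decidedly
non-linear (a logistic shape in our generator and in exploratory survey
work), and because KD is anti-correlated with the other three by sign
convention. Coefficients are reported in absolute value with the sign kept
as metadata. P-values use the large-sample $t$ approximation on $n - 2$
degrees of freedom, with no multiple-testing correction. Tied ranks get
average ranks; a constant vector yields an explicitly *undefined*
correlation rather than a number.

Smoothing curves for visualisation use local linear regression with tricube
weights (`loess_curve`, span 0.75 by default); they are cosmetic and feed
no statistic.

Population-by-class tables split total population into accessibility bands
with right-closed intervals $(b_{k-1}, b_k]$, defaulting to 1/5/10/15 km
for ED and 10/30/60/120 min for CD. Cells with missing accessibility are
reported as a separate *unclassified* share so the shares always sum to 1;
unreachable (`Inf`) cells fall in the open top class, which is where a
planner would want them counted. The KD surface is excluded — its
dimensionless score has no distance meaning.

## Geomasking displacement

DHS cluster coordinates are deliberately perturbed before release: urban
clusters by up to 2 km, rural by up to 5 km, and 1% of rural clusters by up
to 10 km, uniformly in direction and distance, constrained to the level-2
administrative unit. `displace_points` reproduces this scheme: distance is
drawn $U[0, D]$ with $D$ the class maximum, the 1% extension *replaces* the
rural maximum for Bernoulli-selected clusters (the published geomasking
procedure replaces the radius rather than adding a second jump), and the
admin constraint is enforced by rejection sampling against the polygon
containing the *source* point, keeping the original location after a
bounded number of failures. Note that drawing the distance uniformly (not
uniformly in area) concentrates displaced points near the source; the
choice follows the documented DHS procedure and affects how much
displacement attenuates correlations.

`replicate_displacement_study` repeats the displacement $R = 30$ times,
re-extracts all surfaces, recomputes every correlation, and summarises the
spread and the share of replicates in which $|r_s|$ fell below the
undisplaced baseline. Replicate $r$ derives its seed as
$(\text{seed} + 9973\,r) \bmod (2^{31}-1)$ with clusters drawn in table
order, making reruns bit-identical while keeping replicates independent.
Displacement adds noise to the MA covariate of a monotone relationship, so
it can only degrade rank agreement in expectation — the replication's
`share_attenuated` makes that visible (97.5% of replicates in the default
study, pooled over methods).

## The synthetic generator

`make_landscape`, `make_facilities` and `make_clusters` produce the study
conditions; their defaults are fixed once and are the conditions every test
runs under:

* **Landscape**: 200 × 200 cells of 1 km, walking friction uniform at
  0.012 min/m, motorized friction 0.0012 min/m on 6 random edge-to-edge
  road polylines (off-road = walking), 3 impassable partial strips,
  population = 8 Gaussian towns (peak 5,000, sd 6 km) over a floor of 5
  per cell.
* **Facilities**: 80, sampled without replacement proportional to
  population, jittered within their cell — mirroring the empirical pattern
  that facilities concentrate where people are.
* **Clusters**: 600 clusters of 15–35 respondents placed
  population-weighted; the densest 35% are flagged urban. Respondents are
  motorized with probability 0.45 (urban) / 0.15 (rural), matching the
  aggregate survey shares (~65% rural, ~25% motorized) in the data the
  study design targets. Each respondent answers Yes with probability
  $\mathrm{logit}^{-1}(a + b\,\mathrm{ED}_i/1000 + 0.7\,[\text{rural}] +
  0.5\,[\text{non-motorized}] + u_i)$, $a = -2$, $b = 0.18$ per km,
  $u_i \sim N(0, 0.5)$. The random effect reproduces the large
  between-cluster variability in PA at fixed accessibility seen in survey
  data; the intercept and slope put mean PA near 37%, the aggregate
  yes-rate in the target surveys.

What the generator does *not* emulate: real road-network topology (roads
are straight lines), terrain- or season-dependent friction, facility
bypassing (respondents choosing a non-nearest facility), survey sampling
weights, and reporting biases in the survey question. Passing tests
therefore demonstrate the pipeline's internal correctness and the
qualitative behaviour of the methods under known ground truth — not that
any particular real-world correlation value will be reproduced.

The driving accessibility in `make_clusters` is configurable (any surface
can be passed), so tests can build scenarios where a chosen method is the
true data-generating one.

## Numerical and design choices

* Unreachable cells are `Inf` internally and nodata on disk; the ESRI
  ASCII writer makes that conversion, and the reader restores `NA` (file
  nodata) which extraction reports as missing.
* Dijkstra on the lattice graph is delegated to `igraph::distances` from
  all facility source cells, taking the per-cell minimum — numerically
  identical to one multi-source run. The test suite checks it cell-by-cell
  against an independently coded brute-force Dijkstra on 20 random
  landscapes with barriers.
* Grids must have square cells; the ASCII format guarantees this. GeoTIFF
  I/O is not provided in this build — all artifacts are plain text.
* Point-in-polygon uses the even-odd rule (`mgcv::in.out`), with holes as
  additional rings, and overlapping admin polygons resolve to the first
  match in file order.
* Sub-seeds are derived from the master seed by fixed offsets (+1
  landscape, +2 facilities, +3 clusters, +4 displacement), so each stage
  can be regenerated in isolation from the manifest.
* Problem sizes in the test suite are chosen so the whole suite runs in
  well under a minute on a laptop core (oracle comparisons at 20–30 cell
  grids, distributional checks at 10^4–10^5 draws, full default study for
  the end-to-end check); the default study itself completes in seconds.

## A worked run

```{r study, eval = FALSE}
res <- run_study(study_config(seed = 1), out_dir = "study_out")
round(res$method_matrix, 3)
subset(res$pa_ma, stratum %in% c("all", "urban", "rural"))
res$replication$summary
```

With the default seed the between-method matrix shows ED and CD-W nearly
rank-identical (|r_s| = 0.989) — on a landscape whose walking friction is
spatially uniform, walking time is almost a monotone function of distance,
so the two methods cannot rank clusters very differently; CD-M departs
further (0.921) because roads distort travel time away from distance, and
KD further still (0.665). PA correlates positively with ED/CD and
negatively with KD, more strongly in rural clusters than urban ones and
for non-motorized respondents than motorized ones — the stratification
pattern expected when the generating link is steeper (rural shift) and less
confounded (no motorized mobility) in those groups.

## Limitations

The pipeline compares methods under a *known* monotone link on synthetic
data; it cannot adjudicate which method best matches real perceived
accessibility, only verify that each is computed correctly and behaves as
theory predicts (attenuation under displacement, concordance under uniform
friction, sign conventions). Cost-distance inherits raster-graph metric
elongation (bounded, and reducible with 16-connectivity, but present), and
the KD bandwidth default is a documented convention, not an estimate.
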