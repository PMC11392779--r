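---
title: "Methods: diversity surfaces, endemism and spatial congruence in divscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity surfaces, endemism and spatial congruence in divscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscape)
```

`divscape` computes gridded surfaces of taxonomic (TD), functional (FD)
and phylogenetic (PD) diversity and of weighted (WE), functional (FE)
and phylogenetic (PE) endemism from occurrence points, traits and a
dated phylogeny, then maps spatial congruence and mismatch between those
dimensions with geographically weighted regression. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Gridding and sampling redundancy

Occurrence coordinates are assumed planar (projected, conventionally
km); `project_equirectangular()` exists for quick lon/lat fixtures but
real analyses should project properly. Cells are square, indexed
row-major from the grid origin with zero-based indices, and half-open
(`[lo, hi)` on both axes), so boundary points belong deterministically
to the higher-index cell — the standard raster convention.

Per-cell sampling redundancy is `1 − richness / samples`: 0 means one
record per species, values near 1 mean heavy resampling. The working
resolution is chosen among candidate cell sizes (default 25, 50, 75,
100) as the *finest* grid whose average redundancy (ARd) reaches 0.6;
if none qualifies, the best candidate is returned with a
`below_threshold` flag. Two conventions had to be fixed because they are
frequently left unstated in practice: ARd averages over *occupied* cells
only (empty cells carry no sampling information), and the grid is
anchored at the occurrence-cloud minimum.

Cells that pass into the surfaces with redundancy below the threshold
can be interpolated (`interpolate_low_redundancy()`): their six metric
values are replaced by inverse-distance-squared weighted means of
well-sampled cells within a Chebyshev radius of 2 cells. A deterministic
interpolator was chosen deliberately — kriging-style alternatives need a
variogram model that gridded richness surfaces rarely justify, and a
closed-form interpolator keeps the contract testable (values are convex
combinations of neighbours; well-sampled cells are never touched; cells
with no qualifying neighbour stay flagged-missing rather than being
zero-filled). The original values are retained in an attached log, and
the function is a natural hook for plugging in another interpolator.

## The branch-length engine

PD, PE, FD and FE all reduce to one engine over a rooted tree with
branch lengths. For a cell's species set, `branch_sum_diversity()` sums
the branches of the spanning subtree. Two conventions are exposed
because the literature genuinely splits: `mode = "root"` (default)
includes the path from the set's MRCA to the root — the classical Faith
convention, under which a singleton cell scores the species' full root
path — while `mode = "mrca"` stops at the MRCA and scores singletons 0.
All package invariants hold under either mode.

`range_weighted_endemism()` divides each branch length by the branch's
range — the number of cells containing at least one descendant — and
sums over the cell's spanning branches. Summed over all cells (root
mode) this *exactly* equals the spanning length of the occurring
species, a conservation law the tests exploit heavily. Branch ranges are
cell counts by default; a `normalize_by_area` flag rescales them to
fractions of the occupied-cell total for users who prefer
area-normalised magnitudes, since published absolute PE/FE scales vary
with unstated normalisations.

Species absent from the phylogeny are grafted at genus level
(`graft_missing_species()`): a species whose genus has two or more
leaves becomes a new child of the genus MRCA (polytomy) with pendant
length equal to the mean depth of the MRCA's leaves below it; a species
whose genus has one leaf attaches at the midpoint of that leaf's pendant
branch; species with no congeneric leaf are dropped and logged. This
rule is deliberately simple: it is deterministic, needs no external
database, and provably preserves ultrametricity, which the tests check
to a relative depth spread below 1e-9.

## Functional dendrogram

Mixed-type traits are compared with the weighted Gower coefficient:
`S_ij = Σ_k w_k δ_ijk s_ijk / Σ_k w_k δ_ijk`, with `δ_ijk = 1` only when
trait *k* is observed for both species; per-trait similarity is an exact
match for binary/categorical traits and a range-normalised distance for
continuous traits. Ordinal traits use Gower's rank treatment:
tie-averaged ranks rescaled to the observed rank range, then treated as
continuous — ordinal handling differs across implementations and this is
the one documented here. Trait ranges are computed over the full species
pool so that the dendrogram is a single global object, independent of
any cell. A species pair sharing no positively weighted observed trait
is a hard error; silent imputation would contaminate the dendrogram
invisibly. Weights live in `[0, 1]` (in the motivating application,
importance for drought resistance) and traits with weight 0 provably do
not affect the result.

`D = 1 − S` is clustered by UPGMA with merge height equal to half the
average dissimilarity, so the dendrogram is exactly ultrametric. Exact
ties are broken by the lexicographically smallest pair of cluster
representatives, making topologies platform-reproducible. The
implementation is validated against `stats::hclust(method = "average")`
merge heights on random matrices and reproduces ultrametric inputs
exactly. FD and FE are then the branch engine applied to this
dendrogram, which yields engine-sharing guarantees for free: with the
dendrogram set equal to the phylogeny, FD = PD and FE = PE cell by cell,
and on a unit-branch star tree all branch metrics collapse onto TD and
WE.

## Geographically weighted regression

The six congruence models — FD ~ TD, PD ~ TD, FD ~ PD, WE ~ FE,
WE ~ PE, FE ~ PE, in exactly these response/predictor directions — are
fitted at cell centroids. At each location the response is regressed on
the predictor with Gaussian kernel weights
`w_ij = exp(−0.5 (d_ij/b)²)`; a fixed distance bandwidth is used (the
kernel choice follows the Gaussian convention; an adaptive-neighbour
scheme is a possible extension but is not what the default implements).
Local R² uses geographically weighted RSS/TSS, which is guaranteed to
lie in [0, 1] for the joint local fit because the intercept-only model
is nested. Locations where the weighted predictor carries no variance
are flagged degenerate and fall back to the weighted mean rather than
crashing.

The bandwidth minimises the corrected AIC,
`AICc = 2n ln σ̂ + n ln 2π + n (n + tr(S)) / (n − 2 − tr(S))` with
`σ̂² = RSS/n` and `tr(S)` the hat-matrix trace, by golden-section search
over `[min inter-point distance, extent diagonal]` to a relative bracket
tolerance of 1e-3. Bandwidths at which `tr(S) ≥ n − 2` (AICc undefined)
are treated as inadmissible; a search in which every probe is
inadmissible errors out.

`mgwr_fit()` gives the intercept and slope terms their own bandwidths.
Two design decisions deserve note. First, when the term bandwidths
coincide the additive model is mathematically ordinary GWR, so the tied
case is computed as the joint local fit — this makes the
tied-bandwidth/GWR equivalence exact rather than approximate. Second,
with free bandwidths the fit is obtained by backfitting: each term is
re-smoothed against its partial residual at its own golden-section AICc
bandwidth, iterating until the root-mean-square change in fitted values
relative to their norm (SOC-RSS) drops below 1e-5, capped at 200
sweeps; the effective parameter count is approximated as the sum of the
per-term hat traces, the standard treatment. The model suite defaults to
single-bandwidth GWR, which is considerably cheaper and is what all
residual-sign analyses in the package use; `method = "mgwr"` switches
the suite over.

Residuals (`observed − fitted`, exactly) are classified positive /
negative / neutral with a configurable neutral band defaulting to 0.
One behaviour worth understanding when reading residual maps: because
the AICc-optimal bandwidth is often close to the inter-cell distance,
the local fit partially absorbs regional mismatch — residuals are
recentred within any broad region, so arid-zone deficits show up most
reliably as the arid-cell median lying *below* the mesic-cell median,
and less reliably as strict negativity of the arid median itself. The
package's scenario-recovery checks are phrased accordingly.

## Synthetic worlds

`simulate_world()` builds a complete test world from a
`scenario_config()`. The aridity field is a monotone gradient along one
axis plus a smooth bilinear random field (amplitude 0.15 by default),
clamped to [0, 1]; it abstracts a precipitation/altitude gradient into
the single arid-vs-mesic contrast the hypotheses are phrased in. The
phylogeny is a hand-rolled Yule process conditioned on the species
count, giving exact determinism under a seed and a closed-form depth
expectation (`Σ_{k=2..n} 1/k` at unit birth rate) that the tests verify
by Monte Carlo. Traits (11 by default: 6 continuous, 3 ordinal, 2
binary, with an evenly spaced weight ramp from 1 to 0.5 standing in for
application-supplied importance weights) evolve as latent Brownian
motion on the tree; ordinal and binary traits are quartile/median
thresholdings of the latents, which yields mixed-type matrices with
controllable phylogenetic signal.

Ranges are a niche band plus dispersal penalty, not a mechanistic
dispersal model: each species draws a niche optimum on the aridity axis
and a target range size (Poisson around `range_width_mean`, default 25
cells on the default 20 × 20 grid of 25-unit cells — chosen to give
mean cell richness around a dozen species, a realistic regional-flora
occupancy); occupied cells are those minimising environmental distance
plus a distance penalty from a seed cell at the most suitable location.
Sampling effort per occupied cell is uniform on 2–8 records, which
keeps average redundancy near 0.8 — comfortably above the 0.6
acceptability threshold, as a well-sampled compilation would be.
Scenario hooks: `environmental_filter` shrinks continuous traits of
species with optima above 0.7 toward the pool mean by a factor of 0.85;
`in_situ_radiation` compresses the crown of a clade holding roughly a
third of the species to 0.3 of its depth (stem extended to preserve
ultrametricity) and confines that clade to the arid zone;
`isolation_endemism` forces a configurable fraction of species to
single-cell ranges; `biotic_exchange` scatters the arid-adapted set
evenly across the tree.

What the generator does *not* emulate matters for interpreting green
tests: there is no spatial error in coordinates, no taxonomic noise, no
detection bias correlated with accessibility, and the environment is a
single scalar field. Passing scenario-recovery tests therefore shows
the *pipeline* recovers planted signatures under clean sampling — it
does not certify robustness to the messiness of real herbarium
compilations, which is why the redundancy filter and range-based
outlier cleaning exist as explicit, separately tested stages.

## Problem sizes and determinism

The test suite and the acceptance script run the recovery analyses at a
20 × 20 grid with 200 species and 20 seeds per scenario — large enough
for the planted signatures to dominate sampling noise, small enough
that the complete suite runs in about a minute. Every stochastic stage
derives its seed from a single configuration seed, so identical
configurations reproduce identical worlds and identical output files;
the pipeline writes a manifest recording seed, record counts and stage
reconciliation (records in = kept + dropped; surface rows = occupied
cells).

## Known limitations

- Coordinates must be pre-projected; the package does no geodesy.
- The grafting rule is genus-level and topology-agnostic; it is a
  documented simplification, not a substitute for proper placement when
  a curated backbone is available.
- MGWR backfitting recovers term surfaces, but its effective-parameter
  count (and hence AICc) is the standard per-term approximation; model
  comparison across methods should rely on the plain GWR fits.
- The interpolation step smooths *metric surfaces*, not occurrence
  data; strongly under-sampled regions are flagged, and no amount of
  interpolation creates information there.
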