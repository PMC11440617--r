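---
title: "Methods: mosaic spatial statistics and the dendrite-soma exclusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic spatial statistics and the dendrite-soma exclusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmosaic)
```

## The problem

Starburst amacrine cells — like most retinal cell types — are arranged in
mosaics: within one population (OFF cells in the inner nuclear layer, ON
cells in the ganglion cell layer), two somata are rarely found close
together. The package quantifies this organization and tests a developmental
model for it: that each differentiating cell's dendritic territory excludes
the somata of its homotypic neighbors, so that territories, not somata,
define the exclusion zones. Everything operates on 2D point sets of soma
centers (µm coordinates in an axis-aligned rectangular window, 353.55 µm
square by default, matching a 40× confocal field; 636.5 µm for 20× fields)
plus polygonal arbor territories.

## Mosaic statistics

**Density recovery profile.** For every cell as reference, ordered pairs are
binned by center distance into half-open annuli $[r_{k-1}, r_k)$ of width
$\Delta r$ (5 µm default; 3 µm for the larger 20× fields). A pair exactly at
a bin edge belongs to the upper bin — half-open binning prevents double
counting. The per-bin density is

$$\lambda_k = \frac{c_k}{\sum_i A_{ik}}, \qquad
A_{ik} = \text{area}\big(\{p: r_{k-1} \le |p - x_i| < r_k\} \cap W\big),$$

where the edge-correction areas $A_{ik}$ are computed analytically as
differences of circle–rectangle intersection areas (exact and fast inside
the $O(nK)$ loop; a Monte-Carlo estimator serves only as a test oracle).
The global density is $D = n/\text{area}(W)$ — not $n-1$; the difference is
negligible at $n > 100$ and the convention is pinned for reproducibility.
Densities are reported in cells/mm² ($10^6$ µm² per mm²).

**Effective radius.** The exclusion zone is summarized by the radius of the
equivalent step profile (zero density inside $r_e$, $D$ outside) carrying
the same density deficit as the measured profile:

$$r_e = \sqrt{\sum_{k \le k^*} \max\!\big(0,\, 1 - \lambda_k/D\big)
  \left(r_k^2 - r_{k-1}^2\right)},$$

with $k^*$ the last bin before the profile first reaches $D$. Stopping at
the first crossing restricts the sum to the rising part of the curve and
keeps noise beyond the rise out of the deficit; summing all bins instead
would let super-density fluctuations beyond the rise cancel genuine dead
space. Negative contributions are floored at zero. Two consequences worth
knowing: for a random hard-core array the construction returns the hard-core
distance (the soma diameter, 10.0 µm) up to one bin width, and for any array
whose first empty bins span the hard core, $r_e$ is floored at that
distance — an aggregated array with an intact hard core therefore reports
$r_e$ equal to the soma diameter, and aggregation is read instead from the
short-range density exceeding $D$.

**Voronoi domain regularity index.** The window-clipped Voronoi tessellation
is computed by successive bisector half-plane clipping (neighbors visited in
distance order with a pruning bound). VDRI = mean/SD of interior domain
areas. Domains touching the window boundary are flagged and excluded from
the index: clipped domains have artificially truncated areas that inflate
the SD. Published descriptions of Fiji-based VDRI do not state their border
handling, so this choice is pinned here as the package's convention. A
perfect lattice has SD 0 at rounding level and is reported as `Inf` with a
degeneracy flag; at least 10 interior domains are required for a reportable
value. A homogeneous Poisson array yields VDRI ≈ 1.9 (the reciprocal of the
Poisson-Voronoi area coefficient of variation), which the tests verify by
simulation.

**Random-reference battery.** Observed VDRI and $r_e$ are compared with
$n_\text{sims} = 5$ hard-core simulations matched in window, density, and
soma diameter; z-scores are reported against the simulation mean ± SD. When
all simulations coincide (a degenerate envelope, common for $r_e$ exactly at
the hard core) the z-score is 0 on the envelope and ±Inf off it.

## The enclosure analysis

`count_enclosed` counts somata whose whole disk lies inside an arbor
polygon (center inside and boundary distance ≥ radius) — a straddling soma
is not counted. The containment disk defaults to the soma diameter; the
counted nuclear marker may be smaller than the soma, so a
`nucleus_diameter_um` override is exposed. When the arbor is scored on its
own source field, the reference cell's soma is part of the count, so real
counts are always ≥ 1.

`build_unmatched` forms the resampling null: each polygon is transposed at
*identical coordinates* onto every other same-sized field of the dataset —
no re-centering and no reflection, the plainest reading of overlaying an ROI
onto another field. The per-arbor unmatched mean excludes zero-enclosure
images: real images always contain at least the reference soma, so retaining
zeros would skew the null low and make the frequency histograms' zero bin
incomparable. The full (zeros-retained) count set is kept alongside for
box-plot-style summaries; zero exclusion never decreases the unmatched mean.

The **enclosed cell index** is
$\text{ECI} = \overline{u}_{>0} - c_\text{real}$ per arbor; its median is
tested against 0 with a two-sided one-sample Wilcoxon signed-rank test
(zeros dropped, midranks for ties; exact sign-flip enumeration via dynamic
programming for $n \le 25$, tie-corrected normal approximation with
continuity correction beyond — the enumeration handles ties exactly, which
off-the-shelf exact implementations refuse).

**A calibration caveat discovered while validating the null.** The
zero-exclusion rule compensates the guaranteed reference soma only
approximately. For territories much smaller than the mosaic spacing, an
arbor can essentially never enclose a non-reference soma in its real image
(the hard core keeps neighbors out of the eroded polygon), while its
unmatched nonzero counts are at least 1 — biasing ECI positive. For large
territories the inequality reverses. The bias crosses zero when the
territory radius is comparable to the nearest-neighbor spacing (≈16 µm at
1,400 cells/mm²), which is where the package's null-calibration tests
operate; at that design point the median ECI is 0 and the Wilcoxon holds
close to its nominal level at small unmatched-family sizes. The index is
therefore best read as a paired contrast at matched arbor sizes — which is
exactly how the size filter (below) is meant to be used — rather than as a
bias-free absolute.

**Frequency curves and chi-squared.** The real curve is the fraction of
arbors enclosing exactly $n$ somata; the unmatched curve is the across-arbor
mean (± SEM) of per-arbor frequencies over zero-excluded images. The
chi-squared statistic compares observed real counts per bin with expected
counts from the unmatched proportions, pooling upper-tail bins until the
tail expectation reaches 5 (the pooling rule is pinned; source descriptions
do not state their binning).

**Size filter.** Comparisons between genotypes are confounded by arbor
size, so both datasets are filtered to arbors within one SD of the
*reference* (wild-type) mean area, boundary-inclusive — "within one SD" is
read inclusively and pinned. **Levene's test** (group means as centers, via
`car::leveneTest`) compares arbor-area variability between groups.

## Contacts and dispersion

A dendritic tip contacts a soma iff its distance to the nearest soma center
is at most the soma radius plus a tolerance (0.5 µm default, approximating
resolution-limited apposition). Contact is scored in 2D; the source data
were 3D z-stacks, so the synthetic analysis collapses the axial dimension —
the flipped control inherits whatever bias this introduces equally. The
chance rate is estimated by flipping the tip channel about both window axes
(a 180° rotation about the window center — an isometry, so all
tip-geometry statistics are preserved while tip-soma coordination is
severed). Binomial fractions carry Wilson score 95% intervals.

Tangential dispersion: a cell is outside the clone columns iff its center
lies in no column polygon (center membership, no margin), and its dispersion
distance is measured to the nearest point on the nearest column boundary.
The reference point for "distance migrated" is not settled usage — column
centroid and birth position are alternatives — so boundary distance is the
package's stated convention, chosen because it is identifiable from a single
static image.

## Synthetic generators

The generators replace unreleased microscopy annotations and define the
package's study conditions:

- `simulate_hardcore` — somata placed one by one uniformly at random,
  rejecting candidates whose center lies within one soma diameter of an
  existing cell, until exactly `round(density × area)` cells are placed
  (uniform candidates to a fixed count is the sequential-placement reading
  of a density-matched Poisson process). Saturation (per-point attempt
  budget, default $10^4$, exhausted) is an error, never silent
  under-filling. With diameter → 0 this is complete spatial randomness.
- `simulate_exclusion_mosaic` — the generative form of the exclusion model:
  candidates are additionally rejected inside any existing cell's arbor
  polygon; each accepted cell receives a jittered 12-gon territory with
  radius ~ N(14, 2) µm truncated positive at placement. In `coordinated`
  mode final radii are rescaled to α × nearest-neighbor distance (α = 0.9:
  dendrites reach just short of the first homotypic neighbor), which also
  guarantees post hoc that no soma center lies inside another cell's
  territory.
- `simulate_clustered` — a Thomas process (Poisson parents at 150/mm²,
  Poisson(10) offspring per parent, isotropic Gaussian σ = 8 µm) with the
  hard core retained: clumped somata touch, they do not merge. Out-of-window
  offspring are redrawn so the realized count keeps the Thomas mean κAµ;
  hard-core violations get bounded retries and are then dropped (a warning
  fires below 80% of the expected count).
- `generate_arbors` — three regimes: `coordinated` (0.9 × nearest-neighbor
  distance), `independent` (radius ~ N(µ, σ), blind to neighbors), and
  `overgrown` (1.1 × second-nearest-neighbor distance, territories past the
  first neighbor ring). Every polygon is regenerated with a growing floor
  radius until it contains its reference soma disk.
- `generate_tip_field` / `generate_clone_field` — fixtures with known
  ground truth: a controllable fraction of tips on soma rims, and clone
  columns (polygonized disks kept fully in-window) with a known dispersed
  fraction p and |N(mean, sd)| radial displacements, redrawn if they land in
  a column.

Densities are configurable with wild-type presets of 1,495 (OFF) and 1,290
(ON) cells/mm², the printed population densities; soma diameter defaults to
10.0 µm, the measured mean used as the hard-core distance at all ages. The
arbor-geometry parameters (α, 12 vertices, 8% vertex jitter, cluster and
clone parameters) have no published values; they are package choices at
biologically plausible scales, exposed in `sim_config`, and should not be
read as estimates from data.

What the generators deliberately do not emulate: pixel-level images, 3D
z-structure, soma-size variability coupled to position, mechanistic
migration dynamics, and retina-wide density gradients (fields are
homogeneous). Passing tests therefore validate the statistical machinery
and the qualitative phenotype contrasts, not quantitative agreement with
any particular biological dataset.

## Numerical choices and problem sizes

All randomness flows through R's Mersenne-Twister from an explicit seed;
per-stage child seeds derive arithmetically from the master seed
(`derive_seed`), so pipeline stages re-run independently and output bundles
echo their full configuration. Geometry is continuous µm (no pixel grid),
distances Euclidean. Voronoi conservation holds to $10^{-6}$ relative; the
annulus edge correction is exact to rounding.

The test suite runs its simulations at the native field scale (175–190
cells per 353.55 µm window) with 5–20 seeded replicates per property and
1,000-replicate type-I calibrations for the scalar tests; the acceptance
script uses 5 arrays for the effective-radius recovery and 10 mosaics × 30
arbors per density preset. These sizes give sampling error comfortably
inside the asserted tolerances while keeping the whole suite to a few
minutes.

## Known limitations

- The DRP deficit construction reports $r_e$ at the hard core for any
  array with an intact core, so it cannot distinguish "random" from
  "aggregated above an intact core"; use the short-range density excess.
- The unmatched transposition keeps polygons at identical coordinates;
  territories hugging the window edge lose area to the boundary in every
  field equally, but re-positioning schemes could behave differently.
- ECI is exactly unbiased only at matched arbor/spacing scales (above).
- Contact scoring is 2D with an isotropic tolerance; true apposition is 3D.
- Border-domain exclusion makes VDRI depend slightly on window size through
  the interior-domain count.
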