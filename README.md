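# retmosaic

Spatial statistics and seeded simulation for retinal neuron mosaics, built
around the question of how a mosaic forms: do developing dendritic arbors
exclude neighboring somata of the same type, carving out the exclusion zones
that make the adult array regular?

Retinal cell types tile the retina as *mosaics* — semi-regular arrangements
in which two cells of the same type are rarely found close together. The
package targets the cholinergic (starburst) amacrine cells, whose OFF and ON
populations form independent mosaics, and implements the full quantitative
tool chain used to compare real arrays against matched random references and
to test the dendrite-soma exclusion model:

- **Density recovery profile (DRP)** with exact annulus-window edge
  correction: the density of homotypic neighbors in annuli of width
  \(\Delta r\) (5 µm by default) around each cell,
  \(\lambda_k = c_k / \sum_i A_{ik}\), flat at the global density \(D\) for
  random arrangements and depressed near zero inside an exclusion zone.
- **Rodieck's effective radius** — the exclusion-zone summary
  \(r_e = \sqrt{\sum_{k \le k^*} (1 - \lambda_k/D)\,(r_k^2 - r_{k-1}^2)}\),
  the radius of the equivalent step profile with the same density deficit
  ("dead space"); for a random hard-core array \(r_e\) equals the soma
  diameter.
- **Voronoi domain regularity index (VDRI)** — mean/SD of window-clipped
  Voronoi domain areas over interior domains (≈1.9 for a Poisson array,
  larger for regular mosaics).
- **Unmatched-transposition enclosure null** — each dendritic-territory
  polygon is scored for fully enclosed somata on its own field and then
  transposed onto every other field of the dataset; the **enclosed cell
  index** (ECI) is (zero-excluded unmatched mean) − (real count), with its
  median tested against 0 by a one-sample Wilcoxon signed-rank test.
- **Flipped-image contact control** — the chance rate of dendritic tips
  terminating on somata, estimated by reflecting the tip channel about both
  field axes; Wilson 95% intervals.
- **Clonal dispersion metrics** — fraction of cells outside clone columns
  and their displacement distances.
- **Seeded generators** for every input: random hard-core arrays, mosaics
  grown by dendrite-soma exclusion, aggregated (Thomas-process) arrays,
  arbor territories (coordinated / independent / overgrown), dendritic tip
  fields with a known contact rate, and clone-column fields with a known
  dispersed fraction.

## Worked example

Simulate an OFF wild-type mosaic (1,495 cells/mm² in a 353.55 µm square
field) grown by dendrite-soma exclusion, then quantify it:

```r
library(retmosaic)

cfg <- sim_config(mode = "exclusion_mosaic", target_density = 1495, seed = 7)
mosaic <- simulate_exclusion_mosaic(cfg)
mosaic$field
#> <soma_field> 187 somata in 353.6 x 353.6 um window (1496 cells/mm^2)

compute_drp(mosaic$field, bin_width_um = 5, max_radius_um = 150)
#> <drp_result> n = 187, D = 1496 cells/mm^2, 30 bins of 5 um, r_e = 12.65 um

compute_vdri(mosaic$field)
#> <vdri_result> VDRI = 3.094 over 141 interior domains

bat <- random_reference_battery(mosaic$field, n_sims = 5, seed = 8)
round(bat$summary, 3)
#>                     observed sim_mean sim_sd     z
#> vdri                   3.094    2.588  0.141 3.577
#> effective_radius_um   12.652   10.459  0.534 4.105
```

The exclusion-grown mosaic has an effective radius of 12.7 µm — beyond the
10 µm soma hard core of density-matched random arrays (z ≈ 4) — and is more
regular than random (VDRI 3.09 vs 2.59 ± 0.14). Scoring each cell's arbor
for fully enclosed somata shows the coordination the exclusion model
predicts:

```r
counts <- vapply(mosaic$arbors, count_enclosed, integer(1),
                 field = mosaic$field)
mean(counts == 1)   # fraction of arbors enclosing only their own soma
#> 1
```

A command-line front end over the same functions is installed at
`inst/cli/mosaic_pipeline.R` (`simulate`, `drp`, `vdri`, `battery`,
`enclosure`, `contact`, `disperse`), each command writing a
self-describing output bundle (results JSON, tidy TSVs, config echo).

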