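# autoquant

Quantification toolkit for single-cell autophagy and lysosome-positioning
assays. It implements, as tested and reusable R code, the analysis
procedures such studies run downstream of the microscope and the blot
scanner:

* **Equal-area concentric-ring profiling** of a marker's radial
  distribution in a cell — the readout that distinguishes perinuclear
  from peripheral lysosome positioning. Each segmented cell is divided
  into K = 4 rings of equal area whose boundaries are uniformly scaled
  copies of the cell boundary about the nucleus centroid; the per-ring
  intensity density is normalized to the whole-cell density
  (n_k = d_k / d_cell, uniform staining ⇒ n_k = 1), after rolling-ball
  background subtraction (radius 30 px) and maximum-intensity projection.
* **Tandem mCherry-GFP-LC3 flux scoring**: LoG punctum detection in both
  channels, greedy nearest-pair matching, and the standard rule —
  mCherry-positive puncta = autophagic vacuoles (AV), mCherry+GFP =
  autophagosomes (APG), mCherry-only = autolysosomes (AL = flux), with
  AV = APG + AL asserted per cell.
* **TEM vacuole morphometry**: the ≥2-of-4-criteria autophagosome rule
  (with a 0.5 µm size gate and APG precedence) applied to per-vacuole
  annotation tables, plus per-cell AV area fractions and maturation
  percentages.
* **Densitometry and statistics**: loading-control ratios, fold changes
  vs a control group, compartment percentages, pooled-variance unpaired
  t-test and one-way ANOVA with Šidák-adjusted pairwise comparisons.
* **A synthetic-scene generator** (cells, nuclei, radially biased puncta,
  two-channel tandem scenes, vacuole and band tables) with complete
  ground truth, so every stage is verifiable without instrument data.

See `vignettes/autoquant-methods.Rmd` for the model, parameter and
design-choice documentation.

## Worked example

```r
library(autoquant)

# a synthetic cell with strongly perinuclear marker placement
p <- scene_params(ring_weights = c(0.05, 0.10, 0.25, 0.60),
                  n_puncta = 200L, seed = 42)
scene <- generate_lysosome_scene(p)
res <- analyze_cell_rings(scene$stack)   # segment, subtract, partition, profile
res$profile
#>    cell condition ring      I    A     d     n     f
#> 1 cell1      none    1  69837 9145  7.64 0.421 0.104
#> 2 cell1      none    2  99238 9301 10.67 0.589 0.148
#> 3 cell1      none    3 187780 9207 20.40 1.126 0.281
#> 4 cell1      none    4 312472 9287 33.65 1.857 0.467
```

Ring 1 is peripheral, ring 4 perinuclear. The four ring areas `A` agree
within 2% (equal-area invariant); the normalized density `n` rises from
0.42 at the cell edge to 1.86 around the nucleus — the marker is almost
twice as concentrated perinuclearly as the cell average, as the
placement law (60% of puncta targeted at ring 4, measured fraction
`f[4]` = 0.467) dictates.

```r
# tandem-reporter flux on a scene with 20 APG + 30 AL puncta
pt <- scene_params(n_puncta = 50L, apg_fraction = 0.4,
                   spot_amplitude = 200, seed = 42)
flux <- analyze_tandem_scene(generate_tandem_scene(pt)$stack)
flux$summary
#>    cell AV APG AL match_radius
#> 1 cell1 50  20 30            4
```

All 50 red puncta are recovered; 20 match a green punctum (APG), the
remaining 30 are GFP-quenched autolysosomes — the flux readout — exactly
the generator's composition.

## Command line

```sh
autoquant simulate --kind lysosome --config cfg.yaml --seed 1 --out scenes/
autoquant rings    --in scenes/  --out results/
autoquant puncta   --in tandem/  --out results/
autoquant morpho   --in tables/  --out results/
autoquant stats    --in bands.csv --out results/ --control wt
```

(`inst/cli/autoquant` is the launcher; every stage is equally available
as an R function: `run_simulate()`, `run_rings_dir()`, `run_puncta_dir()`,
`run_morpho_dir()`, `run_stats_file()`.)

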