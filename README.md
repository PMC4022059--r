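# stovermorph

Multi-scale morphometrics of pretreated lignocellulosic biomass micrographs.

Dilute-acid pretreatment carried out at identical chemical severity in
different reactor types (batch ZipperClave, steam gun, horizontal screw)
yields substrates with very different enzymatic digestibility, and the
difference is structural: particle size reduction, cell–cell dislocation,
surface roughening, and intra-wall delamination. `stovermorph` is for
microscopists and bioenergy researchers who need to turn micrographs of such
substrates into comparable numbers. It implements one quantitative estimator
per imaging scale, ground-truthed synthetic generators for all four
modalities, and the correlation report linking structure to digestibility.

## The measurements

* **Particle geometry** (flatbed scans): threshold → distance-transform-
  seeded watershed to split touching particles → per-particle area,
  perimeter, aspect ratio (moment ellipse major/minor), roundness
  `4·area/(π·major²)`, plus histograms and per-sample means.
* **Cell wall thickness** (confocal sections): the boundary-distance map
  `D_B(x,y) = l·√((x−x_B)² + (y−y_B)²)` (exact Euclidean distance of each
  wall pixel to the nearest background pixel, `l` = pixel length) evaluated
  at the medial axis transform `MAT(x,y)` of the binarized wall mask gives
  one thickness sample `CWT = D_B(MAT(x,y))` per mid-line pixel — thousands
  of measurements per image. For adjoined cells the raw value is each cell's
  wall thickness; for dislocated cells a `disjoined-doubled` convention is
  provided.
* **SEM surface roughness**: each square ROI is rescaled to the full 0–255
  dynamic range and its population SD of gray values taken; ROI SDs
  (reference protocol: six 0.5 µm ROIs × three micrographs = 18) are
  summarized as mean ± SD-among-ROIs. A relative proxy for exposed surface
  area, not a height roughness.
* **Intra-wall void/delamination fraction** (TEM): threshold anchored to a
  reference region containing only void space (e.g. the lumen),
  `T = x̄_v + k·σ_v`; the pixel share of the intra-wall ROI on the void side
  of `T` is the delamination/porosity percentage, and void regions get
  particle-style shape descriptors.
* **Correlation report**: Pearson R and R² of every structural and
  compositional parameter against glucan release, over the pretreated-only
  or full sample set.

## Worked example

Measure wall thickness on a synthetic cell lattice with 6 px walls at
0.5 µm/px (so true per-cell half-width is 1.5 µm), then reproduce the
structure–digestibility correlation table from the bundled per-sample
summaries:

```r
library(stovermorph)

lat <- make_cell_lattice(wall_thickness_px = 6, cell_diameter_px = 30,
                         n_cells = 9, image_size = c(160, 160),
                         seed = 3, pixel_length = 0.5, units = "um")
cwt <- summarize_thickness(sample_thickness(distance_map(lat$mask),
                                            medial_axis(lat$mask), "raw"))
cwt$overall
#>       mean       sd   n
#> 1 1.534202 0.114291 856

tab <- build_correlation_table(reactor_morphometrics())
render_report(tab, "correlations.csv", "correlations.txt")
```

`correlations.txt`:

```
# response: glucan_release | sample set: pretreated-only | samples: ZC, SG, HS
parameter                         R      R^2    n
xylan                         -1.00     1.00    3
lignin                         0.87     0.76    3
degree_of_polymerization       0.26     0.07    3
particle_size                 -0.71     0.50    3
aspect_ratio                  -0.98     0.97    3
cell_wall_thickness           -1.00     1.00    3
surface_roughness              0.97     0.94    3
delamination_porosity          1.00     1.00    3
```

The 856 thickness samples average 1.53 µm — the 1.5 µm construction
half-width to within rasterization error (lattice nodes contribute slightly
larger values). In the correlation table, xylan removal, thinner walls among
pretreated samples, rougher surfaces and more intra-wall delamination all
track glucan release; composition alone (lignin barely varies) does not
explain digestibility.

A command-line front end over the same functions is installed at
`system.file("cli", "stovermorph.R", package = "stovermorph")`, with
subcommands `particles`, `wallthickness`, `roughness`, `voids`, `correlate`,
and `simulate`.

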