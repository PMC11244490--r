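# bamboostand

Individual-plant inventory of moso bamboo (*Phyllostachys edulis*) stands
from combined airborne (ALS) and terrestrial (TLS) laser scanning.

Dense bamboo stands defeat single-source LiDAR inventory: airborne
scanning sees the canopy but not the culms, so stem diameters are
unobtainable and interlocking crowns are under-segmented; terrestrial
scanning sees the culms but not the crown tops, so heights are
systematically underestimated. bamboostand implements the combined
workflow — register the terrestrial cloud into the airborne frame, merge,
and extract per-plant traits from the cloud that has both dense culms and
complete crowns — together with everything needed to validate it:

* **Registration** — seven-parameter Helmert (similarity) transform
  estimated by least squares from surveyed plot-corner targets,
  $X = \Delta + (1+m)\,M(\theta)\,X_0$ in the small-angle form, refined by
  trimmed, staged point-to-point ICP minimizing
  $\tfrac1n\sum_i \lVert R P_i + T - P_i' \rVert^2$.
* **Terrain** — progressive TIN densification ground filter, 0.5 m DEM,
  height-above-ground normalization.
* **Segmentation** — top-down vertex-based region growing (PCS) for
  airborne clouds; culm-first comparative shortest-path assignment (CSP,
  DBSCAN culm detection + multi-source Dijkstra over a k-NN graph, run as
  a double pass) for terrestrial and merged clouds.
* **Traits** — plant height as the apex height above ground; DBH from a
  least-squares cylinder fit of the 1.2–1.4 m culm slice, minimizing the
  orthogonal surface distance
  $d_i = \lVert (p_i-c) - ((p_i-c)\cdot a)a \rVert - 1/k$, DBH $= 2/k$.
* **Evaluation** — one-to-one nearest-first matching against a field
  inventory; recall $r = N_t/(N_t+N_o)$, precision $p = N_t/(N_t+N_c)$,
  $F = 2rp/(r+p)$; trait RMSE and $R^2$ over correctly matched plants.
* **Simulation** — a synthetic stand generator (tapered culms with
  drooping tips, branch-structured crowns, sloped ground) with ALS-like
  and TLS-like scanner models (logistic height-retention occlusion,
  azimuthal culm shadows, leaf-cluster occlusion, per-plant canopy
  ceilings) so every stage can be tested against labelled ground truth.

The package is tidyverse-native: clouds are tibbles with frame metadata,
every stage takes a data frame first and returns a tibble, fitted objects
have `tidy()`/`glance()` methods, and result types have `autoplot()`
methods.

## Worked example

Simulate a 37-plant plot, run the full pipeline on all three data
sources, and evaluate against the simulated field survey:

```r
library(bamboostand)

run <- run_pipeline(pipeline_config(seed = 101,
                                    stand = stand_config(n_plants = 37)))
run$detection
#> # A tibble: 3 x 9
#>   source n_reference n_detected    nt    nc    no recall precision f_score
#>   <chr>        <int>      <int> <int> <int> <int>  <dbl>     <dbl>   <dbl>
#> 1 als             37         24    24     0    13  0.649         1   0.787
#> 2 tls             37         37    37     0     0  1             1   1
#> 3 merged          37         37    37     0     0  1             1   1
run$traits
#> # A tibble: 5 x 6
#>   source trait        n    rmse r_squared      bias
#>   <chr>  <chr>    <int>   <dbl>     <dbl>     <dbl>
#> 1 als    height_m    24 0.682       0.567 -0.0298
#> 2 tls    height_m    37 1.54        0.742 -1.46
#> 3 tls    dbh_m       37 0.00575     0.785  0.000439
#> 4 merged height_m    37 0.356       0.916  0.193
#> 5 merged dbh_m       37 0.00242     0.960 -0.000139
```

Reading the tables: the airborne source detects only 24 of 37 plants
(close neighbours merge under top-down growing) but with no false
detections; the terrestrial and merged sources detect every plant via
their culms. Heights from terrestrial data alone are biased 1.5 m low —
the scanner does not see the crown tops — while the merged cloud brings
height RMSE down to 0.36 m; DBH from the merged cloud improves on
terrestrial-only because airborne returns fill the culm arcs that leaves
occlude from the ground. `autoplot(run$segments$merged, colour =
"segment")` draws the segmentation; `tidy(run$helmert)` and
`glance(run$icp)` expose the registration diagnostics.

Three preset plots (37, 45, 52 plants) matching a small field campaign
are available as `make_fixtures("A1", dir)`, which writes LAS clouds,
control points, and the truth inventory; `run_pipeline()` also accepts
such files via `pipeline_config(inputs = list(...))`. A thin command-line
front end over the same functions is installed at
`system.file("scripts", "bamboostand.R", package = "bamboostand")`.

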