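# cpmforce

Cell shape simulation and force inference with the Cellular Potts Model
(CPM), for computational biophysicists who model single cells, adhering
pairs, and sorting aggregates on a 2D lattice and want the **force field
that is consistent with the model's own energy** rather than a
phenomenological overlay.

In the CPM each cell is a 4-connected set of lattice sites sharing an
integer spin index (0 = medium), evolving under the Hamiltonian

    H = sum_i [ lambda_a (A_i - a_i)^2 + lambda_p (P_i - p_i)^2
                + J(0, tau_i) P_0i + 1/2 sum_j J(tau_i, tau_j) P_ij ]

by Metropolis dynamics: a random boundary spin copy is accepted with
probability 1 if `dH + H0 < 0` and `exp(-(dH + H0)/T)` otherwise, under a
connectivity constraint. Perimeters are neighborhood-scaled (discordant
site pairs within Euclidean radius `r`, divided by `xi(r)`; default
`r = 3`, `xi = 18`). Since `F = -grad H`, the package computes boundary
forces by centered differences of one-site protrusion/retraction variants,
smooths them against lattice artifacts with perimeter-weighted averaging,
and interpolates them to the cell interior along centroid rays. The
closed-form force `F = -[2 lambda_a (A - a) + 2 lambda_p (P - p) kappa +
J_eff kappa] n` serves as the independent oracle throughout the tests.
A wave-pinning reaction–diffusion module (active/inactive GTPase with mass
conservation on the moving cell interior) couples polarization to edge
contractility via `dH_u = +/- beta u`.

The compiled Monte Carlo core makes multicellular runs (100-cell sorting
aggregates, 1000+ MCS) a matter of seconds.

## Worked example

Force map of a digitized disk (diameter 23) under the benchmark parameters
`a = 300, p = 100, lambda_a = lambda_p = 10, J(0,1) = 3000`:

```r
library(cpmforce)
st <- single_cell_state("disk", width = 50, height = 50, diameter = 23,
                        a = 300, p = 100, lambda_a = 10, lambda_p = 10,
                        j_medium = 3000)
tidy(st)
#> # A tibble: 1 x 7
#>      id  area perimeter     a     p     x     y
#> 1     1   408      74.4   300   100  25.5  25.5

f <- cell_forces(st, smooth_radius = 3, mode = "linear")
f
#> # A tibble: 408 x 6
#>       x     y cell_id    fx    fy weight
#> 1    21    15       1  680. 1931.     15
#> 2    22    15       1  673. 1994.     13
#> 3    23    15       1  465. 2160.     12
#> # 405 more rows

net_force(f)
#> # A tibble: 1 x 2
#>      fx        fy
#> 1     0 -5.46e-12
```

The cell is over its rest area (408 > 300), so the bracket
`2*10*(408-300) + 2*10*(74.4-100)/11.5 + 3000/11.5 ~ 2376` is positive and
all vectors point inward, with magnitudes near 2376 at the boundary and
decaying linearly to zero at the centroid; the net force vanishes to
rounding because the field is the gradient of a scalar. `autoplot(f)` or
`plot_force_field(st, f)` draw the arrow map.

A dynamic run — the shrinking cell whose perimeter equilibrates first:

```r
res <- run_scenario("shrink-equilibrate", seed = 1)
res$summary[c(1, 2, 5, 11), c("mcs", "area", "perimeter")]
#>     mcs  area perimeter
#> 1     0   408      74.4
#> 2     1   400      88.8
#> 3     4   328      98.2
#> 4    10   232      99.6
```

The strong perimeter penalty (`lambda_p = 2000`) drives `P` into its rest
band within ~4 MCS while the area keeps relaxing toward `a = 200`.

Other entry points: `run_scenario("adhesion-pair" | "signaling-cell" |
"signaling-pair" | "sorting-separation" | ...)`, `boundary_forces()`,
`smooth_forces()`, `interpolate_forces()`, `analytic_force()`,
`tension_pressure()`, `rd_step()`, `run_signaling_cell()`,
`directional_deviation()` / `relative_magnitude()` / `field_sse()`,
`optimal_smoothing_radius()`, `lhs_parameter_search()`,
`make_synthetic_reference_field()`. The methods vignette
(`vignettes/cpm-forces.Rmd`) documents the model, parameters, and design
choices.

## File formats and command line

Lattice snapshots are plain-text integer grids (one row per line); force
tables are TSV with columns `x y cell_id fx fy` (0-based coordinates,
x rightward, y downward, origin at the top-left site — the R API itself is
1-based); configs are flat `key = value` files using the Hamiltonian symbol
names (`lambda_a`, `rest_area`, `rest_perimeter`, `temperature`, `J.0.1`,
...). A 5x5 lattice file:

```
0 0 0 0 0
0 1 1 0 0
0 1 1 2 0
0 1 2 2 0
0 0 0 0 0
```

`cpm_cli()` (wrapped by `inst/cli/cpmforce`) exposes `simulate`, `forces`,
`scenario`, and `compare` subcommands, e.g.

```sh
inst/cli/cpmforce scenario shrink-equilibrate --seed 1 --mcs 10 --out out/
inst/cli/cpmforce forces --lattice lat.txt --config run.cfg --smooth-radius 3 --out forces.tsv
inst/cli/cpmforce compare --ref ref.tsv --model forces.tsv --report report/
```

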