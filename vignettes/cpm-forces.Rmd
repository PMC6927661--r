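---
title: "From lattice energies to cellular forces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lattice energies to cellular forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmforce)
```

## The model

`cpmforce` simulates cells as sets of lattice sites sharing an integer index
(the Cellular Potts Model, CPM) and extracts the force field consistent with
the model's energy. For a single cell surrounded by medium the Hamiltonian is

$$H = \lambda_a (A - a)^2 + \lambda_p (P - p)^2 + J(0,1)\,P_{0},$$

a quadratic penalty for deviations of the area $A$ from its rest value $a$, a
matching penalty on the perimeter $P$, and a contact energy per unit length of
cell–medium interface. For many cells the energy decomposes per cell, with
cell–cell contacts weighted by $J(\tau_i, \tau_j)$ and each shared interface
counted half toward either owner. Shapes evolve by Metropolis dynamics:
a random source site copies its spin onto a random Moore-neighbor target, and
the move is accepted with probability $1$ if $\Delta H + H_0 < 0$ and
$e^{-(\Delta H + H_0)/T}$ otherwise. One Monte Carlo step (MCS) makes
`width * height` such attempts. A connectivity constraint rejects moves that
would fragment the losing cell, and also moves that would attach a site to
the gaining cell by a diagonal contact only, so every cell remains a
4-connected set at every step. At $T = 0$ an exactly neutral move is accepted
(the continuous limit of $e^{0} = 1$); a cell may in principle retract its
last site, which no shipped parameter set ever approaches.

### Perimeter estimation

A naive edge count over-estimates the length of staircase boundaries. The
perimeter is instead the number of ordered site pairs $(x, y)$ with
$\mathrm{spin}(x) = i$, $y$ within Euclidean distance $r$ of $x$, and
$\mathrm{spin}(y) \neq i$, divided by a calibration factor $\xi(r)$. The
default is $r = 3$, $\xi = 18$: 18 is exactly the discordant-pair count per
unit length of a straight boundary at $r = 3$, so straight edges measure
their true length and a digitized disk's perimeter lands within a few percent
of $\pi D$ (the package tests assert 6%). Users supplying another $r$ must
supply the matching $\xi$; a practical way to calibrate one is the straight-
edge pair count per unit length, which is how the shipped value arises.

## Forces from the energy

Because $H$ is a scalar energy, a force field follows from
$\mathbf F = -\nabla H$. At each boundary site the gradient is approximated by
a centered difference: for the $x$ component, one variant configuration
advances the cell's boundary one site in $+x$ and another in $-x$ (a
protrusion and a retraction spin copy on the appropriate side), and

$$F_x = -\frac{H^i(\sigma_{+x}) - H^i(\sigma_{-x})}{2h}.$$

$H^i$ is the cell's own share of the energy, so in multicell configurations
the variants shift a cell–cell interface and the cell feels half of the
shared contact energy. At sites where both neighbors along an axis are inside
(or both outside) the cell that component has no defined one-site variant; it
is set to 0 and recovered by smoothing. Vectors are reported as forces
exerted by the cell boundary: inward when the cell is over its targets.
The closed form for this Hamiltonian,
$\mathbf F = -\left[2\lambda_a(A - a) + 2\lambda_p(P - p)\kappa +
J_\mathrm{eff}\,\kappa\right]\hat n$, with $\kappa$ the local curvature and
$J_\mathrm{eff}$ the effective contact energy, is available as
`analytic_force()` and serves as the independent oracle in the test suite;
`tension_pressure()` exposes the equivalent line tension
$\gamma = \partial H / \partial P$ and pressure
$\Pi = -\partial H / \partial A$.

### Smoothing

Raw centered differences inherit the lattice: unsmoothed vectors point along
a handful of axis/diagonal directions. Each boundary vector is therefore
replaced by a weighted mean of the vectors at same-cell boundary sites within
a Euclidean disk (the site itself included), weighted by each contributing
site's local perimeter share — its discordant-pair count. The weight choice
matters: in the package's disk benchmarks, perimeter weights roughly halve
the magnitude error of uniform weights. Smoothing radius 3 aligns disk and
ellipse force directions with the analytic normals to a few degrees (median),
and the tests assert direction medians under 15 degrees and magnitude
medians around 10% against the closed form.

Two caveats the tests make explicit. First, per-site magnitudes are
quantized: one discordant pair in the adhesion term is worth $J/\xi$ energy
units, and where the closed-form bracket nearly cancels (disks near radius
10 under the benchmark parameters) the median magnitude error stays in the
10–16% range no matter how the average is weighted. Second, the package's
sweep of smoothing radii against a 10/20-semi-axis ellipse's unit normals
(evaluated at each site's ellipse parameter angle, normalized vectors,
`optimal_smoothing_radius()`) has its SSE minimum at radius 4: direction
error is essentially converged there, and wider averaging only blends
distinct normals across curved arcs. Published analyses of this construction
report larger optima; reconstructions that evaluate the target normal from
the site's polar angle instead move the optimum to 11–13, so the optimum is
sensitive to details of the error metric that the package fixes as stated
here. The sweep, not any remembered constant, is what the package reports.

### Interior interpolation

The Hamiltonian prescribes forces only on the boundary. For display and for
comparison with traction-force data, the field is interpolated inward: each
interior site is matched to the boundary site whose ray from the cell
centroid (configurable center) deviates least in angle from the site's own
ray — ties resolved to the nearer boundary site, then site order — and the
boundary vector is scaled by $t$, $t^2$, or $(e^t - 1)/(e - 1)$ of the
relative radial position $t \in [0, 1]$ (modes `linear`, `quadratic`,
`exponential`; all zero at the center, full at the boundary). The interior
field is a phenomenological visualization device: a real cell's interior
force pattern can have multiple organizing centers that a single-center
interpolation cannot represent, so it should not be over-interpreted.

## Internal polarization (wave pinning)

The signaling module couples the lattice to a two-species reaction–diffusion
system on the cell interior: active $u$ (slow diffusion, $D_u$) and inactive
$v$ (fast, $D_v$), with

$$f(u, v) = v\left(k_0 + \gamma\,\frac{u^2}{K^2 + u^2}\right) - \eta\,u,$$

$\partial_t u = D_u \nabla^2 u + f$, $\partial_t v = D_v \nabla^2 v - f$, and
zero-flux boundaries at every cell edge (no transport between cells or into
the medium). The explicit scheme uses the conservative flux form, so
$\sum (u + v)$ is conserved to rounding; `rd_step()` refuses a `dt` above the
stability bound $h^2 / (4 \max(D_u, D_v))$. Defaults
($D_u = 0.1$, $D_v = 10$, $k_0 = 0.067$, $\gamma = 1$, $K = 1$, $\eta = 1$,
$dt = 0.02$, 20 substeps per MCS) sit in the bistable wave-pinning regime of
the canonical model: a high-activity front invades, decelerates as the
inactive pool depletes, and stalls, leaving a stable polarized plateau. The
RD-to-MCS clock ratio is a modeling choice (nothing in the lattice dynamics
fixes a physical time), as is the initial condition of the polarized
scenarios: the leftmost 30% of the cell's extent starts at $u = 2$, the rest
at $0.05$, over uniform $v = 2$ — chosen once so that the pinned plateau
covers a mid-range fraction of the cell.

Coupling to the lattice follows a contractility rule: a move's energy change
gains $+\beta u$ for a protrusion (evaluated at the copied source site) and
$-\beta u$ for a retraction (at the lost site), so high activity promotes
local edge retraction. After an accepted retraction the lost site's $u$ and
$v$ are redistributed to same-cell sites within radii 3 and 75 respectively
(proportional to current content, uniform when the neighborhood is empty,
radius doubled until a recipient exists); a gained site starts at zero
concentration. Both rules conserve per-cell mass exactly, which the tests
check through long coupled runs. With $\beta = 0$ the coupled engine
reproduces the uncoupled trajectory bit for bit under the same seed.

## Scenarios and the synthetic data they generate

`run_scenario()` packages the benchmark simulations; all randomness flows
from one integer seed, and identical seeds give identical trajectories.

- `static-shapes` (50×50, $a=300$, $p=100$, $\lambda_a=\lambda_p=10$,
  $J(0,1)=3000$): force maps for a diameter-23 disk, a 21×41-axis ellipse,
  and a seeded irregular blob (a disk roughened by a high-temperature
  burn-in).
- `shrink-equilibrate` ($a=200$, $\lambda_a=8$, $p=100$, $\lambda_p=2000$,
  $J=3000$, $T=10$, diameter-23 disk): the perimeter is driven to its rest
  value within ~4 MCS while the area relaxes slowly; the scaled perimeter at
  MCS 10, averaged over 20+ seeds, is the package's stochastic benchmark
  (≈99.3 against a reference band 98.9–100.1).
- `adhesion-pair` ($\lambda_p=0$, $\lambda_a=8$, $a=300$, $J(0,\cdot)=1800$,
  $T=300$): two touching disks under cell–cell contact energy 1800, 3600 or
  7200 stay widely attached, narrowly attached, or detach — the classic
  trichotomy around $J(1,2) = 2J(0,1)$ — and the interface force at MCS 1
  increases with $J(1,2)$.
- `signaling-cell` ($\lambda_a=10$, $a=4000$, $\lambda_p=0$, $J=5000$,
  $T=50$, $\beta=40$): a left-polarized cell retracts its rear and, via the
  area constraint, expands elsewhere, migrating toward $+x$.
- `signaling-pair` ($\lambda_a=2$, $a=2500$, $J=30000$, $T=200$,
  $\beta=80$): two adhering polarized cells; the per-site force decomposes
  exactly into the passive $-\nabla H$ part and the active $\beta u$ part.
- `sorting-*` (100 cells of rest area 300 in a 10×10 block aggregate, types
  assigned 50/50 by seeded shuffle; $\lambda_a=1000$, $p=67$,
  $\lambda_p=20$, $T=600$): the separation, checkerboard and engulfment
  contact-energy patterns. Under separation parameters (homotypic 900,
  heterotypic 9000) the heterotypic interface drops below half its initial
  length well before MCS 1000, with early force hot spots on heterotypic
  contacts.

The aggregate size (100 cells) and the recorded problem sizes above are the
package's chosen benchmark scale: large enough for the sorting phenomenology,
small enough that the whole suite runs in minutes on one core.

`make_synthetic_reference_field()` fabricates a labeled-synthetic stand-in
for an externally measured traction field — the closed-form radial field
plus interior interpolation, Gaussian noise, and optional magnitude "hot
spots" — for exercising the comparison metrics (`directional_deviation()`,
`relative_magnitude()`, `field_difference()`, `field_sse()`) and
`lhs_parameter_search()`, which ranks Latin-hypercube parameter draws by a
user objective such as the SSE against a reference field. It emulates the
tabular shape and failure modes (localized foci, noise) of real traction
microscopy data but none of its physics; passing tests say the metrics and
search behave correctly, not that the CPM fits any particular experiment.

## What the synthetic benchmarks do and do not show

Passing tests establish internal consistency (incremental energies equal
full recomputation to 1e−9; caches equal recounts; acceptance follows the
Metropolis law to sampling error; mass is conserved) and agreement with the
continuum closed form to the quantization limits stated above. They do not
validate the CPM as a model of any particular cell type, do not assign
physical units to force or time (one MCS is not a second; contact energies
are not calibrated), and do not correct lattice anisotropy — the neighborhood
perimeter suppresses but does not remove direction-dependent bias.

## Numerical choices, degenerate inputs, determinism

Sites outside the lattice are medium; shipped scenarios keep cells several
sites from the frame, and a variant that would protrude off-lattice
contributes a zero force component. Cells whose sites are all boundary
(thin strips) skip interior interpolation. An empty force table sums to a
zero net force. All stochastic entry points draw from R's RNG only, so
`set.seed()` (or a scenario's `seed` argument) makes every trajectory,
including the compiled Monte Carlo loop, bit-reproducible; the blob
generator seeds its own stream and restores the caller's. File formats
(lattice grids, force tables, chemical fields, key–value configs) write
0-based coordinates with x rightward and y downward from the top-left
origin, 9+ significant digits, and are byte-deterministic.
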