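---
title: "Population density simulation on N-dimensional grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population density simulation on N-dimensional grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgrid)
```

## The model

A population of unconnected, homogeneous point neurons that all obey the
same N-dimensional ODE $\dot{y} = F(y)$ and receive Poisson-distributed
spike input can be described by a probability mass function over the
model's state space instead of by individual trajectories. `popgrid`
discretizes the state space into a regular grid of identical half-open
boxes; each cell holds the probability that a neuron from the population
occupies that volume, and the mass function evolves under two processes:

1. **Deterministic drift.** Over one time step the flow $F$ carries the
   contents of each cell to a nearby region. Because $F$ does not change,
   the fractions of a cell's mass that land in each target cell are fixed
   for the whole simulation and are precomputed into a sparse,
   row-stochastic transition matrix.
2. **Shot noise.** Each incoming spike shifts a neuron's state by a
   constant vector $J$ (for example, a step in a synaptic conductance).
   Mass therefore jumps between cells with fixed relative offsets and
   fractions, and the effect of a Poisson stream at rate $R$ is the master
   equation $\dot{p} = \sum_k R_k (M_k - I)\,p$, integrated within each
   time step by explicit Euler iterations.

If the model has a threshold-reset mechanism, mass that enters the
threshold layer is counted (that flux divided by the time step is the
population firing rate), held for the refractory period, and reinserted at
the reset cells. Populations are coupled only through these average firing
rates, each connection multiplying the delayed source rate by its number
of connections and feeding it into the target's master equation — the
solution itself is fully deterministic, with no finite-size variability.

## The transition-matrix construction

For each cell the $2^N$ corner points are advanced by one time step of the
model (explicit Euler with 10 equal sub-intervals by default; corner
points shared between cells are advanced once). Treating the transformed
cell as convex — reasonable for small time steps — the Kuhn decomposition
of the unit N-cube into $N!$ simplices (2 triangles in 2-D, 6 tetrahedra
in 3-D) is mapped onto the transformed corners. Each simplex is then
recursively cut against every grid hyperplane it straddles. A cut
classifies vertices as above, below, or (within $10^{-9}$ of a cell width)
on the plane, and splits one crossing edge at a time at its exact
interpolation point, so the pieces partition the simplex and their volumes
sum exactly. When no plane crosses a piece it lies in a single cell, and
its volume is accumulated there. The per-cell volume fractions, normalized
by the transformed cell's total volume, form one matrix row.

`enumerate_bisection_cases()` exposes the combinatorial classification of
these cuts — for a tetrahedron the four canonical vertex configurations
with 3, 4, 2 and 1 intersection vertices — generated from reference
simplices with the crossing edges bisected. The production path uses the
direct recursive split rather than a template lookup; the two are
equivalent in classification, created vertices and conserved volume, and
the recursion avoids maintaining a template table in every dimension.

Numerical safeguards, all deterministic:

* Vertices are clamped to the grid padded by two cell widths after each
  Euler sub-step. In unreachable corners of the state space the flow can
  be extreme (the Hodgkin-Huxley rate functions grow exponentially in
  `v`), and unclamped corner points would overflow; all mass carried that
  far belongs to boundary cells regardless.
* Mass scattered outside the grid is assigned to the nearest boundary
  cell, so every row still sums to one. The grid should be chosen large
  enough that this is rare for the states the population actually visits.
* A per-cell budget (`max_pieces`, default 4096) bounds the subdivision.
  Cells whose transformed image is stretched across a volume-proportional
  number of cells — again the unreachable extremes — would otherwise
  dominate the generation time; past the budget, remaining simplices are
  assigned whole to their centroid cell, which still conserves mass.
  Ordinary cells use a few dozen pieces and never hit the budget.
* A cell whose summed simplex volume deviates more than 20% from the
  first-order affine image volume (the determinant of the transformed edge
  vectors) is counted in a warning: it signals that the convexity
  assumption is strained and a smaller time step may be appropriate. The
  affine reference is used rather than the untransformed cell volume
  because contractive flows (the conductance decay shrinks cells by
  $e^{-1/2.728} \approx 0.69$ per millisecond step) legitimately change
  volume without any non-convexity.
* Row entries below $10^{-12}$ are dropped and the row renormalized.

## Units, time scales and indexing conventions

The built-in models express derivatives per millisecond (their constants
are ms-based); the grid's `timescale` field holds the duration of one
model time unit in seconds (`1e-3` for both built-ins), and a simulation
step of `time_step` seconds advances the model by `time_step / timescale`
model units. Dimension indices and cell indices are 0-based everywhere —
in the R API, the on-disk formats, and the XML dialect — and the membrane
potential is always the last dimension. Flat cell indices are row-major
with the last dimension varying fastest; cells are half-open, so a state
exactly on a shared edge belongs to the cell whose lower edge it sits on.

## Built-in models

**Conductance-based LIF** (`cond3d_derivative`, state `[u, w, v]`):
$C\dot v = -g_l(v - V_l) - w(v - V_e) - u(v - V_i)$ with first-order decay
$\dot w = -w/\tau_e$, $\dot u = -u/\tau_i$. Defaults: $g_l = 0.03$
nS/cm², $V_l = -70.6$ mV, $V_e = 0$ mV, $V_i = -75$ mV, $C = 281$ pF/cm²,
$\tau_e = 2.728$ ms, $\tau_i = 10.49$ ms, threshold $-50.4$ mV, reset
$-70.6$ mV, refractory period 2 ms. The standard grid (`cond3d_grid()`)
spans $u, w \in [-0.2, 5.2]$ nS/cm² and $v \in [-80, -40]$ mV, the region
that contains all significant mass under the drives studied here.

**Hodgkin-Huxley** (`hh_derivative`, state `[h, n, m, v]`):
$C\dot v = -g_k n^4 (v - V_k) - g_{na} m^3 h (v - V_{na}) - g_l (v - V_l)$
with $\dot x = \alpha_x(v)(1 - x) - \beta_x(v)x$ for the gating variables.
The printed $\alpha_m$, $\alpha_n$, $\beta_m$ are $0/0$ at isolated
potentials; they are evaluated via $x/(e^x - 1)$ through `expm1` with the
analytic limit substituted near zero. The standard grid spans $[-0.1,
1.1]$ for the gating variables and $[-100, 60]$ mV for $v$. The model has
no intrinsic reset, and the experiments it reproduces report only average
membrane potentials; to expose a population firing rate this package
nevertheless places a spike-detection threshold at $-10$ mV with reset
$-65$ mV and no gating shift, so mass crossing the spike upstroke is
counted once per action potential and returned near rest with its gating
state (including the elevated $n$ that carries refractoriness) preserved.
This readout is a package choice, not part of the published experiment.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `time_step` | 1 ms | simulation step; also the step the matrix encodes |
| `substeps` | 10 | Euler sub-intervals for vertex transforms (and the Monte Carlo reference, so integrator error cancels in comparisons) |
| `master_steps` | 10 | Euler iterations for the master equation per time step; must satisfy $\sum_k R_k \, dt / n < 1$ (a warning is raised otherwise). Strongly driven networks need 50–100. |
| `resolution` | per experiment | cells per dimension; diffusion-like discretization error shrinks as cells shrink |
| `tau_refractive` | model-specific | refractory hold, rounded to whole steps |
| `delay` | per connection | rate transmission delay; delay 0 means "previous step" so the update stays explicit |

## What the validation shows — and what it does not

The package ships two independent reference simulators: a direct Monte
Carlo simulation of individual neurons, and a finite-size hybrid sampler
that draws discrete coordinates through the precomputed transitions. The
test suite uses them as oracles:

* On the 3-D conductance LIF driven by 50 Hz excitatory and 50 Hz
  inhibitory input, the acceptance script measures the mean absolute
  difference between the grid solution and a 10,000-neuron Monte Carlo
  average membrane potential at 50³; the test accepts ±0.15 mV around the
  0.354 mV reference value. The residual is dominated by two
  discretization effects: scatter spread lets a small mass flux reach the
  threshold layer that individual trajectories would not produce
  (slightly inflating the firing rate and displacing reset mass), and the
  cell-center readout slightly biases the skewed conductance marginals.
  Both shrink with resolution.
* The 25³-versus-50³ error ordering can fail to be monotone: at 25³ the
  −50.4 mV threshold does not align with a cell edge (the effective
  threshold rises by half a cell), which suppresses the spurious threshold
  flux, and the larger early-transient quantization error partially
  cancels the steady-state bias in the mean-absolute metric. Resolutions
  of 50, 100, 150 or 300 cells over the 40 mV range all align the
  threshold exactly and do not encounter this effect.
* The E-I network reproduces the 1:1 equilibrium exactly symmetric across
  the two populations. The 8:2 configuration is reported (with direct
  simulation concurring) to produce a sustained rate oscillation of the
  delayed mean-field loop at 150³ resolution; on the reduced 40³ grid
  used at desk scale, where the $u$ cells are 2.75 nS/cm² wide against a
  4 nS/cm² inhibitory jump, the jump-splitting diffusion damps the cycle
  to a fixed point, and the oscillation check fails at that scale. Finer
  grids restore the cycle at the cost of proportionally longer runs.
* The Hodgkin-Huxley population at 20⁴ produces a strictly increasing
  steady firing rate over external input rates 0–40 Hz (×100 connections,
  3 mV jumps). The full published 50⁴ experiment is far beyond desk scale
  (6.25M cells, with a transition file in the gigabytes and generation
  times reported in the hundreds of hours).

Problem sizes in the test suite — 50³/25³ single population, 40³ E-I, 20⁴
Hodgkin-Huxley, 10⁴ Monte Carlo neurons — are the package's chosen desk
scale; they exercise every code path at the published parameter values
while keeping a full run in minutes.

The Monte Carlo reference emulates exactly the homogeneity assumptions of
the density method (identical neurons, Poisson input, rate-coupled
populations, frozen state during the refractory hold). Passing these
checks therefore validates the numerics of the density solution, not the
biological fidelity of those assumptions: real populations are
heterogeneous, synapses are conductance transients rather than instant
jumps, and spike transmission is pulse-coupled rather than rate-coupled.

## Design choices where the design was open

* **Triangulation.** Any deterministic triangulation of the N-cube works;
  the Kuhn decomposition is closed-form, needs no convex-hull machinery,
  matches the published simplex counts in 2-D and 3-D, and its fixed
  vertex order makes generation reproducible bit for bit.
* **Integrator.** The reference implementation's integrator is not
  documented; explicit Euler with 10 sub-intervals is simple,
  deterministic, and sufficient because trajectory error cancels between
  the density solution and the Monte Carlo reference, which shares it.
* **Simultaneous inputs** are combined into one master-equation generator
  rather than applied sequentially; the operator sum is the exact
  generator, and sequential application would introduce $O(dt^2)$
  splitting error.
* **Delay semantics.** A connection with delay $d$ delivers the source
  rate from completed step $s - 1 - d/dt$; delay 0 therefore means the
  previous step's rate, keeping recurrent graphs explicit and
  well-defined. Refractory release uses `round(tau_ref / dt)` whole steps.
* **Boundary policy.** Out-of-grid mass is clamped to the nearest boundary
  cell: the grid ranges are declared limits of the simulation, and
  clamping preserves mass exactly where reflecting or absorbing rules
  would not.
* **Coplanarity bound.** The combinatorial enumeration of hyperplane cuts
  allows 0 to $N-1$ coplanar vertices (a cut with $N$ coplanar vertices
  and one off-plane vertex has no crossing edge). A looser bound of
  $2^N - 2$ appears in some descriptions of the algorithm but is not
  attainable for a simplex with $N + 1$ vertices.

## Known limitations

* The curse of dimensionality is inherent: cells multiply with every
  dimension, and transition rows lengthen. Five dimensions and beyond are
  out of practical reach at meaningful resolutions.
* Threshold placement interacts with the grid: when the threshold is not
  a cell edge, the effective threshold is the next edge above, which
  perturbs firing rates on coarse grids.
* Oscillatory network states with large synaptic jumps need fine grids;
  jump-splitting diffusion damps limit cycles on coarse ones (see above).
* Input statistics are Poisson only; renewal or bursty inputs are not
  representable by a constant-rate master equation.
* The finite-size sampler resamples cell-to-cell transitions
  independently each step, so it reproduces occupancy statistics but not
  within-cell state continuity.
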