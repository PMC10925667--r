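---
title: "Modelling damage propagation on connectomes with reaction–diffusion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling damage propagation on connectomes with reaction–diffusion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomeRD)
```

## The model

A structural connectome is given as a symmetric, non-negative weight matrix
`W` over `N` regions of interest (ROIs), with `W[i, j]` measuring connection
strength (typically streamline counts scaled by ROI volume) and a zero
diagonal. Dynamics run on the *thresholded* graph: `A[i, j] = 1` iff
`W[i, j] >= S_w`, with the boundary inclusive. Thresholding discards weak,
likely spurious connections; `S_w` is chosen as high as possible while the
graph stays connected (`largest_connecting_threshold()` automates that
scan). The graph Laplacian is `L = A - K` with `K = diag(k)` the degree
matrix; with this sign convention `L` is symmetric negative semidefinite
with zero row sums.

The state is a concentration `theta_i(t)` of damage or pathological
substance per node, evolving under

    dtheta_i/dt = w * (sum_j A_ij theta_j - k_i theta_i) + r * g(theta_i)

i.e. diffusive exchange along edges at rate `w` plus a *local* reaction
`r g(theta)` acting identically in every node (spatial homogeneity of the
reaction is an assumption; region-specific rates are out of scope for this
version). Time units are arbitrary: only the ratio of `w` to `r` and the
graph set the scales. Carrying capacity is normalised to `theta = 1`.

With `g = 0` the model is pure network diffusion: total mass is conserved,
the mean concentration `M(t) = mean(theta)` stays at `M(0) = theta0/N` for a
point seed, and on a connected graph the state relaxes to the uniform vector
`theta0/N` (the heat-kernel solution `theta(t) = expm(w L t) theta(0)` is
available exactly through the symmetric eigendecomposition of `L`). That
conservation is precisely why diffusion alone is a poor model for
progressive disease, and why a reaction term is added.

## Reaction terms and parameters

* `logistic` — `g = theta (1 - theta)` (the FKPP nonlinearity). Per-capita
  growth is maximal at low concentration, so *any* positive seed eventually
  invades the whole connected graph.
* `strong_allee` — `g = theta (theta - theta_c)(1 - theta)`. Per-capita
  growth is negative below the threshold `theta_c`: small concentrations
  heal away. This is the classical bistable (strong Allee) form.
* `neutral_allee` — `g = max((theta - theta_c)(1 - theta), 0)`. Growth is
  switched off, exactly, below `theta_c`: sub-threshold damage neither grows
  nor heals. It sits between the weak and strong Allee effects, and its
  clamp makes the right-hand side non-smooth at `theta = theta_c` (see
  numerical notes below).

Defaults follow the regime the package is built to explore: `r = 1`,
`w = 1`, `theta_c = 0.001` (all per arbitrary time unit; `theta_c` on the
concentration scale). `theta_c` doubles as the observation threshold in
`N(t; theta_c)`, the count of nodes whose concentration *strictly* exceeds
`theta_c` — the Heaviside convention is `Theta(0) = 0`, so a node sitting
exactly at the threshold is not counted. With that convention the pure-
diffusion long-time count is all-or-nothing, `N -> N` if
`theta0/N > theta_c` and `N -> 0` otherwise (`diffusion_limit_count()`),
which the test-suite uses as an analytic oracle against the integrator.

## Integration

Three schemes are provided:

* `expm` — the exact heat-kernel solution, valid for pure diffusion only.
  Implemented by one symmetric eigendecomposition of `L` reused across all
  output times; for the graph sizes targeted here (hundreds of nodes) this
  is both faster and more accurate than Padé-type matrix exponentials.
* `euler` — fixed-step explicit Euler, the simplest scheme that handles the
  nonlinear reaction. A stability guard caps the step at
  `0.5 / (w k_max + r sup|g'|)` (with `sup|g'| <= 1 + theta_c` for the cubic
  terms on [0, 1]); a larger requested step is reduced with a warning.
* `rk45` — adaptive Dormand–Prince 4(5) (deSolve), the default. Tolerances
  default to `rtol = 1e-8`, `atol = 1e-10`: the absolute tolerance must sit
  well below `theta_c = 1e-3`, because outcome classification hinges on
  whether concentrations cross that threshold. The initial trial step is
  capped at the explicit stability bound — the cubic reaction overflows if
  the first trial step spans a whole output interval from a hub seed.

Discretisation can transiently push concentrations slightly negative;
by default (`clip_negative = TRUE`) output states are clipped at zero.
Clipping is done in one place (the dynamics layer) so the reaction formulas
stay exactly as written. Without clipping, trajectories from states in
[0, 1] remain within [-1e-6, 1 + 1e-6] at the default tolerances, which the
suite asserts as a boundedness property.

## Outcomes, stopping, and the invasion value

`classify_outcome()` operationalises the asymptotic regimes: *invaded* when
every node exceeds `theta_c` and lies within `tol_invaded = 1e-3` of
carrying capacity; *extinct* when `M <= tol_extinct = 1e-6` (far below the
`theta_c / N` scale of any shipped fixture); *stalled* otherwise — e.g. the
frozen sub-threshold states of the neutral Allee term. The stopping rule is
`max_i |dtheta_i/dt| < 1e-10`, or a time cap, whichever comes first; a
capped run carries a not-converged flag rather than a hard label.

`seed_outcome()` integrates in blocks (default 5 time units) and exits early
when the outcome is already decided. Two early exits rest on the maximum
principle for graph diffusion (the maximum of `theta` cannot increase while
the reaction is zero or negative): under the neutral Allee term, once every
node is at or below `theta_c` the reaction is off forever and the state can
only relax diffusively (stalled, or extinct if the mean is tiny); under the
strong Allee term, once every node is strictly below `theta_c` the reaction
is strictly negative wherever `theta > 0` and the mass decays to zero
(extinct). These shortcuts are what make bisection cheap.

The *invasion value* — the minimal point-seed concentration `theta0` at a
given node above which the dynamics invade the whole graph — has no closed
form; `invasion_value()` brackets it and bisects on `theta0` to a requested
width (default `1e-4`), relying on monotonicity of the outcome in `theta0`.
Monotonicity is checked at the bracket ends at every call, and the suite
scans a `theta0` grid on the shipped fixtures to confirm it globally (a
violation would invalidate the bisection contract and fails the suite
loudly). On a single isolated node the neutral-Allee invasion value equals
`theta_c` exactly (phase-line argument: without diffusion losses any
`theta0 > theta_c` grows to 1), which the suite uses as a closed-form
anchor.

## The synthetic connectome generator

Real tractography-derived connectomes are typically restricted data, so the
package ships a generator (`generate_connectome()`) that emulates published
whole-brain *summary statistics* rather than anatomy: 379 ROIs; 1,738
undirected links once the weights are thresholded at `S_w = 0.034`
(realised within 5%); a most-connected hub of degree 36 (within ±3); at
least one degree-1 pendant node; full connectivity. The topology recipe is
a degree-sequence-targeted construction: degree targets are drawn from a
clamped lognormal and adjusted to the exact degree sum, a random spanning
tree over the non-pendant core guarantees connectivity, pendants hang off
the core, and a greedy largest-deficit matching fills the remaining stubs.
Supra-threshold weights are heavy-tailed (Pareto, strictly above `S_w`,
scale set by `weight_scale`), with uniform sub-threshold noise on a sample
of non-edges so that thresholding is actually exercised. The published
weight distribution is not available; the Pareto choice is a modelling
convenience and is labelled as such in the generator manifest.

What the fixture does *not* emulate: hemispheric or modular organisation,
spatial embedding, ROI volumes, degree–degree correlations, or the exact
eccentricity of the real pendant node (the generated pendant's mean
shortest path, ≈ 3.6–3.9 hops, is shorter than the published 5.93, though
reliably longer than the hub's, matching the published ordering 2.84 <
5.93). Results on the fixture therefore demonstrate the *mechanisms* —
conservation, thresholds, hub-vs-pendant asymmetry — not quantitative
predictions for any real brain. Generation is deterministic in `rng_seed`
(constraint-satisfaction retries reseed deterministically), and the
caller's RNG stream is left untouched.

## The hub–pendant asymmetry

The package's headline phenomenon: with the neutral Allee reaction at
`r = w = 1`, `theta_c = 0.001`, a seed of `theta0 = 0.1` *invades* the
synthetic connectome from the pendant node but *stalls* from the hub, and
the bisected invasion value at the hub (≈ 0.31) exceeds the pendant's
(≈ 0.007) by more than an order of magnitude. A hub dilutes its initial
load below `theta_c` through its many links before the reaction can amplify
it; a pendant leaks mass through a single link, keeping the local
concentration high until the front is self-sustaining. The strong Allee
term shows the same asymmetry with a much longer invasion time at equal
seeding (tens of times slower on the default fixture), because its growth
rate near the threshold is quadratic rather than linear in
`theta - theta_c`.

## Numerical and design choices

* Threshold boundary: inclusive (`W >= S_w` connects), a literal reading of
  the edge rule; the boundary case is unit-tested.
* Extremal-node ties: lowest index wins (`which.max`/`which.min`), so
  summaries are deterministic even on regular graphs.
* Mean shortest paths: unweighted BFS hop counts, averaged over the other
  `N - 1` nodes (the node itself is excluded from the denominator); defined
  only on connected graphs, otherwise an explicit error.
* Nonzero diagonals in `W` are rejected at load rather than silently
  zeroed; `fix_diagonal = TRUE` zeroes them with a warning. Symmetry is
  accepted to `1e-12 * max(W)` relative and then symmetrised exactly.
* Node indices are 0-free: 1-based everywhere in R, in label files
  (which declare `# index_base=` in a header) and in all CLI output.
* Floats in output files carry 12 significant digits in scientific
  notation, making repeated deterministic runs byte-identical.

## Problem sizes in the test-suite

The suite exercises exact values on 1–5-node graphs, property checks on
random graphs up to 50 nodes (100 instances for connectivity and Laplacian
properties), oracle comparisons against a fine fixed-step Euler integration
(step `1e-4`) on 20-node fixtures, and the full 379-node synthetic
connectome for the generator contract, logistic invasion, the diffusion
limit, and the hub-vs-pendant bisections (bracket width `1e-3`). These
sizes keep the complete suite under a minute while covering every claim the
package makes.

## Known limitations

* Dynamics run on the *binary* thresholded graph; weighted-Laplacian
  dynamics are a natural extension but not implemented.
* The reaction is deterministic, local and homogeneous: no stochasticity,
  no node-specific rates, no nonlocal coupling.
* The invasion value assumes outcome monotonicity in `theta0`; it is
  verified empirically on shipped fixtures, not proven for arbitrary graphs
  and reaction terms.
* The generator reproduces summary statistics only; see above for the
  anatomical features it ignores.
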