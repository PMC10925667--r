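# connectomeRD

Reaction–diffusion dynamics on structural brain connectomes, in R.

## The problem

Network diffusion — the heat equation on a graph — is a popular model for the
progression of neurodegenerative disease and traumatic brain injury across
the structural connectome. But diffusion conserves the total amount of the
spreading substance, and brain damage is not conserved: pathology grows,
and injuries can heal. `connectomeRD` models propagation instead as
**reaction–diffusion on a graph**,

```
dθᵢ/dt = w (Σⱼ Aᵢⱼ θⱼ − kᵢ θᵢ) + r g(θᵢ)
       = w (L θ)ᵢ + r g(θᵢ),      L = A − K,
```

where `θᵢ(t) ∈ [0, 1]` is the concentration of damage/pathology in region
(ROI) `i`, `A` is the adjacency matrix obtained by thresholding the weighted
connectome `W` at `S_w` (`Aᵢⱼ = 1` iff `Wᵢⱼ ≥ S_w`), `kᵢ` the node degree,
`w` the diffusion rate and `r` the reaction rate. Three local reaction terms
are built in:

| kind | g(θ) | behaviour at low concentration |
|---|---|---|
| `logistic` (FKPP) | `θ(1−θ)` | exponential growth — any seed invades |
| `strong_allee` | `θ(θ−θc)(1−θ)` | negative per-capita growth below `θc` — small injuries heal |
| `neutral_allee` | `max((θ−θc)(1−θ), 0)` | frozen below `θc` — sub-threshold damage persists inertly |
| `none` | `0` | pure network diffusion (mass-conserving) |

The package covers the full workflow: loading/validating a weighted
connectome (CSV or MatrixMarket), thresholding, graph statistics, exact
heat-kernel and numerical ODE integration (explicit Euler and adaptive
RK45), the observables `M(t)` (mean concentration over nodes) and
`N(t; θc)` (count of nodes strictly above `θc`), asymptotic outcome
classification (*invaded* / *extinct* / *stalled*), and estimation of the
**invasion value** — the minimal seed concentration `θ0` injected into one
node above which the whole network is eventually invaded — by bisection.
Because real tractography-derived connectomes are often restricted data, a
synthetic generator builds weight matrices whose thresholded graph matches
published whole-brain statistics (379 ROIs, 1,738 links at `S_w = 0.034`,
hub of degree 36, a degree-1 pendant node, fully connected), so every
analysis here runs end-to-end on open synthetic data.

## Worked example

```r
library(connectomeRD)

wc <- generate_connectome(generator_spec(rng_seed = 42))
g  <- threshold_adjacency(wc, 0.034)
summarize_graph(g)
#> <graph_summary> 379 nodes, 1738 links, connected
#>   max degree: node 49 (ROI_049), k = 36, mean path 2.257
#>   min degree: node 321 (ROI_321), k = 1, mean path 3.926

cfg <- simulation_config(w = 1,
                         reaction = reaction_spec("neutral_allee",
                                                  r = 1, theta_c = 0.001))
hub <- 49; pendant <- 321
seed_outcome(g, cfg, hub,     theta0 = 0.1)$label  # "stalled"
seed_outcome(g, cfg, pendant, theta0 = 0.1)$label  # "invaded"

invasion_value(g, cfg, hub,     bracket = c(1e-4, 1), tol = 1e-3)  # 0.3092
invasion_value(g, cfg, pendant, bracket = c(1e-4, 1), tol = 1e-3)  # 0.0074
```

The same seed concentration `θ0 = 0.1` invades the entire connectome when
injected at the *least* connected node but stalls when injected at the hub —
the counterintuitive signature of threshold (Allee) dynamics on a network:
a hub dilutes its initial load below `θc` through its many links before the
reaction can amplify it, while a pendant node keeps its load concentrated
until the local front is strong enough to spread. Accordingly the invasion
value at the hub (≈ 0.31) is over an order of magnitude larger than at the
pendant (≈ 0.007).

A command-line wrapper is installed with the package
(`system.file("cli", "connectomeRD.R", package = "connectomeRD")`) with
subcommands `gen-connectome`, `stats`, `simulate` and `invasion-scan`;
node indices are 1-based in all files and reports.

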