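# polarscape

Macrophages in a tumor microenvironment (TME) are highly plastic: the same
cell can polarize into a tumor-killing M1 state, a spectrum of
tumor-supporting M2 states (M2a–M2d), or hybrids of both. `polarscape`
implements a quantitative pipeline for studying this plasticity as
**noise-induced polarization**: the molecular signals of the TME are treated
as random fluctuations that drive the macrophage's epigenetic state across a
Waddington landscape whose wells are the phenotypes of a Boolean regulatory
network. It is aimed at systems biologists who want to connect logical
network models of cell-fate decisions to stochastic-dynamics observables
(exit times, transition routes, saddle crossings).

## The model

The pipeline has three layers:

1. **Boolean network.** A transcriptional regulatory network with synchronous
   updates. Attractors (fixed points and cycles) are enumerated exhaustively
   or by sampling, their basins of attraction measured, and each attractor is
   labelled with a macrophage phenotype from compartment rules (M1:
   NFκB, STAT1 or TNF-α∧AP1; M2a: IL4∧STAT6; M2b: AP1∨ERK; M2c: IL10∧STAT3;
   M2d: TLR4∧A2a ∨ HIF1α; none: M0). Clamping nodes ON/OFF reproduces
   overexpression and knockout scans.

2. **Epigenetic landscape.** Attractors are embedded in the plane (t-SNE) and
   each phenotype becomes a paraboloid well; the potential is

   F(u,v) = min_i { a_i [ (u−u_i)² + (v−v_i)² ] },

   where (u_i, v_i) is the phenotype's center and the steepness a_i encodes
   its basin size. Basin boundaries form a multiplicatively weighted Voronoi
   diagram; the lowest point on each pairwise boundary is a **mountain pass**,
   the bottleneck for noise-driven transitions.

3. **Stochastic dynamics.** The state evolves by the reaction–diffusion
   system dx = (Ax + a(x))dt + dW on a 1-D domain, with A the diffusion
   operator (d₁∂²ξ, d₂∂²ξ), drift a(x) = −∇F̃ from a mollified (smoothed)
   landscape, and additive white or colored noise of magnitude σ₁ = σ₂ = σ
   (semi-implicit Euler–Maruyama). A zero-dimensional reduction
   d(u,v) = −∇F̃ dt + σ dW is the fast workhorse for exit-time statistics.

Analysis tools turn trajectories into basin-occupancy profiles, transition
events, polarization itineraries, first-exit-time summaries versus σ, and
pass-localization statistics (in the small-noise limit, log mean exit time ≈
2ΔF/σ² with ΔF the pass height, and crossings concentrate at the pass).

## Worked example

```r
library(polarscape)

net <- make_toy_network("toy3")
net
#> Boolean network with 3 nodes (synchronous update)
#>   A <- B
#>   B <- A
#>   C <- NOT A

atts <- label_attractors(find_attractors(net),
                         phenotype_rules(c(M1 = "A AND B", M2d = "C")))
atts
#> 3 attractor(s) over 8 states (exhaustive)
#>  attractor_id length state_sequence basin_size basin_fraction phenotype
#>             1      2        010;101          4           0.50        M0
#>             2      1            001          2           0.25       M2d
#>             3      1            110          2           0.25        M1
```

Half of all initial states fall into the 2-cycle (labelled M0 since no
compartment is steadily active); the two fixed points are an M1-like and an
M2d-like state with a quarter of the state space each.

The packaged 13-phenotype reference landscape reproduces the canonical
topology — five spatial clusters, only one of which (M1, M1M2d, plus M0 and
the M1 hybrid) is anti-tumoral — and its lowest barriers define the
polarization routes:

```r
rl <- make_reference_landscape()
find_passes(rl)[1, ]
#>  i j label_i label_j         u   v     height
#>  1 2      M1   M1M2d 0.6517622 1.5 0.04606352

st <- polarization_study(rl, mollifier(0.03), "M1", sigma = 0.27,
                         T = 150, replicates = 50, seed = 1)
st
#> Polarization study: start M1 , sigma 0.27 , 50 replicates, T = 150
#> first transitions:
#>       M1->M1M2d M1->M1M2bM2cM2d      M1->M2bM2d
#>              44               5               1
#> final basins:
#>      M2bM2d      M2aM2d   M2aM2bM2d         M2c ...
#>          23           8           5           3
```

At σ = 0.27 the M1 macrophage almost always escapes first into the hybrid
M1M2d well (its lowest pass, height 0.046) and then drifts through the
pro-tumoral clusters — noise alone polarizes it. At σ ≤ 0.1 the same
ensemble stays in the M1 basin for the whole horizon (see
`exit_time_study()`).

A thin command-line wrapper over the same functions is installed at
`inst/cli/polarscape` (subcommands `attractors`, `scan`, `landscape`,
`passes`, `simulate`, `analyze`, `exits`, `fixtures`).

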