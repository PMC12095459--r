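---
title: "Methods: Boolean attractors, epigenetic landscapes, and noise-induced polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean attractors, epigenetic landscapes, and noise-induced polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarscape)
```

`polarscape` models macrophage polarization in a tumor microenvironment
(TME) as stochastic motion on an epigenetic (Waddington) landscape derived
from a Boolean regulatory network. This vignette documents the model layer
by layer: the assumptions, the tunable parameters and their defaults, the
numerical choices, what the synthetic fixtures do and do not emulate, and
the known limitations.

## 1. Boolean network layer

**Model.** A network is an ordered list of nodes with one logical rule per
node over `AND`/`OR`/`NOT`. Updates are *synchronous and deterministic*:
every node evaluates its rule on the current state simultaneously. We chose
synchronous updating because it makes the attractor set well defined (fixed
points and cycles), basin sizes exact, and enumeration reproducible;
asynchronous schemes trade this determinism for update-order ensembles and
are out of scope. Sustained overexpression and knockout are modelled as
clamps: a clamped node ignores its rule and holds 0 or 1 at every step, and
enumeration then runs over the free nodes only, so basin fractions still
sum to one.

**Enumeration.** Exhaustive mode iterates all $2^k$ free-node states by
repeated squaring of the successor map (after $\lceil\log_2 2^k\rceil$
doublings every state has landed on its attractor cycle); it is capped at 24
free nodes to bound memory, beyond which sampled mode (vectorised Floyd
cycle detection from random initial states, seeded) estimates basin
fractions with binomial error $\sqrt{p(1-p)/n}$.

**Phenotype labels.** Attractors are labelled by compartment conditions
(M1, M2a, M2b, M2c, M2d) evaluated on a node-activity vector; active
compartments concatenate in fixed order, none means M0. For cyclic
attractors a node counts as active iff it is ON in *every* cycle state
(`activity = "all"`, the default) — the conservative reading, since a
transiently ON transcription factor is weak evidence of a stable program —
with `"any"` available as the permissive alternative. Cycles are stored in
a canonical rotation (lexicographically smallest state first) so attractor
identity is stable across runs. Labelling is total: unknown nodes in a
condition evaluate as inactive.

**Perturbation scans.** A scan recomputes the attractor set under each
clamp and compares pooled basin fractions per phenotype label against the
wild type: `disappeared` / `novel` for classes present only on one side,
otherwise `increased` / `decreased` by sign, with `minimal` below a 5 %
absolute percent-change threshold (the conventional "no visible change"
band in perturbation heat maps; configurable). Anti- versus pro-tumoral
pooling is driven by user-supplied label sets, since hybrid phenotypes can
be argued either way; the packaged convention counts labels containing M1
as anti-tumoral.

## 2. Landscape layer

**Embedding.** Attractors are reduced to 2-D coordinates with an exact
t-SNE (perplexity calibrated per point by bisection, gradient descent with
early exaggeration and momentum, seeded). At the item counts that occur
here (tens of attractors) the exact algorithm is the appropriate one; no
approximate-neighbor machinery is needed. Cyclic attractors enter as their
mean bit vector, which preserves the "average activity" the label is based
on. Per-phenotype centers are the centroid of that phenotype's attractor
coordinates.

**Potential.** The landscape is the minimum of per-phenotype paraboloids
$$F(u,v) = \min_i\, a_i\left[(u-u_i)^2 + (v-v_i)^2\right],$$
with steepness $a_i$ derived from the pooled basin fraction through a depth
rule. The default rule is proportional ($a_i = s\,f_i$): a phenotype with a
larger basin of attraction gets a steeper well, hence higher escape
barriers and longer residence — the landscape analogue of "large basins
capture". `inverse` and `log` rules are registered for sensitivity
analyses; the rule and scale are recorded in every landscape file. All well
bottoms sit at $F = 0$ (the form above has no per-basin depth offsets); a
rendering offset exists for plots only and never enters the dynamics.

**Mollification.** $F$ has gradient kinks on basin boundaries, so the drift
uses the mollified potential $\tilde F = F * \rho_\varepsilon$. The
convolution is evaluated by tensor quadrature — Gauss–Hermite for the
gaussian kernel, weighted Gauss–Legendre for the compactly supported bump —
which is *exact* wherever one paraboloid covers the kernel support: there
$\tilde F = F + 2a\varepsilon^2$ with unchanged gradient for the gaussian
kernel. Near boundaries the quadrature blends the adjacent paraboloid
gradients over a band of width $\sim\varepsilon$, which is precisely the
smoothing the drift needs; the residual $\sup|\tilde F - F|$ is
$O(\varepsilon)$ there. Defaults: gaussian kernel, 5 nodes per axis
(exact for quadratics from 2 nodes up), and
$\varepsilon = 0.05\times$ the bounding-box diagonal for generic use.
Reference-landscape studies set $\varepsilon = 0.03$ landscape units
explicitly, small against the minimum center spacing (0.34), so that
mollification perturbs barrier heights by
$2a\varepsilon^2 \lesssim 0.004$ — negligible against the smallest barrier
(0.046).

**Mountain passes.** The (i, j) boundary
$\{a_i r_i^2 = a_j r_j^2\}$ is an Apollonius circle (perpendicular bisector
for equal steepness). We parameterise it by the coordinate transverse to
the inter-center axis, where the branch formula
$x(y) = \bigl(-a_j D \pm \sqrt{a_i a_j D^2 - (a_i-a_j)^2 y^2}\bigr)/(a_i-a_j)$
remains well conditioned even when the circle degenerates to the bisector.
The unconstrained minimiser of $\max(F_i, F_j)$ is the on-segment point at
distance $D\sqrt{a_j}/(\sqrt{a_i}+\sqrt{a_j})$ from center $i$ (height
$D^2 a_i a_j/(\sqrt{a_i}+\sqrt{a_j})^2$); when a third basin owns that
point the constrained minimiser is found by dense probing of the owned arcs
plus 1-D refinement. Pairs with no owned boundary inside the bounding box
are not adjacent. Ties in point classification break toward the lowest
basin index.

**Clusters.** Basin centers are grouped by single-linkage hierarchical
clustering cut at the largest *relative* (log-scale) gap between
consecutive merge heights, so the rule is scale-free; a gap below ×1.5 is
read as a single cluster, and a fixed `k` can be forced.

## 3. Stochastic layer

The field $x(t,\xi) = (u, v)(t,\xi)$ on $[0, L]$ follows
$$dx = (Ax + a(x))\,dt + dW,$$
with $A = (d_1\partial_\xi^2, d_2\partial_\xi^2)$,
$a(x) = -\nabla\tilde F(u,v)$ applied pointwise, and additive noise of
magnitude $\sigma_1 = \sigma_2 = \sigma$ on two independent Wiener
processes.

Numerical choices, in order of consequence:

* **Semi-implicit Euler–Maruyama.** Diffusion is treated implicitly (one
  dense-factorised tridiagonal solve per component per step — stable for
  any $d\,\Delta t$), drift and noise explicitly. The explicit drift
  imposes $\Delta t \cdot 4\max_i a_i \le 1$, enforced as a configuration
  error rather than silent instability; non-finite values abort with the
  offending step.
* **Noise discretisation.** White space-time noise enters as i.i.d.
  $\mathcal N(0, \sigma^2\Delta t/\Delta\xi)$ per grid point per component
  (the standard cylindrical-Wiener grid scaling, which makes the $N = 1$,
  $L = 1$ field exactly the 0-D reduction). Colored noise is a truncated
  cosine expansion $\sigma\sqrt{\Delta t}\sum_k w_k\eta_k\phi_k(\xi)$ with
  $L^2$-orthonormal Neumann modes and configurable weights (default
  $w_k = 1/k$); a single mode gives rank-one spatially coherent forcing.
* **Boundary conditions.** Neumann (zero flux) by default — the natural
  choice for a closed tissue domain, and it conserves the spatial mean
  under pure diffusion, which the tests exploit — with periodic available.
* **0-D reduction.** $d(u,v) = -\nabla\tilde F\,dt + \sigma\,dW$ with the
  same drift code, run as a vectorised ensemble. In a single well of
  steepness $a$ the gaussian-mollified drift is exactly linear, so the
  stationary variance per component is the Ornstein–Uhlenbeck value
  $\sigma^2/(4a)$ — the main quantitative oracle for the integrator.
* **Determinism.** Every simulation consumes a caller-supplied seed through
  an RNG scope that restores the global state, so (config, seed) determines
  trajectories bit for bit on one platform.

## 4. Transition analysis

Occupancy is the fraction of grid points per basin at each snapshot (an
indicator in 0-D). The *dominant* basin must exceed a threshold (default
0.5); snapshots with no dominant basin are "mixed" and emit no events,
which debounces boundary flicker in field runs. A transition event is a
change of dominant basin between consecutive dominant snapshots; its
crossing point is the spatial mean field at the flip. First-exit times are
defined on the dominant-basin process so that 0-D and field analyses share
code; censored replicates (no exit before the horizon) are excluded from
the mean and reported separately, because the mean of a censored sample
would be biased low exactly where exits are rare. Exit-time studies default
to the 0-D reduction for tractable ensembles; the field mode is available.

Two asymptotic facts anchor the analysis and the test suite: for gradient
dynamics with additive noise, $\log$ mean exit time grows like
$2\Delta F/\sigma^2$ with $\Delta F$ the pass height
(Kramers/Freidlin–Wentzell), and transition paths concentrate at the
mountain pass as $\sigma \to 0$. The calibrated double well
(`make_double_well()`: steepness 4, separation 1, pass height 1) makes both
testable at desk scale: exit ensembles of 200–400 replicates at
$\sigma \in [0.55, 1.2]$, $\Delta t = 0.005$, horizon 2000 run in about a
minute each, and the fitted slope is compared at 25 % — the accuracy the
asymptotic regime at these $\sigma$ supports, since the prefactor is not
$\sigma$-free at finite noise.

## 5. The reference landscape fixture

The real polarization network and the exact geometry behind the published
landscape live in external data we deliberately do not depend on, so the
package ships a synthetic 13-basin reference landscape
(`make_reference_landscape()`) that encodes the *published topology*:
thirteen phenotypes in five spatial clusters, exactly one of them
anti-tumoral (M1 with M1M2d, plus M0 and the M1M2bM2cM2d hybrid, which
cannot sit in a pure-M2 cluster), four purely M2. Within that topology the
center spacings and steepness values were constructed, once, so that the
barrier ordering reproduces the canonical noise-induced polarization
routes: the lowest pass out of M1 leads to M1M2d (0.046) with the onward
route to the M2aM2d cluster next (≈0.1), the monocyte M0 sits at the edge
of the anti-tumoral cluster with its cheapest escape toward the
M2d/M2bM2d cluster (≈0.066), and M2bM2d is the widest well so that at
moderate noise it dominates the long-run occupancy. Intra-cluster spacing
(≤0.56) versus inter-cluster spacing (≥0.92) keeps the single-linkage gap
rule unambiguous at five clusters.

Under these frozen conditions the qualitative study grid is: confinement
sweep from M1 at $\sigma \in \{0.05, 0.1, 0.15, 0.2\}$ (200 replicates,
horizon 60), route studies at $\sigma = 0.27$ from M1 and $\sigma = 0.20$
from M0 (100 replicates, horizon 150, $\Delta t = 0.01$,
$\varepsilon = 0.03$). Ensemble sizes and horizons were chosen so each
study resolves its majority/monotonicity claim at roughly 3 Monte-Carlo
standard errors while remaining a desk-scale computation.

What the fixture does *not* emulate: the true embedding geometry (distances
between real phenotype centroids), real basin fractions, any per-basin
depth offsets, and any coupling between noise magnitude and TME composition.
Passing tests therefore certify the machinery — enumeration, landscape
construction, integrator, exit statistics — and the *qualitative* route
structure, not quantitative predictions about real macrophages.

## 6. Limitations

* Synchronous Boolean dynamics only; probabilistic/asynchronous updating
  and ODE network models are out of scope.
* The landscape is 2-D by construction (the embedding target); no 3-D or
  higher embeddings.
* Noise is additive and state-independent; multiplicative noise and control
  terms (therapy models acting on drift or diffusion) are not implemented.
* Exit-time asymptotics are used as scaling checks, not as rigorous
  large-deviations computations.
* Exhaustive enumeration is capped at 24 free nodes; larger networks must
  use sampled mode and inherit its binomial error.
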