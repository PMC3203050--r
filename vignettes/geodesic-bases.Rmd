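---
title: "Geodesic spatial bases for value learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geodesic spatial bases for value learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`navbasis` simulates how the spatial codes of the hippocampal formation —
place cells and entorhinal grid cells — could serve as basis functions for
reinforcement learning of a value function, and what geometry those codes
should have.  The central contrast is between *Euclidean* firing fields
(functions of straight-line distance, which generalize across walls) and
*geodesic* fields (functions of along-path distance on the environment's
transition graph, which generalize around walls).  This vignette documents
the models, the tunable parameters, the numerical choices, and what the
simulations can and cannot show.

## The learning model

The environment is a `width × height` gridworld.  States are cells; the
four cardinal moves are actions; walls are blocked edges between adjacent
cells; one absorbing goal cell carries reward $r = 1$ (all presets are
20 × 20, $M = 400$ states).  The agent learns the state value function

$$V(s) = E\left[\sum_t \gamma^t r(s_t) \mid s_0 = s\right]$$

as a linear combination of $N$ basis functions,
$\hat V(s) = \sum_i w_i \phi_i(s)$, by TD($\lambda$):

$$\delta_t = r_t + \gamma \hat V(s_{t+1}) - \hat V(s_t), \qquad
  e \leftarrow \gamma \lambda e + \phi(s_t), \qquad
  w \leftarrow w + \alpha \, \delta_t \, e.$$

Rewards follow the *visiting* convention: the reward of a state is credited
while the agent occupies it, so ordinary steps carry $r = 0$ and bootstrap
the successor's learned value, and arrival at the goal triggers one final
terminal update ($r = 1$, bootstrap $0$).  Under this convention the
dynamic-programming fixed point is $V^*(s) = \gamma^{d(s)} r$ with $d$ the
geodesic distance to the goal — the closed form `ground_truth_dp()` is
tested against.  Eligibility traces are accumulating and are reset at each
trial start (resetting between trials is a choice of this package, made
once and documented here).

Actions are chosen by softmax over one-step-lookahead values
$Q(s, a) = \hat V(\mathrm{next}(s, a))$ with unavailable actions excluded,
$P(a) \propto \exp(\beta Q(s,a))$.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$ | learning rate (fractional step, rows are unit-norm) | per condition | grid-searched; see below |
| $\lambda$ | trace decay | 0.9 | long credit assignment along trajectories |
| $\gamma$ | discount | $0.9^{d/c}$ | equal value range across worlds |
| $\beta$ | softmax inverse temperature | 80 | explore/exploit balance at value scale $\le 1$ |
| max steps | trial cap | 500 | bounds unsuccessful trials |

$\gamma$ scaling: $c$ is the world's maximum geodesic distance from any
(reachable) state to its goal, and $d = \min c$ over the six preset worlds
(here $d = 20$, $c$ ranging from 20 for the open field to 209 for the
hairpin maze), so $\gamma^c = 0.9^d$ is constant and every world spans the
same value range.  A world's characteristic distance could also be taken
as its graph diameter; we adopt the goal-distance reading and expose the
diameter rule as `discount_for_world(rule = "diameter")`.

Learning rates are calibrated per condition (world × basis family ×
metric) so that family comparisons are fair: `grid_search_alpha()` over the 21
point grid $\{0, 0.05, \dots, 1\}$, 50 runs × 50 trials per grid point,
paired seeds, objective = mean steps to termination.  The selected values
are frozen in `preset_alphas()`; re-running the search reproduces them.
One wrinkle: in conditions where learning *collapses* (Euclidean bases at
the narrow aperture) the objective is nearly flat in $\alpha$ and its
literal argmin is $\alpha = 0$, i.e. an agent that never updates; the
frozen preset uses the smallest positive grid point instead, since a zero
learning rate describes the absence of an agent rather than a calibrated
one (the qualitative orderings are unaffected — every positive $\alpha$
gives collapse-level performance there).

## Basis families

All bases are $M \times N$ matrices; after construction every row is
L2-normalized so that $\alpha$ has the same fractional-step meaning in
every state and family.  Rendering of firing-rate maps always uses the raw
(pre-normalization) activations.

* **Tabular** — the $M \times M$ identity; TD($\lambda$) over it is exactly
  classic tabular TD($\lambda$) (asserted to 1e-12 against an independent
  table-based oracle).
* **Place** — isotropic Gaussians at four scales, $\sigma$ = 0.25, 0.15,
  0.1, 0.075 of the environment extent, tiled on 5², 7², 10², 15² square
  lattices (25 + 49 + 100 + 225 functions, large to small), with
  half-spacing margins, plus one constant function: **400 columns**.
* **Grid** — sums of three cosine plane waves with wave-vector magnitude
  $f = 4\pi/(\lambda\sqrt{3})$ along directions $\theta + \pi/2$,
  $\theta - \pi/6$, $\theta + \pi/6$ and phases $p_1, p_2, p_3 = p_1 + p_2$;
  all combinations of 4 orientations (0, $\pi/12$, $\pi/6$, $\pi/4$),
  4 spacings ($4/(3n)$ extents, $n = 1..4$), and 25 phase pairs on a 5 × 5
  lattice over $[0, 2\pi)^2$, plus a constant: **401 columns**.  The
  non-negativity shift is 1.5, which we derive numerically: the minimum of
  $\cos a + \cos b + \cos(a+b)$ is $-1.5$, so activations span $[0, 4.5]$.
* The constant column has value 1 before normalization; any positive
  constant is equivalent after row normalization, so 1 is fixed for
  reproducibility.

Weights for all columns are learned independently; there is no weight
sharing.

## Geodesic transformation

For a given world, `geodesic_embedding()` computes all-pairs shortest-path
distances on the state adjacency graph (igraph's unweighted shortest
paths; a breadth-first-search oracle in the test suite checks them
exhaustively on small worlds).  Disconnected pairs, which would have
infinite distance and make MDS inestimable, are capped at their Euclidean
cell-center distances, with a mask recording the replacements.  The capped
matrix is embedded in 2-D by iterative MDS under Sammon's stress

$$S = \frac{\sum_{i<j} (d_{ij} - \delta_{ij})^2 / \delta_{ij}}
           {\sum_{i<j} \delta_{ij}},$$

started from the classical (Torgerson) scaling solution and run through
`MASS::sammon` (stop at relative stress change $< 10^{-6}$ or 500
iterations; stopping settings are this package's own choices).  The seed only perturbs
degenerate starts (e.g. exactly collinear classical solutions); given seed
and options the embedding is deterministic, and it is computed once per
environment and cached — a static basis set.

Numerical notes, decided here and tested:

* The 4-neighbor geodesic metric of an *open* field is the city-block (L1)
  metric, which is not exactly Euclidean-embeddable in 2-D.  Open-field
  "no difference between metrics" claims are therefore stated as
  correlations (distance correlation ≥ 0.95; per-column field correlation
  ≥ 0.9), not equalities.  In practice the 10 × 10 open-field embedding
  sits within a few hundredths of a state of the true lattice.
* The embedded configuration is aligned to the cell-center frame by
  Procrustes rotation/translation/reflection plus a single global scale
  (`vegan::procrustes`).  None of these affect relative geometry — basis
  scales are fractions of the *embedded* extent, so a global rescale
  cancels — but alignment keeps centers and phases comparable across
  metrics and lets fields be drawn in the original frame.
* Basis scale units: $\sigma$ and $\lambda$ are fractions of the
  environment extent; for Euclidean coordinates the extent is
  `max(width, height)`, for an embedding it is the larger side of the
  embedded bounding box plus one cell, because embeddings of obstructed
  worlds stretch.  Center positions and phases are shared verbatim between
  the metrics: identical per-column parameters, different coordinates.

## Experiments and what they show

`run_experiment()` trains `n_runs` independent agents (default 500 — small
enough to run in seconds, large enough for CI-separated orderings; every
problem size used is stated)
for 50 trials from uniformly random starts in the goal's connected
component, and reports per-trial mean steps-to-goal with 95%
normal-approximation confidence intervals; ordering claims compare per-run
means over a stated trial window with non-overlapping CIs.  The compiled
training loop is arithmetic-identical to the exported `run_trial()`
reference (asserted bit-for-bit in the tests).

The qualitative findings the test-suite asserts, each on its fixture:

* **Simple barrier**: Euclidean place and grid bases learn much faster
  than tabular TD — long-range spatial generalization helps.
* **Narrow aperture**: Euclidean bases collapse (worse than tabular) where
  the value function is discontinuous across a thin wall; their geodesic
  counterparts learn at least as fast as the tabular control.
* **Wall bleed**: after near-asymptotic training (100 runs × 200 trials;
  at short training both metrics share a transient positive offset from
  under-convergence, while the Euclidean smear is the component that
  *persists* at asymptote), Euclidean place value maps overrepresent value
  on the goal-far side of the barrier (positive mean signed error over
  wall-adjacent cells) and underrepresent it on the near side; geodesic
  maps cut the far-side error at least in half.
* **Field predictions**: a geodesic place field bisected by a new wall
  loses more than half its peak rate (the "disappearance" threshold 0.5 is
  our convention — the phenomenon is reported qualitatively); a field far
  from the wall changes by under 10%; some fields *gain* rate when
  distortion pushes coordinates into previously empty regions, and
  suppressed fields concentrate near the changed wall; hairpin grid fields
  track along arms rather than across walls.

The fixture layouts approximate enclosures that appear in the experimental
literature only as figures (open field, barrier worlds, two rooms joined
by a corridor, a bisecting barrier, a hairpin maze); all quantitative
checks are therefore orderings, correlations and ratios on these frozen
fixtures — none claim to reproduce any particular laboratory enclosure's numbers.

## Limitations

The synthetic worlds have deterministic transitions, a single static goal,
thin walls and no sensory noise; the generator emulates task *geometry*,
not rat behavior.  Passing tests show the geometric mechanism — geodesic
generalization rescues learning near obstacles and predicts field
distortions — not that biological place/grid fields are numerically
Gaussian or three-cosine.  The model does not capture repetitive place
fields in hairpin mazes, directional firing on tracks, or how geodesic
representations would be constructed upstream from sensory input; those
are out of scope by design.
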