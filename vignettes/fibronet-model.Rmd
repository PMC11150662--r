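---
title: "Stretch, stiffness and self-healing: the fibronet model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stretch, stiffness and self-healing: the fibronet model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibronet)
```

## The model

Pulmonary fibrosis progresses, or resolves, through the behaviour of
fibroblasts and myofibroblasts, which are mechanosensitive: they read both
the *stiffness* of the matrix they crawl on (through integrin engagement)
and the *stretch* it carries (through stretch-gated channels and
strain-mediated release of latent TGF-β).  fibronet models lung parenchyma
as a prestressed two-dimensional network of Hookean springs and the cell
population as discrete agents walking randomly over it.  Each spring has a
cross-sectional area $A$; with a uniform Young's modulus $E$ and a
cell-scale perceived rest length $L_0$, its stiffness $K = EA/L_0$ varies
only through $A$, so $A$ is the single remodeling variable.

An agent crossing a spring receives two saturating (Hill) signals,

$$a_K = \frac{(A/A_t)^\beta}{(A/A_t)^\beta + 1}, \qquad
  a_\varepsilon = \frac{(\varepsilon/\varepsilon_s)^\gamma}
                       {(\varepsilon/\varepsilon_s)^\gamma + 1},$$

where $A_t$ is the fibrotic threshold area, $\varepsilon_s$ the target
(homeostatic) strain, and $\beta = 3$, $\gamma = 1$ set the steepnesses.
The signals combine into a signed activation with memory $r$:

$$a \leftarrow a(1-r) + r\,(w_1 a_\varepsilon + w_2 a_K - c), \qquad
  c = \tfrac{w_1}{2} + w_2\,\frac{(A_0/A_t)^\beta}{(A_0/A_t)^\beta+1},$$

so that $a = 0$ exactly at homeostasis ($\varepsilon = \varepsilon_s$,
$A = A_0$); with $A_0 \ll A_t$, $c \approx 0.5$.  Positive activation
deposits matrix on the crossed spring ($A \leftarrow A + P a$ per
crossing), negative activation digests it; a spring digested to $A \le 0$
ruptures irreversibly.  Strain supplies negative feedback (an over-stiff
spring carries less strain, silencing the strain signal and triggering
digestion) and stiffness supplies positive feedback (deposition raises
$a_K$, which drives more deposition); which one wins sets the outcome.

In the lumped single-element reduction the spring hangs under a constant
external force, so strain is slaved to area as
$\varepsilon = \varepsilon_s A_0 / A$, and agent density follows

$$D \leftarrow D + p_1 \tfrac{n}{s} + p_3(a)\,D\,(1 - D/D_{max})
    - p_2(a)\,D,$$

with constant influx, logistic proliferation and activation-dependent
apoptosis (below).

## Parameters

| symbol | meaning | default |
|---|---|---|
| `w1` | strain-signal weight | 1 |
| `w2` | stiffness-signal weight (fibrosis predisposition) | 1–3 |
| `A0`, `At` | initial / threshold cross-sectional area | 1, 10 |
| `eps0`, `eps_s` | prestrain / target strain | 1, 1 |
| `gamma`, `beta` | Hill steepness (strain, stiffness) | 1, 3 |
| `r` | agent activation memory | 0.5 |
| `P` | deposition/digestion scale | 0.2 |
| `p1` | per-node agent appearance probability | 0.01 |
| `p3_max` | division probability scale | 0.02 |
| `D0`, `Dmax` | initial / maximal density (agents per spring) | 0.3, 3 |
| `E` | Young's modulus (uniform) | 1 |

All quantities are dimensionless; one iteration corresponds to one
spring-crossing per agent.  `model_params()` derives and caches `c` and
the maximal fibrotic activation `a_fib = w2 - c` (the limit of an
infinitely stiff, strain-free spring).

### Population rates: a closed pair of fixed points

The density equation must hold two states: homeostasis
($a = 0$, $D = D_0$) and full fibrosis ($a = a_{fib}$, $D = D_{max}$,
"activated myofibroblasts resist apoptosis").  We take

* division ramping linearly with activation,
  $p_3(a) = p_{3,max}\,\mathrm{clip}(a, 0, a_{fib})/a_{fib}$, with a
  logistic crowding factor $(1 - D/D_{max})$;
* apoptosis declining over the same ramp,
  $p_2(a) = p_{2,0}\,[1 - (1 - D_0/D_{max})\,
  \mathrm{clip}(a, 0, a_{fib})/a_{fib}]$, with the baseline
  $p_{2,0} = p_1 (n/s) / D_0$ fixed by the homeostatic balance.

With these forms both fixed points are *exact*: at $a=0$ influx
$p_1 n/s$ equals death $p_{2,0} D_0$, and at $a = a_{fib}$, $D = D_{max}$
the crowding factor kills proliferation while the reduced death rate
$p_{2,0} D_0/D_{max}$ exactly absorbs the influx.  A constant $p_2$
cannot do this: with $p_{3,max} = 0.02 < p_{2,0} \approx 0.022$,
proliferation would never outrun death and the fibrotic density plateau
would not exist.  Note that $a_{fib} \to 0$ as $w_2 \to c \approx 0.5$;
the ramps divide by $a_{fib}$, which is the divide-by-zero instability at
the critical weight, and for $w_2 \le c$ both ramps are defined as zero
(fibrotic proliferation impossible).  In the network model the ratio
$n/s$ is frozen at its initial value (a biological constant of the
tissue, not something apoptosis should track as springs rupture).

## The bifurcation in the single element

For a stiffening insult $A \mapsto m A_0$ the activation along the
constant-force curve is
$f(A) = w_1/(1+A) + w_2 a_K(A) - c$ (at defaults).  $f$ vanishes at
$A_0$, dips negative (healing basin), and for large enough $w_2$ rises
through zero again at the *fibrotic threshold*: beyond it deposition is
self-sustaining, $A$ grows without limit, $\varepsilon \to 0$, and $D$
climbs to $D_{max}$.  `find_fibrotic_threshold()` locates this critical
multiplier by a geometric scan plus bisection; it decreases strictly as
`w2` grows (a more stiffness-sensitive subject needs a smaller insult).
`find_critical_weight()` bisects `w2` itself on "any fibrotic outcome
exists" and lands just above $w_1/2$, the closed-form boundary at which
the runaway activation $w_2 - c$ changes sign.

Two honest subtleties, both visible in the test suite:

* **A saturating fibrotic branch below the closed-form boundary.**  The
  closed-form condition $w_2 > w_1/2$ considers only the runaway limit.
  Because the strain signal decays like $1/A$ while the stiffness
  deficit $w_2(1 - a_K)$ decays like $1/A^3$, there is a narrow window of
  weights just below $0.5$ (e.g. $w_2 = 0.49$ at defaults) where $f > 0$
  on a *middle* interval of areas: insults landing there converge to a stable
  elevated-area state — fibrosis that saturates rather than runs away.
  `find_fibrotic_threshold()` keeps the conventional sentinel
  (`Inf` for $w_2 \le w_1/2$) so the reported critical weight is the
  runaway boundary, and a characterization test documents the
  saturating branch.
* **Outcome trend rules.**  Because $\Delta A = P D a$ is additive, a
  large insult being digested back takes $O(A/PD|a|)$ iterations; at the
  2000-iteration horizon it may not yet be inside the homeostasis
  tolerance.  `classify_outcome()` therefore also accepts "strictly
  decreasing toward $A_0$ with $a < 0$" as healing (the healing basin is
  monotone), and requires growth *above the post-injury starting area*
  before the divergence cap reads fibrotic.

## Network mechanics

Networks are Voronoi tessellations of Poisson-disk (Bridson) point
samples on a unit square — blue-noise geometry whose interior vertices
have degree 3, a reasonable idealization of alveolar septa — with the
honeycomb lattice as a deterministic fixture.  The default domain
(`side = 1`, `radius = 0.07`) yields ≈350–500 springs, the desk scale at
which every behavioural claim is exercised; both knobs are exposed.
Generation, prestress and boundary handling follow this pipeline:

1. every spring gets $L_0 = L/(1+\varepsilon_0)$, i.e. uniform prestrain
   (`eps0 = 1`, inflated parenchyma);
2. interior nodes are relaxed with the boundary pinned (a uniform-strain
   Voronoi configuration is not an interior force balance — vertex stars
   are not 120°);
3. the boundary reaction forces are frozen
   (`compute_boundary_forces()`), after which the whole configuration is
   an exact equilibrium of its own reactions.  Constant boundary forces
   (rather than fixed positions) let the network *contract* as fibrosis
   stiffens it.

Equilibria are found by `equilibrate()`: the default engine is a
Newton–Krylov relaxation (matrix-free conjugate gradients on the
per-spring Hessian blocks $k\,\hat u \hat u^T + (t/L)(I - \hat u\hat
u^T)$, with a backtracking line search and early exit on negative
curvature under compression), which converges in a handful of steps from
the warm starts a running simulation provides; FIRE inertial descent is
the fallback, and a greedy random-displacement schedule with shrinking
steps (`mode = "anneal"`) is retained as a fidelity check — both engines
must land on the same energy to $10^{-4}$ relative on fixtures.
Compressed springs carry force by the same Hookean law (no slack or
buckling model).  If rupture removes a loaded boundary node, the
remaining boundary forces are re-centred to zero sum; otherwise the
energy would be unbounded under translation and no equilibrium would
exist.

Whole-network stiffness is measured as a tissue strip would be: five
accumulating isotropic boundary stretches of 2% about the boundary
centroid, interior re-equilibrated with the boundary pinned, total spring
energy fit against cumulative strain with a quadratic — the quadratic
coefficient is the stiffness, and runs report it normalized by its
iteration-0 (pre-injury) value.  Isotropic rather than uniaxial stretch
is a declared choice (`stiffness_assay()` exposes the step schedule).

## Agents on the network

Each iteration: every agent picks a uniformly random incident spring
(migration is deliberately unbiased — no durotaxis), crosses it, updates
its activation from that spring's $K$ and $\varepsilon$, and deposits
$\Delta A = P a$ on it.  Density acts through the *number of crossings*,
so the per-crossing increment carries no explicit $D$ factor; the
mean-field recovery of the density equation is a Monte-Carlo test.
Compressive strains (possible in a heterogeneous network, impossible in
the lumped element) contribute zero strain activation.  Then ruptured
springs, isolated springs and stranded agents are pruned; nodes spawn new
unactivated agents with probability $p_1$; agents die (activation-
dependent, death evaluated first) and divide (logistic crowding,
unactivated daughter on the same node); and the network re-equilibrates
from a warm start.  A single `set.seed()` governs the entire run — the
draw order (migration picks, births, deaths, divisions; agents in id
order) is fixed, so equal seeds give bit-identical metrics.

## Experiments and study conditions

`injury_spec(fraction, multiplier)` scatters a single insult uniformly
over springs (a clustered-patch option exists, off by default).
`run_simulation()` records per iteration: density, percent ruptured
springs (relative to the initial count, non-decreasing), mean |a|,
convex-hull network area, and the normalized stiffness (assayed every
`assay_stride = 50` iterations; curves are step functions between
assays).  Iteration 0 is the pre-injury state, so normalized stiffness
starts at exactly 1 and healing reads as a return toward 1.

A run's outcome is read from its stiffness trajectory, the way replicate
stiffness plots are read: *healing* when the final normalized stiffness
is inside [0.8, 1.2] and not climbing, *fibrotic* when it exceeds 2 or is
strictly climbing out of the band at the end.  A "trend" requires both
monotonicity over the assay tail and a >2% rise, so assay jitter around a
stationary value is not read as progression.  Agent activation is
deliberately *not* folded into the outcome: a healed network can retain a
small activated focus, and activation is reported separately (mean |a|,
histograms, per-node accumulation maps — the α-SMA proxy).

Demonstration conditions used by the behavioural test suite, chosen from
the model's own structure:

* homeostasis: no injury, `w2 = 1`, 150–500 iterations — stiffness stays
  within a few percent of 1, no rupture;
* softening heals: 20% of springs × 0.5, `w2 ∈ {1, 2, 3}`, 500
  iterations, 5 replicates each;
* progression: 10% × 10 at `w2 = 3` — stiffness climbs monotonically,
  density rises toward `Dmax`;
* bifurcation: 20% × 5 at `w2 = 2.3`, 2000 iterations, 20 seeds.  The
  single-element threshold at `w2 = 2.3` is ≈5.7, so the insult sits
  *below* it (ratio ≈0.9) — the regime where network effects, not the
  lumped equations, decide the outcome: some replicates heal, others
  turn fibrotic.  At the threshold-matching weight (`w2 ≈ 3.0` for a ×5
  insult) every replicate progresses; at `w2 ≤ 2` every one heals.

Replicate studies default to 9 networks per condition, mirroring the
study design this model family uses; significance testing across
conditions is intentionally out of scope (distributions are exported as
tidy CSV).

## What the generator does and does not emulate

The synthetic networks reproduce the geometric disorder, prestress and
constant-force boundary of parenchymal tissue, and the emergent
behaviours tested on them (self-healing, runaway stiffening, rupture
voids, contraction, agent differentiation) arise from the same rules a
real tissue's cells are hypothesized to follow.  They do not include
airways, three-dimensional septal geometry, nonlinear (strain-stiffening)
fiber laws, explicit cyclic stretch (static strain approximates it),
inflammatory or epithelial cell types, or measured parenchymal
dimensions — so green tests show the mechanism is sufficient to generate
the phenotypes, not that the parameters are calibrated to human lung.

## Numerical choices

* Equilibrium tolerance $10^{-6}$ (in units of the homeostatic tension
  $E A_0$) during runs; $10^{-9}$–$10^{-12}$ in oracle tests.
* Bisections (injury threshold, critical weight) to $10^{-3}$; injury
  scans geometric with ratio 1.1 up to $100 A_t/A_0$.
* Outcome tolerances for the element: $|A - A_0| < 0.01 A_0$ and
  $|a| < 10^{-3}$, well separated from both fixed points.
* Divergence cap $10 A_t$; area overflow truncates a trajectory as
  fibrotic.
* Degenerate inputs: negative areas/strains are domain errors; a spring
  of zero length contributes no force direction; an element digested to
  $A \le 0$ is classified "unstable"; a fully disintegrated network ends
  its run early.
* Voronoi construction contracts edges shorter than $10^{-6}$ of the
  domain side and keeps the largest connected component.

## Worked example

```{r element, eval = FALSE}
p <- model_params(w2 = 2)
find_fibrotic_threshold(p)        # ~6.03: insults above this never heal
tr <- simulate_element(p, injury_multiplier = 8)
attr(tr, "outcome")               # "fibrotic"

run <- run_simulation(model_params(w2 = 3), injury_spec(0.1, 10),
                      n_iterations = 500, seed = 3)
run                               # fibrotic; stiffness climbing
render_histology(run$final_net, "fibrotic.png")
```

## Known limitations

Two-dimensional, linear springs, uniform modulus, static strain, one
agent type, unbiased migration.  The per-crossing deposition constant and
the population rates were fixed by qualitative behaviour (both fixed
points, finite carrying capacity, the instability at the critical
weight), not fit to data, so lumped-element trajectories should be read
qualitatively.  The percent-ruptured and contraction phenotypes are
emergent and stochastic; they are asserted as trends over replicates,
not as point values.
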