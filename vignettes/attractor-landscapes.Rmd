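---
title: "Attractor landscapes of endogenous networks: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor landscapes of endogenous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endonet)
```

## The model and its assumptions

`endonet` treats a cell's core regulatory machinery as a closed signed
network: nodes are genes, pathways or cellular functions with normalized
activities $x_i \in [0,1]$, and directed edges are activations or
inhibitions. The dynamics are a coarse-grained rate equation per node,

$$\frac{dx_i}{dt} = f_i(x) - x_i,$$

with first-order self-degradation setting the unit of time and a Hill-type
generation rate bounded by 1. Writing $u_j = (x_j/a_j)^{n_j}$ for each
activator of node $i$ and $v_k = (x_k/a_k)^{n_k}$ for each inhibitor, the
default composition pools activators into one saturating term and
inhibitors into one repressive term:

$$f_i = \frac{\sum_j u_j}{1 + \sum_j u_j} \cdot \frac{1}{1 + \sum_k v_k}.$$

A single activator reduces to the familiar $x^n/(a^n + x^n)$ and a single
inhibitor to $a^n/(a^n + x^n)$; the two are complementary (they sum to 1
at matched input and parameters) and both cross $1/2$ exactly at $x = a$.
A node with inhibitors but no activators has activation part 1 — absent
repression it produces at full rate — and a node with no regulators decays
to 0. These conventions make the unit box forward invariant
($f_i \ge 0$ at $x_i = 0$ and $f_i \le 1$ at $x_i = 1$), so trajectories
never leave the biologically meaningful region.

The composition rule is deliberately pluggable: `hill_params(rate_law =
"hill_product")` switches to an independent per-edge form (activators
combined as $1 - \prod_j (1 - u_j/(1+u_j))$, inhibitors as a product of
repressive terms). Re-running an analysis under the alternative form is
the standard sensitivity check that conclusions reflect network structure
rather than one algebraic choice; the toggle fixture keeps its bistability
under both forms.

Assumptions worth stating plainly: activities are deterministic (no
intrinsic noise, hence no stochastic transition rates or potential
landscape), interactions are time-invariant, and all regulation acts
through the two monotone Hill shapes. Saddle-mediated adjacency is a
statement about the deterministic flow, not about transition probabilities.

## Parameters

* `n` (Hill coefficient, dimensionless, default **3**): steepness of the
  regulatory response. Values below ~2 make switches shallow enough that
  multistability is easily lost; values above ~6 approach step functions
  and stiffen the ODEs.
* `a` (threshold, default **0.5**): the input activity at which a single
  interaction is half-active. On the normalized $[0,1]$ scale with the
  $>0.5$ activity convention, the midpoint is the natural default.
* Per-edge values may be stored on the network's edges (TSV dialect:
  `EDGE src tgt + n a`) or drawn by `resample_parameters()`; either
  overrides the global default edge by edge.
* Degradation rates are fixed at 1 by the normalization: time is measured
  in degradation half-life units, so a "duration 50" clamp means fifty
  decay timescales — deep relaxation for every transient.

## Fixed-point search and classification

Attractors are found by relaxation: `sample_attractors()` integrates from
uniform random initial states (`lsoda`, rtol $10^{-8}$, atol $10^{-10}$,
chosen because large `n` makes the flow locally stiff near thresholds)
until the max-norm of the right-hand side drops below $10^{-6}$, with a
relaxation cap of 100 time units. Endpoints are polished by a damped
Newton iteration with backtracking on the residual norm and every iterate
projected into the unit box, then deduplicated greedily at max-norm radius
$10^{-3}$ — far below the spacing between the near-binary attractor
profiles this model produces, and far above integrator noise. Saddles and
other unstable points are sought by the same Newton polish started from
fresh random seeds and from midpoints between attractor pairs, because a
saddle separating two basins lies between them on the connecting segment
(the toggle fixture's saddle sits exactly at the midpoint by symmetry).

Classification uses the Jacobian spectrum (analytic, verified against
central differences at $10^{-6}$): index 0 is an attractor, index 1 a
saddle, index $\ge 2$ unstable. Eigenvalues with $|\mathrm{Re}\,\lambda| <
10^{-6}$ flag the point as degenerate rather than force a class; such
points are reported but excluded from censuses. The search is sampled,
not certified — coverage grows with `n_starts` and `n_seeds`, and the
suite asserts monotone completeness (more starts never lose an attractor)
rather than global enumeration.

The transition graph displaces each non-attractor by $\varepsilon =
10^{-3}$ (above dedup radius, far below basin scale) along every unstable
eigendirection, relaxes, and matches endpoints to attractors within the
dedup radius; complex pairs are displaced along real and imaginary parts
separately. Attractor adjacency is derived from saddles only — index-1
points are the generic "passes" — while higher-index points appear in the
graph but not in route derivation. Routes between attractors are simple
paths in that adjacency, shortest first, lexicographic on ties.

## Boolean cross-validation

The synchronous Boolean analogue sets a node to 1 iff its activation
condition holds (any activator on; vacuously true when the node has
inhibitors but no activators, mirroring the continuous law's unopposed
production) and no inhibitor is on; input-free nodes go to 0. Up to 20
nodes the whole $2^N$ state space is enumerated exactly (bit-coded
successor table plus pointer doubling); larger networks fall back to
sampled trajectories with cycle detection. The consistency check asserts
that every continuous attractor's $>0.5$ profile recurs under the Boolean
map. This holds for all of the package's designed fixtures. It is *not* a
theorem: randomly wired networks routinely produce continuous attractors
with mid-range activities whose discretizations are not Boolean-recurrent,
which is why the cross-validation is asserted on the designed fixture
family and offered as a diagnostic (`on_boolean_attractor()`) for user
networks.

## Perturbation protocols

A clamp sets the chosen coordinates to their clamp values and holds them
(zero derivative) for the stage duration; release lets the network relax
to convergence before the next stage, matching staged induced-switching
protocols in which each intervention completes its relaxation. Screens
restrict clamp levels to $\{0,1\}$ — full suppression or activation — and
search size-ascending in lexicographic node order, so results are
reproducible and the first reported sets are minimal.

One subtlety the toggle makes vivid: a *full* clamp of a two-node switch
moves the state across the basin boundary instantly, so the outcome does
not depend on dwell time. Dwell-time dependence appears for sub-maximal
clamps (e.g. holding `B` at 0.6: 0.01 time units relaxes back, 50 units
switches) and for indirect interventions that need time to propagate.
The default stage duration of 50 time units guarantees effectively
complete relaxation either way.

## Robustness analysis

`recurrence_statistics()` redraws independent per-edge $(n_i, a_i)$
uniformly over configurable ranges (defaults $n \in [2,5]$, $a \in
[0.3,0.7]$), re-runs the attractor search, and matches reference
attractors primarily by identity of the discretized profile — parameter
changes move attractor coordinates continuously, but phenotype identity is
the on/off pattern — with a max-norm fallback for near matches.

A quantitative caveat established with an independent nullcline-composition
oracle: for the two-node toggle, bistability does **not** persist over the
whole default range. When both edges draw shallow, high-threshold
parameters (around $n = 2$, $a = 0.7$) the composed inhibition map's
maximal slope falls below 1 and only one fixed point survives; at the
package's reference seed 13 of 50 draws are monostable, an intrinsic
property of the sampled dynamics rather than a search failure — in every
draw the search finds exactly the attractors the oracle certifies. The
robustness tests therefore assert perfect search/oracle agreement per
resample, full recurrence on the oracle-certified-bistable draws and under
collapsed ranges, and monotone non-increase of recurrence as ranges widen.

## Synthetic fixtures: what they do and do not show

The generators provide networks whose complete answer is computable by
brute force, so every stage of the pipeline is tested against an
independent oracle with no external data:

* `make_self_activator()` — 1-D; fixed points from a sign-change scan of
  $x^n/(a^n+x^n) - x$ (three roots at defaults: $0$, $a$, $(1+\sqrt5)/4$).
* `make_toggle_switch()` — 2-D mutual inhibition; fixed points from the
  composed nullcline map, phase-plane basins, brute-force clamp screens.
* `make_inhibition_ring()` — a ring whose continuous flow spirals into the
  symmetric point while the Boolean map cycles (periods 2 and 6).
* `make_miniature_fate_network()` — a frozen 10-node caricature (two
  self-activating, mutually suppressing fate hubs with downstream modules,
  an apoptosis–survival toggle, a cycle node) with four attractors whose
  profiles are disjoint; its wiring is versioned in
  `inst/extdata/mini_fate_network.tsv` so test censuses stay frozen.
* `make_random_signed_network()` — smoke tests: valid wiring, reproducible
  from seed, at least one attractor (every node keeps an in-edge by
  default so no coordinate is trivially decoupled).
* `generate_expression_table()` — corrupts the true differential calls of
  an attractor pair at a flip rate $\varphi$; since agreement conditional
  on a non-flat observation is Bernoulli with $p =
  (1-\varphi)/(1-\varphi/2)$, mean concordance recovery has a closed form
  the tests check to three standard errors.

What passing these tests shows: the numerics (integration, refinement,
classification, graph construction, screening, matching) are correct on
systems where the truth is enumerable. What they do not show: that any
particular biological network has a given census. Real curated networks
are far from random — their feedback structure is what produces clean,
near-binary multistability — and transcription of a published wiring (the
81-node leukemia network is the motivating case; see `load_apl_network()`)
is required before the package can reproduce a published census. Problem
sizes used throughout the suite (hundreds of random starts on $\le 10$
node fixtures, $10^3$ box-invariance integrations on 20-node random
networks, 50 parameter resamples) were chosen as the smallest scales at
which every sampled census is already stable under doubling.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold appears ($>0.5$ activity,
  $>$`threshold` sub-network membership): a node exactly at threshold is
  inactive, so profiles are well-defined at the symmetric fixed points
  this model produces exactly at 0.5.
* States are clipped to the unit box inside the rate law, so non-integer
  Hill exponents never see a (numerically) negative base and the flow
  outside the box points back in.
* Ties in the perturbation screen and route search are broken
  lexicographically; dedup is greedy in input order — all outputs are
  deterministic given the seed.
* Empty networks are rejected at construction; a network with no edges is
  legal and decays to the origin (its Jacobian is $-I$ exactly).
* Newton refinement failure (singular step, no backtracking progress)
  raises an error carrying the best iterate rather than returning a
  spurious point; non-converged relaxations are tallied in the attractor
  set's metadata, never silently dropped.

## Known limitations

Sampled coverage can miss small-basin attractors and, more often,
higher-index unstable points; escape endpoints that match no known
attractor are recorded as novel rather than resolved; there is no
stochastic extension (transition rates, potential landscape) and no
parameter fitting to data. The concordance machinery deliberately takes
pre-discretized up/down/flat call tables — raw expression preprocessing is
out of scope.
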