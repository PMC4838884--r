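# endonet

Attractor-landscape analysis of endogenous molecular-cellular networks.

## The scientific problem

A cell type is not defined by any single gene but by the collective state of
a closed regulatory network of core genes, signalling pathways and cellular
functions — an *endogenous network* with no designated input or output.
When such a signed activation/inhibition network is modelled as a dynamical
system, its stable states (attractors) correspond to robust phenotypes:
proliferating, differentiated, apoptotic, or disease states such as a
leukemic expression program. Saddle points — fixed points with exactly one
unstable direction — are the "mountain passes" between neighbouring
attractors, and clamping a few node activities (the model analogue of drugs
or genetic intervention) can push a cell across a pass from one phenotype to
another. That is the dynamical-systems picture behind differentiation
therapy: the disease state is an attractor, and therapy is an induced
transition out of its basin.

`endonet` implements this entire analysis for arbitrary signed interaction
networks: compiling the wiring into normalized Hill-type ODE and Boolean
dynamics, enumerating and classifying fixed points, mapping the
saddle-mediated transition graph, simulating clamp-and-release switching
protocols, screening for minimal switching interventions, and quantifying
attractor robustness under random parameter resampling.

## The model

Each node activity `x_i` is normalized to `[0, 1]` and evolves in units of
the degradation timescale:

    dx_i/dt = f_i(x) - x_i

with a Hill-type generation rate composed from the node's regulators
(coefficient `n` sets steepness, threshold `a` the half-activity input;
defaults `n = 3`, `a = 0.5`):

    f_i = [ Σ_j u_j / (1 + Σ_j u_j) ] * [ 1 / (1 + Σ_k v_k) ],
    u_j = (x_j / a_j)^(n_j)  over activators j,
    v_k = (x_k / a_k)^(n_k)  over inhibitors k

A single activator reduces to `x^n / (a^n + x^n)` and a single inhibitor to
`a^n / (a^n + x^n)`. Because `f_i` takes values in `[0, 1]`, the unit box
is forward invariant. Fixed points solve `f(x) = x`; the Jacobian spectrum
classifies them (index 0 attractor, index 1 saddle, index ≥ 2 unstable).
A synchronous Boolean analogue (activators OR-combined, inhibitors veto)
cross-validates every continuous attractor's >0.5-discretized profile.

## Worked example

```r
library(endonet)

net <- make_toggle_switch()            # A -| B, B -| A
fit <- attractor_landscape(net, n_starts = 200, seed = 1)
fit
#> Attractor landscape of a network with 2 nodes
#>   2 attractor(s), 1 saddle(s), 0 other unstable, 0 degenerate
#>   1 saddle-mediated attractor adjacencies

coef(fit)                              # attractor coordinates
#>            A         B
#> A1 0.9880663 0.1147184
#> A2 0.1147184 0.9880663

print(fit$fixed_points)
#> Fixed-point census: 2 attractor(s), 1 saddle(s), 0 unstable, 0 degenerate
#>   F1  attractor index 0  [0.115 0.988]
#>   F2  attractor index 0  [0.988 0.115]
#>   F3  saddle    index 1  [0.5 0.5]
```

The two attractors are the A-high and B-high expression programs; the
saddle at exactly `(0.5, 0.5)` is the pass between them. An induced switch
clamps one node and releases:

```r
att <- fit$attractors
switch_experiment(net, hill_params(), "A2", c(A = 1), attractors = att)
#> Induced switch: A2 -> A1

perturbation_screen(net, hill_params(), "A2", "A1",
                    max_set_size = 1, attractors = att)
#> [[1]]  A = 1
#> [[2]]  B = 0
```

so either fully activating `A` or fully suppressing `B` for one dwell
period is a minimal switching intervention — the toy version of a
therapeutic-target screen. The same verbs run unchanged on the bundled
10-node miniature fate network (`make_miniature_fate_network()`: two fate
programs, an apoptosis toggle, four attractors) and on any user network in
the TSV/JSON dialects read by `read_network()`.

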