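# prognet

Cancer prognosis prediction when the patient's regulatory network is
uncertain.

`prognet` is for computational biologists studying how far a single
molecular snapshot of a patient can be pushed when the *identity* of the
patient's aberrant gene regulatory network is unknown. It models gene
regulation as a Boolean network with perturbation (BNp), treats cancer
progression as a set of possible mutations of a known healthy network,
computes the best possible drug-style intervention for every candidate
network, groups candidates into four prognosis categories by how
treatable they are, and then asks: given one observed gene activity
profile (GAP), how well can an *optimal* classifier predict the
patient's prognosis category? Because every distribution involved is
known exactly, the classifier and its error are computed in closed form
— the error reported is the best achievable by any classifier, so it
quantifies the intrinsic difficulty of prognosis under network
uncertainty.

## Model

**Dynamics.** A network on `n` genes is a signed regulatory matrix *R*
with entries in {−1, 0, +1} (activation / suppression / no edge).
States are GAPs `v ∈ {0,1}^n`, encoded as integers
`x = Σᵢ 2^(n−i) vᵢ` (gene 1 is the most significant bit). Genes update
synchronously by majority vote:

    fᵢ(v) = 1 if Σⱼ Rᵢⱼ vⱼ > 0,   0 if < 0,   vᵢ otherwise,

and each gene independently flips with perturbation probability `p` per
step; when at least one gene flips, the flip pattern overrides the
update. This gives the transition matrix

    P(x, y) = 1[f(x) = y] (1−p)^n + 1[d(x,y) ≥ 1] p^d (1−p)^(n−d),

with `d` the Hamming distance, an ergodic chain with a unique
steady-state distribution (SSD) π. A phenotype is scored by the SSD
mass `π_U` of a set *U* of undesirable states.

**Optimal control.** An external action flips one control gene before
the transition. The policy minimizing the long-run occupancy of *U*
solves the occupation-measure program

    min Σ_{x∈U, a} ν_xa   s.t.   Σ_a ν_xa = Σ_{y,a} ν_ya P_yx(a),
                                 Σ ν_xa = 1,  ν ≥ 0,

whose optimum is attained by a stationary deterministic policy.
`optimal_control()` solves it by Howard policy iteration (block-pivoting
simplex on the same program) and returns the policy, its occupation
measure, the controlled SSD mass `π*_U`, and the steady-state shift
`π_U − π*_U` (the benefit of treatment).

**Uncertainty class and prognosis classes.** From a healthy matrix,
`uncertainty_class()` enumerates all mutants with up to `rem` edges
removed and `add` edges added, keeps those at least as pathological as
the healthy network and as the average single-mutation candidate, and
weights survivors by a truncated geometric prior Λ(R) ∝ γ^l / N_l over
the mutation count `l`. Members are partitioned by thresholds
(α, β₁, β₂) on controlled mass and shift into: 1 — not critical, 2 —
responds well, 3 — improvable to some extent, 4 — poor and untreatable.

**Optimal Bayesian classifier.** With class probabilities
`cᵢ = Σ_{R∈Θⁱ} Λ(R)` and effective densities
`fᵢ(x) = Σ_{R∈Θⁱ} π_R(x) Λⁱ(R)`, the OBC assigns an observed state `x`
to the class maximizing `cᵢ fᵢ(x)` (smallest index on ties); its exact
expected error, per-state posteriors and per-network correct-
classification probabilities follow by direct summation.

## Worked example

The packaged mammalian cell-cycle network (10 genes; undesirable states
are those with CycD, Rb and p27 simultaneously off):

```r
library(prognet)
fx <- load_fixture("cellcycle")
tm <- build_tpm(fx$R, p = 0.01)
undesirable_mass(steady_state(tm), fx$U)
#> [1] 0.3405221
```

The healthy cell already spends ~34% of its long run in the proliferative
states. The full study — 39 single-edge-removal mutants, filtered to a
21-member uncertainty class, optimally controlled through E2F,
partitioned, and classified:

```r
st <- prognosis_study("cellcycle", cgene = "E2F", rem = 1, add = 0,
                      gamma = 1)
st
#> Study: cellcycle
#> Prognosis partition of 21 networks (control gene E2F )
#>   alpha = 0.2776, beta1 = 0.07195, beta2 = 0.06672
#>   sizes: 5/5/6/5  class probs: 0.238/0.238/0.286/0.238
#> Optimal Bayesian classifier: expected error 0.657187
#>   decisions: 257/302/277/188 states per class
```

Even the *optimal* classifier mislabels the patient's prognosis
two-thirds of the time from a single GAP — slightly better than the 0.714
of always guessing the largest class, and a quantitative statement that
one snapshot reveals very little here. `class_expectation(st$class,
"mass_controlled")` gives the class-average controlled mass (0.2889,
down from 0.3541 uncontrolled).

A command-line driver with the same functionality is installed at
`inst/cli/prognet` (subcommands `ssd`, `control`, `uncertainty`,
`classify`, `reproduce`, `synth`).

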