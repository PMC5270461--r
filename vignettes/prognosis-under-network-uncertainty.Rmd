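---
title: "Prognosis prediction under regulatory-network uncertainty: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognosis prediction under regulatory-network uncertainty: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

This vignette documents the modeling assumptions, numerical conventions
and design choices behind `prognet`, in the spirit of a methods section:
everything a user needs to judge what the computed numbers do and do not
mean. No empirical claim is made here beyond what the package's tests
and the acceptance script compute.

## The network model and its assumptions

Gene regulation is modeled as a synchronous Boolean network on $n$
genes with a signed regulatory matrix $R \in \{-1,0,1\}^{n\times n}$:
$R_{ij} = +1$ ($-1$) when gene $j$ activates (suppresses) gene $i$.
Updates follow the majority-vote rule: gene $i$ turns on when its active
activators outnumber its active suppressors, off in the opposite case,
and holds its value on a tie. A gene whose regulators have all been
removed by mutation therefore simply holds its value between
perturbations — no special casing is needed. The model is a coarse
abstraction: binary expression, synchronous updates, and no transcript
dynamics. Its virtue is that the entire state space ($2^n$ gene activity
profiles, GAPs) is tractable, so every quantity downstream is exact
rather than sampled.

Stochasticity enters through random gene perturbation: each gene flips
independently with probability $p$ per step. Several conventions for
combining perturbation with the deterministic update coexist in the
probabilistic-Boolean-network literature; `prognet` uses the one in
which a step with no flips (probability $(1-p)^n$) follows the
deterministic map $f$, and any realized flip pattern overrides the
update:
$$P_{xy} = \mathbf 1[f(x)=y]\,(1-p)^n + \mathbf 1[\eta(x,y)\ge 1]\,
  p^{\eta(x,y)}(1-p)^{n-\eta(x,y)},$$
where $\eta$ is the Hamming distance between the GAPs of $x$ and $y$.
Two consequences worth knowing: the current state has zero transition
probability to itself unless it is a fixed point of $f$ (the no-flip
mass sits on $f(x)$), and at $p = 0.5$ only the perturbation *kernel* is
uniform, not the TPM itself. The chain is ergodic for any $0<p<1$
(every off-diagonal entry is positive), so the steady-state distribution
(SSD) $\pi$ exists and is unique. This convention was adopted because it
reproduces the published undesirable-mass values of both packaged
real-network fixtures to all printed digits (0.3405 for the cell-cycle
network, 0.0057 for the p53 network at $p=0.01$); with bit order fixed
by $x=\sum_i 2^{n-i} v_i$ (gene 1 is the most significant bit).

The SSD is obtained by a direct linear solve of $\pi P = \pi$ with one
stationarity equation replaced by $\sum_x \pi_x = 1$, at residual
tolerance $10^{-10}$, falling back to the principal left eigenvector if
the solve degrades. Since the perturbation kernel depends only on
$(n,p)$, it is computed once and shared when thousands of mutant
networks are processed.

## Optimal intervention

Treatment is modeled as external control of a single gene: at each step
the controller either does nothing ($a=0$) or flips the control gene
($a=1$), in which case the row of the current state is replaced by the
row of its flip partner. Performance is the long-run expected occupancy
of a set $\mathcal U$ of undesirable states, and the optimization over
stationary randomized policies is the classical occupation-measure
linear program
$$\min_{\nu\ge 0} \sum_{x\in\mathcal U}\sum_a \nu_{xa}
  \quad\text{s.t.}\quad
  \sum_a \nu_{xa} = \sum_{y,a}\nu_{ya}P_{yx}(a)\ \forall x,\qquad
  \sum_{x,a}\nu_{xa}=1,$$
whose optimum is attained by a stationary deterministic policy.
`optimal_control()` solves this program by Howard policy iteration on
the equivalent average-cost Markov decision process. Policy iteration is
exactly the simplex method applied to this LP with block pivoting —
each policy corresponds to a basic feasible solution
$\nu_{xa} = \mu(a|x)\pi_x(\mu)$, and each improvement step is a
(multi-)pivot — so the returned occupation measure is an optimal vertex
of the LP feasible set. Numerical conventions: policy evaluation solves
the gain/bias system by dense LU; actions switch only on strict
improvement beyond a tie tolerance of $10^{-9}$ (preventing cycling);
final ties resolve to $a=0$, the less invasive action; and the reported
cost $J^\*$ is recomputed from the controlled chain's SSD and must agree
with the policy-iteration gain within $10^{-7}$. Optimality is
cross-checked in the test suite against exhaustive enumeration of all
$2^{2^n}$ deterministic policies on 3-gene networks and against an
independent simplex LP solve (`pracma::linprog`) on 2-gene instances.

## The uncertainty class, prior and prognosis partition

Cancer progression is modeled as edge mutations of a healthy matrix
$R^H$: a removal sets an existing entry to 0, an addition sets a zero
entry to $+1$ or $-1$ (each sign a distinct mutation); direct sign flips
are not in the alphabet, and self-loops are mutable like any other
entry. "Up to `rem` removals and up to `add` additions" are independent
limits, so with `rem = add = 1` a mutant may carry one removal, one
addition, or both (counting as two mutations). This combined-edit
reading is what reproduces the published p53 class size of 829 from the
2,024 enumerated candidates; pure single edits alone would only give
148 candidates.

Candidates are filtered by two criteria, both evaluated against the
*pre-filter* candidate set: a member must have undesirable mass at least
that of the healthy network, and at least the mean undesirable mass of
all single-mutation candidates. Ties are kept. Survivors are weighted by
the truncated-geometric prior $\Lambda(R) \propto \gamma^l / N_l$, with
$l$ the number of entries edited and $N_l$ the number of *surviving*
members at that mutation count.

Members are then partitioned by their controlled mass
$\pi_{R^\*\mathcal U}$ and shift
$\pi_{R\mathcal U}-\pi_{R^\*\mathcal U}$ into four prognosis classes
(not critical / responds well / improvable / untreatable) using
thresholds $\alpha,\beta_1,\beta_2$. `auto_thresholds()` chooses them so
the classes have nearly equal sizes: $\alpha$ is the median controlled
mass, $\beta_1$ the median shift among members below $\alpha$, $\beta_2$
the median shift among the rest, all with `stats::median()`'s midpoint
interpolation for even counts. The interpolated-median convention was
chosen over attained-value (lower-median) thresholds because it yields
the more balanced 5/5/6/5 split on the 21-member cell-cycle class and
reproduces the published optimal-classifier error for that study to all
printed digits, where the lower-median convention does not. Data-derived
shift medians may legitimately equal 0 when control brings no benefit to
half a group; explicitly supplied thresholds are validated to $(0,1]$.

## Optimal Bayesian classification

A patient contributes one observed GAP, drawn from the SSD of their
(unknown) network without intervention. With class probabilities
$c^i = \sum_{R\in\Theta^i}\Lambda(R)$ and effective densities
$f^i_x = \sum_{R\in\Theta^i}\pi_{Rx}\Lambda^i(R)$, the optimal Bayesian
classifier assigns $x$ to the class maximizing $c^i f^i_x$, breaking
exact ties toward the smallest index. Its expected error, the per-state
class posteriors and each network's probability of correct
classification are computed as exact sums over the state space and the
class — no sampling anywhere in the implementation (Monte-Carlo
appears only in tests, as an independent check of the posteriors).
Empty prognosis classes (possible under extreme thresholds) simply drop
out of the argmax; their density is zero.

## The packaged real-network studies

Two fixtures ship with the package: the 10-gene mammalian cell-cycle
network (undesirable: CycD, Rb and p27 all off; the published source
writes "Rd" once, read here as a typo for Rb) and a 9-node p53
stress-response network (undesirable: DNA damage present, p53 off). The
cell-cycle study uses single removals only, which makes the prior
uniform; the p53 study uses `rem = add = 1` with $\gamma = 0.5$.

One reporting subtlety, preserved deliberately: in the published p53
summary table, the class-average mass columns
($\mathrm E[\pi_{R\mathcal U}] = 0.0183$,
$\mathrm E[\pi_{R^*\mathcal U}] = 0.0104$ for ATR) are consistent with
*unweighted* means over the 829 members, while the optimal-classifier
error (0.4789 for ATR) is consistent with the stated geometric prior
($\gamma^l/N_l$ gives 0.4788; a uniform prior would give 0.5859). The
$\Lambda$-weighted expected uncontrolled mass is 0.0124, which matches
no published figure. `study_table()` therefore reports the mass columns
as unweighted means — the published estimator — while the classifier
itself always uses $\Lambda$; `class_expectation()` exposes both
weightings so users can pick either convention knowingly.

A second subtlety concerns reproducibility of the p53 classifier error
in its fourth decimal. Many mutants of the p53 network are dynamically
identical (different edits, same transition map), so dozens of members
share controlled masses and shifts *exactly* — including values that
become the auto-threshold medians. Members lying exactly on a threshold
have their prognosis label decided by the strict-`<` comparisons, which
in floating point means by solver round-off at the $10^{-16}$ level.
The resulting classifier error is stable to about three decimals
(0.4787–0.4788 across solver variants for ATR, against a published
0.4789); forcing ties wholesale to either side of the thresholds moves
~60 labels and the error to 0.477 or 0.503. `prognet` keeps the exact
comparison semantics and makes no attempt to re-resolve ties.

## The synthetic-study generator

`run_synthetic_study()` emulates the randomized study design: seed
matrices with $r(i)\sim\mathrm{Uniform}\{1..r_\max\}$ predictors per
gene, uniformly placed, each activating with probability $\beta$;
defaults $n=7$, $r_\max=3$, $\beta=0.5$, $p=0.01$,
$\mathrm{rem}=\mathrm{add}=1$, $\gamma=0.5$, 250 seeds, with the
undesirable states those where gene 1 is downregulated (half the state
space) and every other gene allowed as control. The healthy network is
the single-mutation variant of the seed with minimal undesirable mass
(ties broken by enumeration order: removals before additions, cells in
column-major order, $+1$ before $-1$). What the generator does *not*
emulate: measurement noise on the observed GAP, asynchronous or
continuous dynamics, correlated mutation processes, or any real genome's
topology — so passing tests demonstrate internal correctness of the
pipeline under the model, not fidelity to real tumor data. Because the
random seeds behind the published scatter plots are unknown, figure-level
results are validated as qualitative trends only (e.g. larger
uncertainty classes give higher optimal error); the package's checks run
a reduced batch of 10 seeds at $n=7$, a size chosen to exercise the full
pipeline while keeping the default test run fast.

## Degenerate inputs and limitations

* Networks with all-zero rows are valid (frozen genes); networks whose
  every candidate mutant fails the filter yield an empty class with a
  warning.
* `auto_thresholds()` refuses classes with fewer than 4 members or with
  indistinguishable members.
* Exhaustive policy search refuses $n>4$ ($2^{2^n}$ policies).
* All computations are dense in the $2^n$ state space: practical up to
  $n\approx 12$; beyond that, memory for the $4^n$-entry TPM dominates.
* Mutation enumeration is combinatorial in `rem`/`add`; the intended
  regime is the published one (at most one or two edits).
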