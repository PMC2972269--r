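---
title: "Boolean and continuous models of the Arabidopsis root stem cell niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean and continuous models of the Arabidopsis root stem cell niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootscn)
library(dplyr)
```

## The biological problem

The *Arabidopsis thaliana* root tip harbours a stem cell niche (SCN): four
rarely dividing organizer cells — the quiescent center (QC) — surrounded by
initial cells that found every root cell lineage.  Experimentally, two
regulatory modules dominate SCN patterning: the SHR/SCR pathway (with JKD and
MGP) that governs the radial pattern, and the auxin → Aux/IAA → ARF → PLT
readout along the root axis; WOX5 marks the QC and connects the two.  The
question the models in this package address is whether these documented
interactions, plus a small number of predicted ones, *suffice* to generate
the stable gene-expression configurations of the four niche cell types —
QC, vascular initials, cortex-endodermis initials (CEI) and the merged
columella/epidermis initials (CEpI) — and their spatial arrangement.

## The discrete model

Each gene (or collapsed gene family) is a Boolean variable.  A network is a
list of logical update rules, one per node, applied synchronously:

$$x_n(t + 1) = F_n\!\left(x_{n_1}(t), \dots, x_{n_k}(t)\right), \qquad
x_n \in \{0, 1\}.$$

The state space is finite ($\Omega = 2^N$), so every trajectory ends in an
attractor — a fixed point or a cycle — and attractors are identified with
cell-type expression profiles.  `find_attractors()` follows every one of the
$2^N$ initial configurations (exhaustive mode) or a seeded random sample, and
reports attractors with basin sizes.  Truth-table rows are enumerated with
the declared inputs most significant first, row 1 being all-zeros; under the
SCR input order (SHR, SCR, JKD, MGP), "line 14" is the pattern 1101.  This
convention is what makes the single-bit difference between the primed and
unprimed model variants well defined.

Loss- and gain-of-function mutants are simulated by clamping a node to 0 or
1 from $t = 0$ onwards (`clamp()`, `simulate_mutant()`).

## The four niche variants and their reconstructed rules

The variants differ in who shuts WOX5 off outside the QC: in models A and A'
MGP and WOX5 repress each other; in B and B' a hypothetical CLE-like gene,
CLEX, carries the repression (and is itself activated by the SHR/SCR context
and WOX5).  A' and B' differ from A and B in a single SCR truth-table bit
(line 14), which makes SCR expression independent of JKD.

The literal truth tables of the original study are not redistributable, so
the package ships a reconstruction constrained to reproduce the published
attractor tables, basin structure, mutant outcomes and robustness behaviour:

* `auxin = 1` (constant source), `AuxIAA = NOT auxin`, `ARF = NOT AuxIAA`,
  `PLT = ARF` — the auxin readout chain;
* `SHR = SHR` — no known transcriptional regulator, so its state is its
  initial condition;
* `SCR = SHR AND SCR AND (JKD OR NOT MGP)` (A, B); the primed variants flip
  line 14, equivalently `SHR AND SCR`;
* `JKD = SHR AND SCR`; `MGP = SHR AND SCR AND NOT WOX5`;
* `WOX5 = ARF AND SHR AND SCR AND (NOT MGP OR WOX5)` (A/A'), with `NOT CLEX`
  replacing `NOT MGP` in B/B';
* `CLEX = SHR AND NOT WOX5 AND (MGP OR CLEX)` (B/B').

Two reconstruction choices deserve emphasis.  First, the WOX5 rule carries a
self-maintenance disjunct (`... OR WOX5`).  A *symmetric* synchronous mutual
repression between WOX5 and MGP would oscillate with period 2 from mixed
initial states; the published models converge to fixed points only, so some
asymmetry must have been present, and a self-input is the smallest device
that provides it.  A side effect is that a CLEX gain-of-function clamp does
not extinguish an already-active WOX5, so the original study's aside that
CLEX over-expression consumes the QC is not reproduced by this
reconstruction.  Second, the single-cell regulation of CLEX is nowhere
stated; the rule above is the minimal one that makes CLEX on in CEI, off in
QC and CEpI, and bistable in the vascular initials — which is exactly why
the B variants have five attractors (vascular appears with CLEX on and off).

```{r attractors}
net <- build_scn_model("B_prime")
aset <- label_attractors(find_attractors(net), scn_reference_profiles("B_prime"))
tidy(aset)
```

Every variant's full attractor table, the all-fixed-point property, and the
basin law (exactly half of all initial states — those with SHR off — reach
CEpI) are asserted in the test suite.

## Robustness analyses

`rule_flip_scan()` flips every output bit of every truth table one at a
time, recomputes the exhaustive attractor set, and classifies the flip as
neutral iff the attractor *state set* is unchanged (basin sizes may move; the
comparison deliberately ignores them).  The scan size is
$\sum_n 2^{k_n}$ — 69 flips for the 9-node variants and 85 for the 10-node
variants under the reconstructed arities.  About 62–64% of flips are neutral
here; the exact published percentages depend on the original tables'
arities, which are not recoverable, so the tests pin the structural
properties (flip count, strict 0–1 bounds on the neutral fraction) rather
than those two numbers.

`derrida_map()` measures criticality: pairs of states at a controlled
Hamming distance are advanced one synchronous step and the mean distance
afterwards is recorded.  Near the origin the curves of all four variants
hug the identity line — the signature of dynamics at the order/chaos
boundary.  The engine itself is validated on the standard NK random Boolean
ensemble (`random_network()`), whose one-step map has the annealed closed
form $H_{t+1} = 2p(1-p)\,[1 - (1 - H_t)^K]$ (`annealed_derrida_curve()`).
That formula assumes input choices independent of the flipped positions
(the large-$N$ limit); the cross-validation therefore uses $N = 60$, where
the hypergeometric finite-size bias of exact-distance sampling is several
times smaller than the Monte-Carlo standard error of a 100-network
ensemble.

## The continuous counterpart

`to_continuous()` renders each logical rule as a fuzzy input function
$w_k : [0,1]^N \to [0,1]$ (AND $\to$ min, OR $\to$ max, NOT $\to 1 - x$) and
builds the Glass-type system

$$\frac{dX_k}{dt} = f\!\left[w_k(X)\right] - \gamma_k X_k, \qquad
f[w] = \frac{1}{1 + e^{-h (w - w_{thr})}},$$

with defaults $h = 50$, $\gamma_k = 1$, $w_{thr} = 1/2$ — steep enough that
$f$ is effectively a differentiable step.  The structural min/max rendering
(rather than a disjunctive-normal-form rendering of the tables) matters: it
reproduces Boolean outputs exactly on corners *and* preserves the saddle
geometry between attractors; a DNF rendering caps some input functions at
1/2 along the CEI–QC connecting line and destroys that structure.

`find_steady_states()` runs damped Newton iterations from every Boolean
corner, the all-0.5 midpoint, and the pairwise midpoints of the roots found
(a cheap vectorized fixed-point sweep resolves the corner seeds first).
Roots are merged within $10^{-4}$ (sup-norm), accepted below a residual of
$10^{-8}$, and classified by the real parts of numerical Jacobian
eigenvalues; `assess_stability()` confirms classifications by seeded
perturbed restarts, and disagreements would surface as reported
classification columns rather than being silently resolved.

For every variant the stable steady states, rounded at 1/2, are exactly the
discrete attractors, and the count is unchanged as $h$ sweeps 20–200.  The
A variants additionally possess an unstable steady state midway between the
CEI and QC configurations with MGP and WOX5 both at exactly 0.5 — the
mutual-repression balance point; 1000 seeded restarts perturbed by up to
30% of each coordinate all fall to CEI or QC.  At finite steepness the
logistic system also has further threshold-type unstable equilibria (any
self-input node, such as SHR, supports a root at its threshold, and an
SCR-threshold family exists).  These sit on basin boundaries, round to
states that *are* discrete attractors, and are reported as unstable roots;
the CEI–QC saddle is the only root whose non-Boolean coordinates are
exactly {MGP, WOX5}, which is how the package identifies it.

```{r saddle}
ss <- find_steady_states(to_continuous(build_scn_model("A")))
tidy(ss) |> filter(!stable, abs(MGP - 0.5) < 1e-4, abs(SCR - 1) < 0.05)
```

## The coupled spatial model

`build_meta_grn()` places one copy of model B' in each of four positional
cells — V (vascular), C (CEI), Q (QC), E (CEpI), adjacency V–Q, V–C, C–Q,
Q–E — giving 40 variables named `node_cell`.  Four components act across
cells, with per-component semantics:

* **SHR** moves to a neighbour only from cells not expressing SCR (SCR
  sequesters the protein); `SHR_V` is clamped on (the stele source) and
  `SCR_V` clamped off — the only topological change relative to the
  single-cell model;
* **auxin** flows acropetally: clamped on in V and C, reaching Q and then E;
* **WOX5** acts at long range: it activates CLEX in every cell *except* the
  QC, and (with auxin) represses Aux/IAA — the local-activator half of an
  activator–inhibitor motif;
* **CLEX** from any cell shuts WOX5 off everywhere *except* in the QC, whose
  WOX5 rule escapes the repression — the long-range-inhibitor half.
  CLEX is structurally absent from the QC.

Because SCR requires itself, a Boolean model cannot represent its basal
expression; following the original study's convention, `run_spatial()`
forces every unclamped SCR variable on at $t = 0$ and $t = 1$ and then
releases it.  Under that convention, every sampled initial configuration
(100,000 seeded states in the acceptance runs; the $2^{40}$ space is not
enumerable on a desk machine) converges to one global fixed point whose
per-cell projections are exactly the single-cell reference profiles —
V = vascular, C = CEI, Q = QC, E = CEpI — with WOX5 confined to the QC.
Without the convention the all-zero start demonstrates the bootstrap
failure: SCR never turns on.

Spatial mutants clamp a gene in all four cells and are run under both
conventions (`simulate_spatial_mutant()` reports both, with provenance).
The union matters for SHR gain of function, whose second columella outcome
(CEpI-plus-ectopic-SHR) is only reachable when SCR may start off; claims of
the form "nothing changes" (the MGP knockout) are evaluated within the
convention-on run, since the convention-off wild type itself has
SCR-bootstrap-failure attractors that would confound a union-to-union
comparison.  The continuous spatial system, integrated from random interior
points with SCR levels started at 1, reaches the same rounded global state
(`spatial_continuous_check()`).

## Numerical and design choices

* Deterministic throughout; every stochastic operation requires an explicit
  integer seed, and identical seeds give identical results.
* Attractor canonicalization rotates cycles so the lexicographically
  smallest state leads; de-duplication and set comparisons use that form.
* Cycle detection: exhaustive mode walks the successor graph with
  path-marking (linear in $\Omega$); sampled/batch mode freezes fixed points
  as soon as a state repeats and catches longer cycles with per-trajectory
  Brent checkpointing.
* The exhaustive cap defaults to 24 nodes; beyond it the engine refuses and
  points to sampled mode.
* ODE integration uses lsoda (relative tolerance $10^{-8}$ for trajectory
  work, $10^{-6}$ for the bulk restart screens); steady-state residual
  tolerance $10^{-8}$; duplicate-root merge radius $10^{-4}$.
* Problem sizes in the shipped tests: exhaustive searches up to $2^{10}$;
  100,000 spatial samples; 1000 saddle restarts; 100 continuous spatial
  starts; 100 NK networks × 300 pairs per distance class for the Derrida
  cross-validation.

## What the synthetic generator does and does not emulate

`random_network()` draws from the standard NK ensemble: $K$ distinct inputs
per node (self-inputs allowed), output rows independently 1 with
probability $p$.  It exercises every engine path — arbitrary arities,
cycles of any period, sampled and exhaustive searches — with known
statistical structure, and the annealed Derrida map gives an analytic
oracle.  It does *not* emulate the biological models' canalized structure
(constant sources, nested AND chains, self-inputs with meaning), so
passing the NK cross-validation certifies the measurement machinery, not
any biological claim; the biological claims are tested against the frozen
reference tables instead.

## Known limitations

* The reference rules are a constrained reconstruction, not the original
  tables; single-rule details with no published dynamical consequence
  (e.g. exact CLEX regulation, the published robustness percentages to one
  decimal, the CLEX-gain prediction) are outside what it can pin down.
* Only synchronous updating is implemented; asynchronous schedules can
  change basin structure and are out of scope.
* Mobility in the spatial model is pre-specified, not emergent; cell
  division, growth, and graded auxin transport are not modelled.
* `PLT`, `ARF` and `Aux/IAA` are family-collapsed single nodes; auxin is a
  Boolean presence/absence, not a concentration.
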