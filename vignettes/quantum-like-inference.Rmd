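---
title: "Quantum-like inference in Bayesian networks: model, heuristic, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-like inference in Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlbn)
```

## The problem

In several well-replicated experiments people violate the Sure Thing
Principle: they prefer an action under each known state of the world, yet
abandon it when the state is unknown. In the Prisoner's Dilemma variants,
most participants defect when told the other player defected *and* when told
the other player cooperated, but defect far less often when told nothing. No
classical mixture can produce this: the law of total probability (LTP)
forces the unknown-condition probability to lie between the two
known-condition probabilities. In the averaged Prisoner's Dilemma data
(known-defect 0.87, known-cooperate 0.74) the LTP predicts 0.805 while the
observed value is 0.64.

`qlbn` implements a quantum-like Bayesian network: an ordinary directed
acyclic network of binary variables with conditional probability tables,
whose inference rule is modified by replacing each classical probability
with a Born-rule amplitude, amplitude = sqrt(p) · e^{iθ}. Summing amplitudes
over unobserved ("hidden") completions *before* squaring produces cross
terms — interference — that can push the prediction outside the classical
interval.

## The inference rule

For a query on a binary target with evidence `e`, let `y = 1 … m` index the
hidden completions consistent with the evidence and one target state, and
let `|ψ_y|` be the square root of the classical joint probability of that
full assignment. The unnormalized score of that target state is

    score = Σ_y |ψ_y|²  +  2 Σ_{i<j} |ψ_i||ψ_j| cos(θ_i − θ_j)

The same phase differences are applied to both target states, and the two
scores are normalized by α = 1 / (score₁ + score₂). Two limits anchor the
model:

* at phase difference π/2 every cosine vanishes and the result *is*
  classical exact inference (tested on 200 seeded random networks to
  1e−10);
* with a single hidden completion there are no pairs and the result is
  classical regardless of phases.

A network with N binary variables exposes 2^N phases; the package never asks
the user for them. They are either set explicitly (`quantum_infer()`,
`sweep_phase()`) or derived by the similarity heuristic (`qlbn_predict()`).

## The similarity heuristic

For a binary query with two hidden completions, group the four relevant
joint probabilities into two 2-component vectors: `a` holds the two
components for the queried state, `b` those for the opposite state (the
components are probabilities, i.e. squared magnitudes — not amplitudes; the
inference normalization absorbs the non-unit lengths). The vectors and their
Euclidean difference `c = a − b` form a triangle; the law of cosines gives
its inner angles θ_A (facing `a`), θ_B (facing `b`) and θ_C (facing `c`,
which equals the angle between `a` and `b` — the package cross-checks this
against the direct cosine similarity). With the similarity ratio
φ = (θ_C − θ_B)/θ_A, the phase is chosen piecewise:

* φ < 0  →  θ = π (full destructive interference),
* φ > 0.2 →  θ = π − θ_C/2,
* otherwise → θ = π − θ_C.

The thresholds 0 and 0.2 are empirical constants of the heuristic; they were
chosen in the originating work by inspecting the Sure-Thing-Principle
corpus and have no derivation, so the package implements them verbatim,
with strict inequalities: φ exactly 0 or 0.2 falls in the "otherwise"
branch. All three branches give cos(θ) ≤ 0 whenever θ_C ≤ π/2, so the
heuristic always injects destructive interference on these scenarios —
which is the direction Sure-Thing-Principle violations require. Note that
destructive interference on *both* outcomes does not force the normalized
probability below the classical value: the ratio of two shrunken scores can
move either way (Croson's Game 1 rises from a classical 0.425 to 0.588).

Worked end to end for the averaged Prisoner's Dilemma conditions:
a = (0.435, 0.370), b = (0.065, 0.130), ‖c‖ = 0.4410, θ_C = 0.4023,
φ = 0.1046 → θ = π − θ_C = 2.7393; scores 0.0667 and 0.0258, α = 10.81,
Pr(defect) = 0.7208 against the observed 0.64 (fit error 12.6%):

```{r worked}
net <- record_to_network(stp_studies("T1")[6, ])
qlbn_predict(net, "P2", observed = 0.64)
```

## Baselines

Two comparison predictors are included. The classical baseline is the LTP
value itself (`ltp_predict()`, identical to `classical_infer()` on the
two-node networks — an identity the tests exploit). The Quantum Prospect
Decision Theory (QPDT) baseline fixes the interference magnitude at 1/4
(the "interference quarter law") with opposite signs on the two prospects;
operationally, on these two-condition scenarios, every published QPDT cell
equals the classical LTP value minus 0.25 on the focal action. We verified
that identity by exact arithmetic on all fourteen published comparison rows
and implement `qpdt_predict()` as that rule, with clamping to [0, 1]
flagged; the amplitude-level prospect machinery would add no testable
behavior here.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `prior1` | probability | 0.5 | the experiments tell participants nothing about the first condition; every fixture uses a uniform prior |
| heuristic thresholds | — | 0 and 0.2 on φ | empirical constants of the heuristic, implemented verbatim |
| phase grid in `sweep_phase()` | radians | 1001 points on [0, 2π] | fine enough to bracket extremes of a smooth 1-parameter curve; includes π exactly on the default 2001-point acceptance grid |
| `synth_scenarios()` conditionals | probability | Uniform(0.05, 0.95) | bounded away from 0/1 so no generated evidence is impossible and degeneracy-free property tests stay meaningful |

## Numerical choices

* arccos arguments are clamped to [−1, 1] before evaluation; without the
  clamp, collinear vectors can produce arguments like 1 + 2e−16.
* No intermediate rounding anywhere. The originating tables round to four
  decimals mid-computation, so comparisons against printed values use
  absolute tolerances (±0.005 on probabilities, ±0.01 rad on angles) rather
  than exactness.
* Degenerate triangles (a zero-length side, e.g. when one outcome has no
  probability mass) have no defined angles; `qlbn_predict()` falls back to
  the classical collapse phase π/2 with a warning, since classical behavior
  is the model's stated limit.
* Hidden completions are enumerated in a fixed, documented order —
  variables sorted by name, first-listed state before second — because the
  per-pair phase keys `"i-j"` refer to positions in that order.
* Negative unnormalized scores (possible under extreme per-pair phases,
  never under a single shared phase with two completions) are not clipped;
  the result is flagged `nonphysical` and still normalized by the score sum,
  so the caller can see exactly what the phases did.
* Evidence with probability zero raises an error rather than returning 0/0.

## Design decisions that were genuinely open

* **One phase spec for both target states.** The general rule allows each
  target state its own phase set; the originating worked example computes a
  single θ and applies it to both scores, and that is what `qlbn_predict()`
  does. Independent per-outcome phases remain reachable through
  `quantum_infer()` for exploration.
* **Vector components are probabilities, not amplitudes.** The printed
  worked-example vectors (0.435, 0.370, …) are joint probabilities; the
  package follows them.
* **Generalization past two hidden completions.** No published fixture
  exercises it, so the package takes the least-surprising extension: one θ
  per completion pair, computed from the 2-component vectors restricted to
  that pair, fed to the inference as a per-pair phase map. It is flagged
  experimental in the documentation; on uniform three-variable networks
  the six destructive phases can drive a score negative, which is reported
  via the `nonphysical` flag rather than hidden.
* **Orientation.** Vector `a` is always built for the queried state. The
  swap symmetry (a↔b, θ_A↔θ_B, θ_C fixed) is tested; the branch selector φ
  is *not* swap-invariant, so querying the complementary state may fire a
  different branch — a real asymmetry of the heuristic, not a bug.

## What the synthetic generator emulates — and what it does not

`synth_scenarios()` produces two kinds of networks under one seed: two-node
uniform-prior scenarios shaped exactly like the literature designs, and
random chains/trees of up to five binary variables. It emulates the
*structure* of decision scenarios (small DAGs, binary actions, bounded
conditionals). It does not emulate human data: no response noise, no
sampling variability, no payoff structure. Passing property tests on these
networks therefore establishes the algebraic contracts of the engine
(normalization, classical collapse, enumeration-oracle agreement) — not
predictive validity on new behavioral data, which only the embedded
literature fixtures speak to.

## Problem sizes used in the test suite

Property suites run on 200 seeded networks of up to four nodes for the
classical-collapse check, 25 networks of up to five nodes against the
brute-force enumeration oracle, and 500 random vector pairs for the
triangle identities; sweeps use grids of 361–4001 points. These sizes fully
cover the model's discrete structure (every topology class the generator
emits) while keeping the suite fast.

## Known limitations

* Binary variables only; multi-valued or continuous nodes are out of scope,
  as are approximate inference and structure learning.
* The heuristic's thresholds are empirical; on scenarios far from the
  Sure-Thing-Principle corpus (e.g. the guessed-condition games, where no
  phase reproduces the observations exactly) its predictions can carry
  large fit errors, and the published record itself contains internally
  inconsistent cells which `reproduce_table()` flags rather than matches.
* Interference phases have no time dynamics here; Hamiltonian/unitary
  evolution and density-matrix formulations are different models and are
  not implemented.
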