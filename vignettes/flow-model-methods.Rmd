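---
title: "Flow models for medication-error incident reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow models for medication-error incident reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Hospital incident-reporting systems accumulate structured accounts of
medication errors: what went wrong (the *event*) and which circumstances
and behaviors contributed (the *factors*). `medflow` models a corpus of
such reports as a discrete Bayesian network — a directed acyclic graph
with one conditional probability table (CPT) per variable — over a fixed
34-variable codebook: 10 error events (wrong dose, wrong patient,
improper mixing, ...) and 24 contributing factors in four categories:

* **attributional** — stable properties of the nurse involved (years of
  experience; tenure in the current work setting), in bands;
* **system** — organizational/technical context (whether the electronic
  record system could have detected the error);
* **conditional** — circumstances of the moment (work time band, holiday
  work, night shift, patient age band, time pressure, schedule changes,
  failures of medical orders, non-adherent patients);
* **knowledge/behavioral** — the nurse's knowledge state and actions
  (failure to confirm the 5 rights, assumptions and forgetfulness,
  invalid double checks, and so on).

The joint distribution factorizes as
$P(x_1,\dots,x_n) = \prod_i P(x_i \mid \mathrm{pa}(x_i))$. All factor
and event variables are binary (`absent`/`present`) except the four
banded context variables. The learned, layered network is called the
*flow model*: causes flow from stable attributes through circumstances
and behaviors into events.

The package deliberately treats the codebook as a fixed artifact. Coding
free-text narratives into this vocabulary is qualitative work outside
the scope of the software.

## Exact inference

All probability queries are answered exactly by variable elimination
over table factors, with two safeguards:

* **Barren-node pruning.** Only ancestors of the query and evidence
  nodes enter the computation. Besides speed, this gives a useful
  sharpness guarantee: editing or intervening on a node that is not an
  ancestor of the query cannot change the answer *even at the
  floating-point level*, which the test suite checks bit-for-bit.
* **Impossible evidence.** If the evidence has probability zero under
  the model, inference raises an explicit error instead of returning
  `NaN`; silent `NaN` propagation hides modelling bugs.

The elimination order is min-fill with deterministic ties (node name).
Correctness is established against an independent brute-force oracle —
full joint enumeration, feasible up to $2^{20}$ states — on hundreds of
random networks, at tolerance $10^{-9}$, including post-intervention
graphs; a further test confirms the posterior is invariant to the
elimination order.

## Structure learning

The flow model is learned by steepest-ascent hill climbing over edge
additions, deletions and reversals, under constraints:

* **Category ordering.** Attributional and system factors have no
  parents; edges may otherwise only point from lower to higher rank
  (attributional/system < conditional < knowledge/behavioral < event),
  with within-rank edges allowed among conditional factors and among
  knowledge/behavioral factors — behavior can trigger behavior, which
  is what makes deep (5-layer) models possible.
* **Blacklist / whitelist.** Forbidden edges are never added; forced
  edges are placed in the starting graph and never removed. The default
  whitelist is empty. A mechanized refinement loop
  (`refine_blacklist()`) re-adds any category-violating edge of a
  fitted model to the blacklist and re-runs the search until a fixed
  point; because the blacklist grows monotonically, termination is
  guaranteed.

The local score of a family is the Laplace-smoothed log-likelihood of
the child given its parents, with an AIC penalty by default (BIC and raw
log-likelihood are available). Scores are decomposable, so moves are
evaluated from two family scores, which are memoised.

**The acceptance threshold.** An edge addition is accepted only when it
improves the score by at least `threshold` *nats per record* (default
0.02). For maximum-likelihood scores this gain is exactly the empirical
conditional mutual information between child and new parent, so the
threshold is an information floor: dependencies carrying less than 0.02
nats per record are deliberately left out of the model, whatever the
sample size. Deletions and reversals require strict total-score
improvement. The precise semantics of the threshold in the commercial
tool this procedure emulates are not published; per-record score gain is
the reading we adopt, and it is configurable. Ties between moves are
broken by move type and then lexicographically, making the search fully
deterministic; optional random restarts (off by default) use the
configured seed.

Parameter defaults and why:

| parameter | default | rationale |
|---|---|---|
| `threshold` | 0.02 nats/record | information floor for edge acceptance |
| `max_parents` | 3 | ~119-record corpora cannot support larger CPTs |
| `smoothing_alpha` | 1 (Laplace) | keeps every scenario query defined on sparse rows |
| `score` | AIC-penalized log-likelihood | mildest standard complexity penalty; the threshold, not the penalty, is the binding filter at survey scale |

Layer assignment is by longest directed path from any source (so every
edge spans strictly increasing layers); variables with no edges are
excluded from the flow model and reported as such.

## Scenario analysis

The question the scenario analysis answers: *if education eliminated a
behavioral factor, how often would each error still occur?* Formally the
factor is forced to `absent` and event posteriors are recomputed. Two
readings of "set the prior to 0%" are implemented:

* `mode = "do"` (default) — graph surgery: incoming edges of the
  controlled node are removed and the node is clamped. This is
  intervention semantics, appropriate because an educational program
  *manipulates* the factor rather than observing it.
* `mode = "condition"` — the forced state is treated as evidence. For a
  root factor the two coincide (checked in tests); for a factor with
  parents they differ, and the report records which mode produced it.

Reports contain one cell per (event, factor) pair where the factor is an
ancestor of the event — other pairs are provably unaffected under
intervention semantics — with base and posterior percentages to one
decimal. Factors are ranked by total absolute risk reduction (summed
base − posterior across events), ties broken by name.

## The synthetic-data generator

Incident-report corpora of this kind cannot be redistributed as
structured data, so the generator produces datasets with the statistical
shape the analysis assumes, from a *known* ground truth, enabling
end-to-end recovery testing.

**Ground-truth DAG.** A layered emulation: attributional/system roots;
binary conditional factors with 0–2 root parents; knowledge/behavioral
factors with 1–2 conditional parents; events with 1–3 behavioral
parents. Work time and patient age stay exogenous (shift schedules and
patient mix are not caused by nurse attributes). Random parent choices
are weighted by the candidate's marginal variability, so near-degenerate
factors (e.g. the 3.4%-prevalence ones) tend to stay peripheral — in the
published analysis, too, the rarest factors dropped out of the flow
model. A fixed backbone (tenure → time pressure → assumptions →
failure to confirm the 5 rights → wrong dose, plus insufficient
knowledge → improper handling) guarantees five layers, the depth the
published model reports.

**CPT family.** Child risk is additive in its parents:
$P(\text{present} \mid \text{config}) = \min(\lambda + e \sum_j w_j,\,0.99)$,
with graded weights $w_j \in [0,1]$ per parent state and effect size
$e = 0.3$ by default. Additivity is the crucial design property: every
edge carries the full contrast $e$ regardless of co-parents, so each
true edge contributes detectable marginal dependence. (An OR-gate
variant, where co-parent activity masks individual contributions, drops
single-edge information below the 0.02-nat acceptance floor whenever a
child has several prevalent parents — the learner then cannot accept the
first edge of such a family no matter how much data it sees. We
consider the additive form at least as defensible for incident
causation, and it keeps the generator's edges learnable by the very
method the package implements.) The default $e = 0.3$ is strong enough
for recovery at simulation scale and modest enough to be a realistic
behavioral risk increment.

**Calibration.** The baseline $\lambda$ of each node is solved by
bisection, in topological order, so that the node's *exact* marginal
(computed by variable elimination over already-calibrated ancestors)
matches the published frequency table of the N = 119 corpus; root nodes
take their target exactly. Two context variables have no published
counts and use documented defaults (night shift present 30%; patient
age bands 10/30/60%). $\lambda$ is clipped to $[0.01, 0.99]$: for
targets rarer than the effect size allows (several events have
prevalence below 6%), the contrast is kept and the residual marginal
error is *reported* in the calibration table rather than silently
absorbed. Non-clipped nodes match their targets to within $10^{-4}$.

**Sampling.** Records are drawn ancestrally; draws in which no event is
`present` are rejected, mirroring that a report corpus only contains
reports. Targets are interpreted pre-rejection: conditioning on "at
least one event" inflates marginals of event-connected variables by up
to the reciprocal of the acceptance rate (about 0.84 under defaults).
This bias is real in the emulated setting too — incident databases are
selection-biased in exactly this way — and it has one important
consequence for validation: a model learned from the selected records
estimates the *post-selection* distribution, so its probability levels
sit above the pre-selection truth, coherently for base and posterior
alike. Recovery of scenario results is therefore judged on absolute
risk reductions (base − posterior), which are invariant to this
coherent shift, rather than on raw posterior levels.

**What passing tests do and do not show.** The generator produces
independent rows from a sparse layered network with additive CPTs and
exact marginal calibration. Real incident reports have features it does
not emulate: reporter selection beyond the one-event condition,
correlated reporting cultures across hospitals, coding noise in the
qualitative extraction, non-additive interactions, and duplicated
events from a single incident narrative. Passing recovery tests shows
the pipeline is correct and powerful under the stated assumptions, not
that a 119-record corpus identifies the true causal graph.

## Numerical and degenerate-input choices

* CPT rows must sum to 1 within $10^{-9}$; parent configurations are
  enumerated in `expand.grid` order (first parent fastest) and the
  ordering is serialized explicitly.
* Calibration bisection runs 60 halvings (resolution $\sim 10^{-18}$ on
  the leak), far inside the $10^{-4}$ acceptance band.
* Empty record sets are rejected by tabulation and scoring; records
  with zero `present` events are invalid everywhere (an incident report
  documents an incident), except that generic codebooks without event
  variables skip the rule.
* Rejection sampling aborts with advice once the acceptance rate is
  provably below 1%.
* Serialization writes numbers at full precision (no rounding), so a
  learned model round-trips exactly and re-running a stage reproduces
  its output byte for byte.

## Problem sizes used by the test suite

Simulation-based checks use sizes chosen to make the statistical
assertions sharp while keeping the default suite quick on one CPU:
structure recovery runs 10 replicates of n = 5000 records over the
34-node truth (skeleton recall averages ≈ 0.97 against an acceptance
floor of 0.80); the 6-node recovery study uses 20 replicates of
n = 5000; inference oracle equivalence covers 100+ random networks of
up to 10 binary nodes; Monte-Carlo sampling checks use up to 50 000
draws with 3-standard-deviation bands.

## Known limitations

* Equivalence-class ambiguity: within-rank edges (behavior → behavior)
  are only sometimes orientable from observational data; a reversed
  within-rank edge changes intervention results. Category constraints
  orient all cross-rank edges.
* The scenario analysis quantifies effects *within the model*; it
  inherits every causal assumption of the learned graph and cannot
  adjust for unmeasured confounding.
* Multi-state variables are supported as roots in the generator's
  calibration (they are exogenous in the default truth); a multi-state
  child would need a different CPT family.
* N = 119-scale corpora support at most coarse structure; the package's
  defaults (parent cap 3, Laplace smoothing) are chosen for that scale,
  and learned CPTs at that size carry wide sampling error.
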