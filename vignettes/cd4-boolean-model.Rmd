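---
title: "Logical modeling of CD4+ T cell differentiation with cd4logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical modeling of CD4+ T cell differentiation with cd4logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4logic)
```

## The model and its assumptions

`cd4logic` models CD4+ T helper cell differentiation as a synchronous
Boolean regulatory network. Every node — a transcription factor, a cytokine
signaling pathway, or an extrinsic cytokine — carries a binary activity
value and a logical update rule; all nodes update simultaneously from the
same source state, so the dynamics is a deterministic map on `{0,1}^n`.
Attractors (fixed points or cycles of that map) are interpreted as stable
cellular expression phenotypes; the basin of attraction of an attractor
counts the initial states that reach it and serves as a crude measure of
how accessible the phenotype is.

The biological reading of the node classes:

* **Transcription factors** (TBET, GATA3, RORGT, FOXP3, BCL6): the
  lineage-defining master regulators. `1` means functionally expressed
  (for GATA3, the high expression state).
* **Intrinsic pathways** (IFNG, IL2, IL4, IL21, IL9, TGFB, IL10): "signal
  transduced" — the cytokine is present (produced by the cell itself or
  supplied from outside) and its STAT/SMAD messenger is active.
* **Extrinsic cytokines** (IFNGe, IL2e, IL4e, IL21e, TGFBe, IL10e):
  inputs. They carry the identity rule, so they hold whatever value the
  micro-environment sets and are never regulated by the network.

Standing assumptions baked into the bundled models: TCR engagement and
receptor expression are constitutive (resting/anergic cells are out of
scope); epigenetic regulation, IL-22/Th22 biology, and dendritic-cell
cytokines such as IL-12/IL-18 are not represented; the inflammatory STAT3
inputs (IL-6/IL-21) are merged into the single IL21 pathway node, kept
separate from IL-10's STAT3 signaling because their physiological effects
oppose each other.

## The bundled rule files and how they were constructed

Two models ship under `inst/extdata/` in BoolNet-style text format, plus a
SOCS-edge annotation table:

* `trn.bnet` — the 5-node transcription-factor core (no inputs),
* `tsrn.bnet` — the 18-node transcriptional–signaling network,
* `tsrn_socs_edges.csv` — the pathway-level inhibitions mediated by SOCS
  proteins; `load_model("TSRN_noSOCS")` removes exactly these edges from
  the rules programmatically (never by hand-editing a second file).

The exact truth tables of the original supplementary material were not
available to this package, so the bundled rules are a **reconstruction**:
the tables were built from canonical Th-differentiation regulatory logic
and then required to satisfy, simultaneously, the published qualitative
behaviour of the system —

1. the transcription-factor core alone yields exactly six fixed points
   (none, TBET, GATA3, FOXP3, TBET+FOXP3, GATA3+FOXP3) and can sustain
   neither RORγt nor Bcl6;
2. the full network's attractors over all `2^18` states fall into exactly
   eleven classes (Th0, Th1, Th2, GATA3+IL4-, Th17, iTreg, Tfh, Th9,
   TrFoxp3-, Th1R, Th2R), with no unclassifiable attractor;
3. every Th17 attractor requires extrinsic TGF-β, every iTreg attractor
   extrinsic IL-2, every Th9 attractor extrinsic IL-4 plus active TGF-β;
4. removing the SOCS-mediated edges preserves the original repertoire and
   adds exactly the RORγt+IL-10+ (Th17R) and GATA3+IL-10+IL-9+ (Th2RIL9+)
   classes;
5. IL-2 knockout eliminates every iTreg attractor in every environment.

Two structural choices were forced during this construction and are worth
knowing about. First, every self-sustaining factor carries an explicit
maintenance term (e.g. `TBET = (TBET | IFNG) & !GATA3`): under synchronous
updating, a two-node positive feedback loop *without* such terms always
admits a spurious anti-phase cycle, and delayed negative loops through
IL-10 generated rotating period-3 artifacts. Second, the pathway-level
inhibition structure is acyclic (IL-10 blocks effector pathways; nothing
blocks IL-10), for the same reason. With these choices the bundled TSRN
has 215 attractors, all fixed points, over the full state space.

The files are guarded by checksums recorded in the package; `load_model()`
refuses silently modified copies.

**Consequences for quantitative statistics.** All class-level, dependency
and mutant behaviour above is reproduced exactly and verified in the test
suite. Quantities that depend on the fine-grained shape of every truth
table — the overall transition percentages of the perturbation scan, the
cross-class transition census, and the bit-flip robustness fractions — are
emergent properties of the reconstruction and differ from the originally
printed values (the package measures, for example, an overall transition
fraction of ~16% where ~38% was reported). The acceptance test file states
both the measured and the reference values; treat the package's numbers as
properties of *these* rule files.

## Phenotype classification

`classify_attractor()` labels an attractor from the activity of marker
nodes, evaluated on nodes active in *every* state of the attractor (for
fixed points, simply the state). The rule table
(`inst/extdata/phenotype_rules.csv`) is declarative — required-on
conditions as AND-groups with OR-alternatives, required-off conditions,
and a priority — and the highest-priority match wins, so compound states
take their most specific label: Foxp3+ regulatory states are iTreg, not
TrFoxp3-; a Th9 signature (IL-9 on) outranks the Th2 signature it often
co-occurs with. Two classes (Th17R, Th2RIL9+) only arise in the
SOCS-removed variant; their rules are always loaded, which is harmless for
the wild type because their marker combinations do not occur there.

Th0 is the lowest-priority labeled class and is implemented as "no master
transcription factor, no regulatory cytokine (TGF-β/IL-10), no IL-9":
under a clamped micro-environment, attractors exist whose only active
intrinsic nodes are pathway echoes of the clamped inputs (e.g. IL-2
signaling on under IL-2e with everything else off), and the closed label
vocabulary reads these as resting cells rather than leaving them
unclassified. Attractors whose marker nodes oscillate (possible in
principle for cyclic attractors, which the bundled models do not have) are
reported as `"unclassified"`.

## Micro-environments, mutants

An environment clamps input nodes only. Named presets follow the standard
polarizing conditions — Th1 (IFN-γe), Th2 (IL-4e + IL-2e), Th17 (IL-21e +
TGF-βe), iTreg (TGF-βe + IL-2e), IL10 (IL-10e), Tfh (IL-21e), Th9 (IL-4e +
TGF-βe), Th0 (none) — and clamp the unlisted extrinsic nodes to 0. That
choice (rather than leaving them free) makes each preset a fully specified
condition directly comparable with the cytokine-free condition; the scan
over all 64 input combinations covers the free-combination reading, and
`make_environment(..., free_unlisted = TRUE)` selects the other convention
explicitly. Basin sizes are reported as raw counts (4096 per fully
specified environment); log-scaling is left to plotting.

Mutants clamp *any* node (0 = knock-out, 1 = over-expression) for the
entire simulation, on top of an optional environment. Clamping an input
through `simulate_mutant()` is verified to be identical to clamping it
through an environment.

## The plasticity protocol

A transient perturbation flips one node of an attractor state for exactly
one synchronous step; afterwards the node obeys its rule again. For
extrinsic inputs under a clamp, the clamp is suspended for that one step
and then restored — a one-step flip of an input is the model's version of
a temporary change in the micro-environment. Sustained alterations are
mutants, not perturbations.

Conventions used by `perturbation_scan()` and the statistics built on it:

* one event per (attractor, node) pair; for a cyclic attractor the
  canonical first state would be perturbed (a convention without effect in
  the bundled models, which have only fixed points);
* transition identity is judged at the phenotype-class level: landing in a
  different attractor of the same class counts as a self-loop, matching
  the fate-map reading where nodes are classes;
* fractions are micro-averaged over events (transitions ÷ perturbations);
  a macro-average (mean of per-attractor fractions) is reported alongside
  because averaging conventions differ between studies;
* activation events are flips 0→1 of a previously inactive node,
  inhibitions 1→0 of an active one.

Accounting identities (edges + self-loops = perturbations; per-node and
per-category tallies summing to the total) are enforced in the test suite.

## Functional robustness

`functional_robustness()` flips one truth-table entry at a time (input
identity rules are structural and excluded by default) and compares, for
every initial state of the full space with inputs free, the final
attractor against the unperturbed network's. Attractor identity across
networks uses the canonical state set, so a "novel" attractor is one whose
state set does not occur in the original network. Exhaustive mode
evaluates every flip (for the TSRN: 290 flips × 262144 states ≈ 7.6×10⁷
pairs, about half a minute); sampled mode draws flips evenly across nodes
with a recorded seed and converges to the exhaustive value as the sample
grows (verified on small networks).

## Network reduction

`substitute_node()` eliminates a non-self-regulated node by inlining its
rule into every rule that references it, recomputing truth tables exactly
(duplicate regulators merged, ineffective regulators dropped). Inlining
that would exceed a configurable regulator cap (default 16) is refused.
The method guarantees that fixed points of the original network, projected
onto the kept nodes, are fixed points of the reduced network — that is the
verification `reduce_network()` reports — but synchronous *cycles* are not
guaranteed to be preserved, and the report says so. Self-regulated nodes
and inputs are never removed.

## The continuous approximation

`fuzzify()` rewrites each truth table in disjunctive normal form and reads
it under Zadeh's fuzzy semantics (conjunction = min, disjunction = max,
negation = 1 − x), producing input functions `w_i(q)` that agree with the
Boolean rules exactly at every vertex of the unit hypercube (tested
exhaustively). The continuous dynamics is

```
dq_i/dt = 1 / (1 + exp(−2 b (w_i(q) − w_i^thr))) − α_i q_i
```

a steep sigmoidal activation minus linear relaxation: the canonical
smooth embedding of a logical system, chosen here because the saturation
limit is transparent — as the gain `b` grows the activation approaches a
Heaviside step at `w_i^thr`, and for `α = 1`, `w_thr = 0.5` every Boolean
fixed point becomes a continuous steady state. Defaults are `b = 10`,
`α_i = 1`, `w_i^thr = 0.5` (all configurable through
`continuous_params()`); at these values every fixed point of both bundled
models is recovered by `find_steady_states()` within L∞ distance 0.05 of
its 0/1 embedding, and is stable under ±0.05 perturbations of every node.
Integration uses `deSolve::lsoda` with absolute and relative tolerance
1e−8; a steady state is declared at field residual < 1e−6, and
re-convergence within 0.02 defines stability.

## Synthetic networks

`random_network()` (seeded, pure function of its arguments) draws
regulators uniformly and truth-table entries with a configurable bias;
`planted_fixed_point_network()` adjusts one table entry per node so a
chosen pattern is a fixed point; `toy_model_suite()` provides
hand-enumerable fixtures (toggle, relay, chain, self-activator,
feed-forward loop). These generators share the structural contract of the
biological models (named nodes, truth-table rules, identity-rule inputs),
so every pipeline stage is tested independently of the CD4 rules. They
emulate structure, not biology: random tables have no canalizing bias, no
scale-free topology and no signed-interaction realism, so passing tests on
them certify the *machinery* (enumeration, reduction, statistics,
fuzzification) — not the biological adequacy of any particular rule set.

## Numerical and engineering choices

* Exhaustive enumeration refuses state spaces above `2^22` states rather
  than silently sampling.
* Node order in state vectors is the declaration order of the rule file;
  cyclic attractors are rotated so their lexicographically smallest state
  (in that order) comes first, making canonical forms idempotent and
  deterministic.
* All outputs carry node names; no positional-only encodings cross a file
  boundary. Fate maps export to GraphML (primary) and DOT with basin-size
  and count attributes.
* Test problem sizes: oracle-equivalence checks run brute-force trajectory
  simulation on networks up to 10 nodes; robustness convergence checks use
  6-node networks; the continuous correspondence check integrates all TRN
  fixed points and one representative per TSRN phenotype class.

## Known limitations

* Synchronous updating only; asynchronous and probabilistic schemes are
  out of scope, and some reported behaviour (e.g. absence of cycles) is
  specific to the synchronous scheme.
* The rule files are a reconstruction (see above): class-level behaviour
  is faithful, fine-grained percentages are model-specific. In particular,
  the SOCS-removed variant cannot reproduce a *rise* in IL-10 sensitivity
  here, because in this reconstruction all of IL-10's outgoing influence
  is SOCS-mediated and removing those edges leaves IL-10 inert.
* Boolean abstraction: no graded cytokine doses, no kinetics, single-cell
  scope (no population dynamics), no epigenetic memory.
* The continuous module is a correspondence check, not a fitted kinetic
  model; its parameters are dimensionless defaults, not measurements.
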