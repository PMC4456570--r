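---
title: "Binding exteroceptive patterns to valences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding exteroceptive patterns to valences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoval)
```

## The problem

Episodic memory binds the sensory content of an experience to its affective
meaning in a single exposure. Modelling this is awkward because the two
kinds of information are wildly asymmetric: an exteroceptive stimulus here
is a 300-cell sparse binary pattern with 8 active cells, while its valence
is a 3-cell one-hot code. Stored together, exteroceptive features shared
between experiences of opposite valence inevitably become linked to both —
*valence overload*. Incremental learners solve this by slowly reshaping
representations over many repetitions; a hippocampus-like one-shot learner
cannot, and clipped binary synapses cannot unlearn at all. The model
implemented here resolves the conflict structurally instead: redundant,
prewired groups of valence cells plus inhibition, recruited one at a time
as conflicts are detected.

## Model

All memories are binary Willshaw networks. Storage is clipped Hebbian:
`w[i,j]` switches from 0 to 1 on a single pre/post coincidence and never
changes again — storage is therefore monotone and idempotent, two
invariants the test suite asserts directly. Recall is a single synchronous
pass: output cell `j` fires iff its dendritic sum reaches the threshold
`theta = ` number of active cue cells.

The architecture wires three plastic matrices — exteroceptive recurrent
`W_e` (300×300), interoceptive recurrent `W_i` (3×3), heteroassociative
`W_ev` (300×15) — and two fixed ones: inhibition among the `p = 5` groups
of intermediate valence cells (each cell inhibits all cells of *earlier*
groups) and a one-to-one projection from each valence cell to the
interoceptive cell of its valence.

A trial runs recall (complete the cue; excite valence cells; keep the
highest-indexed excited group; project and recall the predicted valence),
then matching (completion Hamming distance vs. threshold `e`; prediction
distance vs. threshold `v`; an active group mismatching the actual valence
by more than `v` raises interference and gates the next group), then —
only if a mismatch occurred — storage, with the heteroassociative write
directed at the highest-indexed gated group.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 300 | exteroceptive cells (dimensionless binary units) |
| `k` | 8 | active cells per pattern, ≈ log2(n); sparse enough for reliable Willshaw recall |
| `m` | 3 | valence cells: positive, negative, neutral, in that fixed order |
| `assoc_groups` | 4 | associated valence groups beyond the primary one (`p = 5`) |
| `e` | 0 | completion mismatch (Hamming distance) above which the input counts as novel |
| `v` | 0 | prediction mismatch above which valence is in error / a group interferes |
| `runs` | 20 | replicates per condition, summarised with Student-t 95% CIs |

Raising `e` makes the network tolerant of exteroceptive noise; raising `v`
makes it tolerant of valence change — the threshold experiment shows that
`v > 0` is what breaks adaptation, since recognised patterns with changed
valences are then silently accepted.

## What the generator emulates — and what it does not

`stimulus_set()` draws each pattern's 8 active cells uniformly without
replacement and assigns valences uniformly over the three labels; two
independent patterns share 8·8/300 ≈ 0.21 cells on average (asserted
against the hypergeometric expectation in the tests). This emulates
*decorrelated* hippocampal codes, i.e. it assumes upstream pattern
separation has already done its job. Real exteroceptive codes are
correlated and drift over time; none of that is modelled, so passing tests
says nothing about interference between *similar* exteroceptive patterns
(pattern overload), only about interference between valences. Duplicate
patterns are astronomically unlikely at these sizes and are not filtered.
The reversal task is the one structured generator: 8 cue cells and 8
disjoint 7-cell context blocks, combined into three 4-pattern groups with
the signed design (originals +, +, −, −; cue-reversed and context-reversed
groups carrying the opposite signs).

## Numerical and design choices

* **A cell exactly at threshold fires.** This makes full-cue recall of a
  stored pattern exact (every stored cell's dendritic sum equals `theta`).
* **Self-connections are stored.** The diagonal is included in
  autoassociative storage; at these loads recall behaviour only differs
  for single-cell cues, and including it is the literal clipped-Hebbian
  outer product.
* **Empty-cue guard.** `theta = 0` would fire every cell; an all-zero cue
  returns an all-zero output instead. A consequence worth knowing: a novel
  pattern completes to silence, so valence cells cannot fire for it, and
  interference can only ever be detected on a *re*-presentation — which is
  why detections first appear in training block 2 and why resolution needs
  multiple blocks.
* **One-pass inhibition.** Keeping only the highest-indexed excited group
  is the closed form of the shunting dynamics (later groups inhibit all
  earlier ones, nothing inhibits the last excited group); a sequential
  settling process reaches the same fixed point.
* **Interference is evaluated post-inhibition**, on the surviving group's
  activity. At most one group can therefore flag interference per trial,
  and escalation beyond the next group requires further trials.
* **Gating is per-trial.** The gate signals are recomputed from each
  trial's recall and discarded; the only persistent state is the weights.
* **Capacity exhaustion.** Interference at the last group has no group
  left to recruit; the heteroassociative write is skipped and the trial
  flagged, while the autoassociative stores still proceed. (Writing into
  an already-conflicted group could not resolve the conflict.)
* **Flat-model cue.** The concatenated baseline is cued with
  `[a_e | 0…0]` and `theta` counts only exteroceptive cells — the only
  convention under which full-cue recall of stored pairs is exact.
* **Indices are 1-based** (R convention); the primary valence group is
  group 1, associated groups 2–5.
* **Reproducibility.** Each driver takes one master seed and draws one
  sub-seed per run up front, so any individual run can be reproduced
  without running the ones before it.

## Expected crosstalk level

The baselines' error rate under full cues has a useful closed form. A
wrong valence cell fires for a stored pattern iff all `k` of its cells are
linked to that valence by other patterns. With `N` patterns, the
probability that a given cell is linked to a given wrong valence is
`1 − (1 − k/(3n))^(N−1)` (≈ 0.59 at `N = 100`), giving a per-pattern error
probability of about `1 − (1 − 0.59^8)² ≈ 3%` — zero for `N ≤ 40` at
plotting resolution, with onset around `N = 50`. The capacity driver and
`scripts/acceptance.R` compute the simulated value, which lands near this
expectation. The proposed model shows the same errors after one block
(interference is not yet detectable), then resolves them: re-presentation
triggers the mismatch, the association is rewritten into an associated
group, and that group's inhibition masks the conflicted primary group.

## Problem sizes used

The packaged tests and the acceptance script run the full study
conditions — `n = 300`, `k = 8`, up to `N = 100` stimuli, 20 replicate
runs, up to 5 training blocks — which complete in well under two minutes;
module-level property tests use reduced instances (`n ≤ 50`, and `n ≤ 12`
for the brute-force recall oracle) chosen to keep exhaustive checking
cheap while exercising every code path.

## Known limitations

* Valence only: arousal and other interoceptive dimensions, graded
  activity, and correlated exteroceptive statistics are out of scope.
* No forgetting and no capacity management beyond the associated groups;
  once all groups are conflicted for a cue, the model records exhaustion
  rather than resolving it.
* The storage/recall mode switch is abstract (a flag driven by the two
  novelty signals); no neuromodulatory dynamics are simulated.
* Recall is a single synchronous pass, not an attractor settling process;
  at the loads studied the fixed point coincides, but this is untested at
  high load by design (the study conditions keep exteroceptive recall
  error-free so that all observed errors are valence interference).
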