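# hippoval

Simulation of rapid, single-trial binding between what an animal perceives
and how it feels about it: sparse exteroceptive activity patterns are bound
to interoceptive valence codes (pleasant / unpleasant / neutral) inside a
network of interconnected binary associative memories modelled on the
hippocampus. The package is for computational-neuroscience work on episodic
memory, one-shot learning and interference: it provides the model, two
baseline architectures, the synthetic stimulus generators, and the
block/trial simulation protocols that characterise them.

## The model

All memories are binary Willshaw networks: clipped Hebbian synapses
`w_ij ∈ {0, 1}` that switch on after a single pre/post coincidence and never
decay, with one-pass threshold recall — output cell `j` fires iff

```
Σ_i w_ij · ã_i  ≥  θ,    θ = Σ_i ã_i
```

(the classical Willshaw threshold, the number of active cue cells; a cell
exactly at threshold fires). Exteroceptive patterns `a⁽ᵉ⁾ ∈ {0,1}ⁿ`
(n = 300, exactly 8 active) live in a recurrent autoassociative network
supporting pattern completion; valence codes `a⁽ⁱ⁾ ∈ {0,1}³` (one-hot) live
in a second, tiny autoassociative network. The two are linked
heteroassociatively through `p = 5` ordered groups of 3 intermediate valence
cells — one primary group plus 4 associated groups — where later groups
carry prewired inhibition onto all earlier ones, so at most one group is
ever active.

Because exteroceptive features vastly outnumber valence features, a cue can
become linked to contradictory valences ("valence overload": store AB+,
AC−, BD− and the cue AB excites both the positive and the negative cell).
The model detects this at recall — an active valence group whose pattern
mismatches the actual valence by more than a threshold `v` — and resolves it
without unlearning: the mismatch gates the next group, the association is
re-encoded there in one trial, and that group's inhibition silences the
conflicted one from then on. Two novelty signals (completion mismatch > `e`,
prediction mismatch > `v`; both default 0) switch the network from recall
to storage mode.

Two baselines frame the behaviour: a **flat autoassociative model** storing
the concatenation `[a⁽ᵉ⁾ | a⁽ⁱ⁾]` in one memory (completion and prediction
happen concurrently), and a **simple heteroassociative model** — the model
without associated groups (`p = 1`).

## Worked example

```r
library(hippoval)
df <- capacity_experiment(kinds = c("proposed", "simple_hetero"),
                          N = c(40, 100), blocks = 2, runs = 5, seed = 7)
summarize_experiment(df, "error_pct")
#>           model   N block mean ci_low ci_high n_runs
#> 1      proposed  40     1  0.0  0.000    0.00      5
#> 5      proposed  40     2  0.0  0.000    0.00      5
#> 3      proposed 100     1  2.2 -0.492    4.89      5
#> 7      proposed 100     2  0.0  0.000    0.00      5
#> 2 simple_hetero  40     1  0.0  0.000    0.00      5
#> 6 simple_hetero  40     2  0.0  0.000    0.00      5
#> 4 simple_hetero 100     1  2.2 -0.492    4.89      5
#> 8 simple_hetero 100     2  2.2 -0.492    4.89      5
```

`error_pct` is the percentage of stimuli whose predicted valence differs
from the true one on a full-cue test block after each training block, with
Student-t 95% confidence bounds over runs. At 40 stored patterns every model
is perfect after one exposure (single-trial learning). At 100 patterns,
valence-overload crosstalk produces errors in both architectures after the
first block; the proposed model detects the interference on the second pass,
re-encodes the conflicted associations into an associated group, and is
errorless from block 2 on — the reduced baseline stays wrong forever, since
clipped weights cannot unlearn.

For a narrated single-case walkthrough of the AB+/AC−/BD− conflict, run
`demo_interference()`.

The same drivers expose the other protocols: `partial_cue_experiment()`
(recall from degraded cues), `threshold_experiment()` (tolerance to valence
change under different `e`/`v` settings) and `reversal_experiment()` (the
12-pattern cue/context reversal task). Each is also available from a shell
via the installed `exec/hippoval` script, e.g.
`hippoval capacity --model all --runs 20 --seed 42 --out results/`.

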