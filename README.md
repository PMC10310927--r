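# colseq

Clock-driven simulator for a modular cortical-column spiking network that
learns both the **order** and the **duration** of stimulus sequences from a
globally broadcast reward/novelty signal, together with the full
training/recall protocol and the measurement procedures used to
characterize it.

## The model in brief

Each sequence element is represented by one *column* of four populations of
conductance-based leaky integrate-and-fire neurons: **Timer** (T) and
**Messenger** (M) excitatory cells plus inhibitory partners I<sub>T</sub>
and I<sub>M</sub>.  Membrane dynamics follow

    C_m dV/dt = g_L (V_rest − V) + g_exc (E_exc − V) + g_inh (E_inh − V) + ξ(t)

with saturating exponential synapses and a higher spike threshold for
inhibitory cells (−50 mV vs −55 mV), which makes I<sub>T</sub> rates decay
faster than the Timers' and opens a Messenger window at element offset.
Plastic synapses (recurrent T→T, feedforward M→T between columns) carry two
competing eligibility traces

    τ_a dT_a/dt = −T_a + η_a H (T_max,a − T_a),   a ∈ {p, d}

driven by a thresholded Hebbian rate term H.  A global 25 ms reward gate,
25 ms after each element boundary, converts the trace difference into
weight change, dw/dt = η R(t) (T_p − T_d), after which the traces are
consumed.  Recurrent learning converges when the two traces cancel at the
reward; the learned weight is the one that sustains Timer activity for the
element's duration, so interval timing is stored in recurrent weights and
transitions in feedforward ones.  Architecture variants: baseline (hard-wired
next-column projections), all-to-all cross-columnar projections, purely
local inhibition, and a size-scaled network.

## Worked example

```r
library(colseq)

net  <- build_network(n_columns = 2, seed = 1)   # two columns, 100 neurons/pop
seq2 <- fixture_sequence("two_element")          # two 700 ms elements
tr   <- run_training(net, seq2, n_trials = 100, seed = 11)
tr
#> <training_result> 100 trials on 2 elements
#>   final plastic means (nS):
#> T_T.T1_T1 T_T.T2_T2 M_T.M1_T2
#>    0.0440    0.0292    0.2987

rc <- run_recall(tr$net, seq2, n_trials = 10, seed = 21)
rt <- recall_times(rc)
aggregate(relative ~ column, rt, median)
#>   column relative
#> 1      1    748.5
#> 2      2    693.0
```

The recurrent weight of column 1 has converged near 0.04 nS — just enough
for its Timer to sustain activity up to the reward — and a single cue now
replays both elements: the *relative recall time* (the time from each
element's expected onset until its Timer rate drops below 10 spks/sec) is
close to the trained 700 ms for both columns.  `weight_trajectory()`, `convergence_trial()`,
`count_deviation_outliers()`, `modified_zscore()`, `recall_isi_cv()` and
`ordered_fraction()` implement the study's measurements;
`run_experiment()` packages whole protocols (e.g.
`run_experiment("all_to_all_high_threshold")`), and
`inst/cli/colseq.R` exposes them from a shell.

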