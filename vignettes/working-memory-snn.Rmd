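---
title: "Working memory in spiking neural networks: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working memory in spiking neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnwm)
```

## The problem

A classic spiking neuron aggregates input in one direction only: the
membrane potential at time $t$ is dominated by the most recent spikes,
older input survives only through a geometrically decaying leak, and a
firing event erases even that by resetting the membrane. A network of
such neurons therefore has a short effective temporal receptive field.
Whether a classifier can use *global* temporal structure — e.g. tell
"motif A then motif B" from "B then A" — is exactly what this limitation
threatens, and it also makes the network sensitive to *when* within a
short span spikes happen to land (uneven spike density), not only to
which spikes occur.

This package implements and tests one remedy: give each connection a
group of dendrites with different transmission delays, so that a neuron
at time $t$ sees a weighted window of the past rather than a single
instant, and optionally *rectify* that window — a working-memory
mechanism that aggregates all spikes within a fixed-length window and
feeds the aggregate to the neuron throughout the window.

## Model

### Membrane dynamics

The discrete-time leaky integrate-and-fire (LIF) neuron $j$ updates as

$$V_j(t) = e^{-1/\tau}\, V_j(t-1) + I_j(t),$$

fires $s_j(t) = H(V_j(t) - \theta)$ with the convention $H(0)=1$ (a
membrane exactly at threshold fires), and is hard-reset,

$$V_j(t) \leftarrow V_j(t)\,(1 - s_j(t)) + V_{rest}\, s_j(t),$$

at the same timestep. The spike-response kernel is the identity: a
presynaptic spike contributes its synaptic weight directly to the drive.
Setting $\tau = \infty$ (leak 1) recovers the non-leaky
integrate-and-fire neuron; `leak_factor()`, `lif_step()` and `lif_run()`
expose these pieces directly. Time is 0-based in the event notation and
1-based in R matrices; membranes start at $V_{rest}$ unless a `V0` is
given.

### Multi-delay dendrites and the factorized kernel

With $N_k$ dendrite groups of integer delays $d_k$, the drive becomes

$$I_j(t) = \sum_{k=1}^{N_k} \sum_i w_{ijk}\, s_i(t - d_k),$$

a tensor of $N_i N_j N_k$ weights (`dense_delay_drive()`, kept as the
brute-force reference). The factorized form shares one spatial matrix
across groups and one temporal tap per group,
$w_{ijk} = w_k\, w_{ij}$, cutting the count to $N_i N_j + N_k$ — only
$N_k$ more than a classic layer — and making the drive a spatial
projection followed by a causal 1-d temporal convolution
(`factorized_delay_drive()`). Spikes at negative times are zero (causal
zero-padding). Delay sets are arithmetic, $\{0, 1, \dots, L-1\}$, shared
by all synapses of a layer and identical between adjacent layers.

### Working-memory rectification

In segment mode (`segment_drive()`) the train is cut into
non-overlapping windows of length `mem_len`; window
$m = \lfloor t / \texttt{mem\_len} \rfloor$ aggregates its spikes once,

$$I_j^{(m)} = \sum_{p=0}^{L-1} w_p \sum_i w_{ij}\, s_i(mL + p),$$

and this constant drive is delivered at every step of the window. The
temporal taps are indexed by within-window position $p$ in ascending
time, which is the same thing as delays $L-1-p$ referenced to the window
end; we fix this convention to remove the sign ambiguity between
"delay" and "position". With uniform taps the drive — and everything
downstream of it, given the window-entry membrane state — is invariant
to any permutation of spike times inside a window: the rectification
property, tested as such.

One published description of this mechanism indexes the input as
$s_i(t - d_k - m)$, which conflicts with the accompanying pseudocode and
prose (segment-constant drive, all window spikes fed continuously for
`mem_len` steps). Both cannot hold at once; this package implements the
segment-constant semantics, which the pseudocode and the hardware
scheduling argument agree on.

### Temporal fusion readout

The decoding layer (`fusion_head()`, `temporal_fusion()`) weights the
spikes of *every* timestep of the final hidden train,

$$o_j = \sum_{t=1}^{T} w_t \sum_i w_{ij}\, s_i(t),$$

emitted once per sample, with no leak and no threshold; the $o_j$ are
used as class logits. The delay set written as $\{0, \dots, T\}$ would
hold $T+1$ taps for $T$ timesteps; we resolve the off-by-one in favor of
exactly $T$ taps, one per timestep. A "count" variant fixes all taps at
1 (untrainable), reducing the readout to a spike-count decoder — the
natural time-blind baseline.

## Training

Networks are trained by backpropagation through the unrolled dynamics in
both the layer and the time dimension. The forward pass uses the exact
hard threshold; the backward pass substitutes the exponential surrogate

$$\frac{\partial H}{\partial x} \approx e^{-2x^2}, \qquad x = V - \theta,$$

at every firing decision. The surrogate peaks at 1 on the threshold and
never vanishes for finite $x$, so some gradient flows even far from
threshold. By default the gradient also passes through the reset product
$V(1-s) + V_{rest}s$ exactly as written; `detach_reset = TRUE` treats
the spike inside the reset as a constant, a common alternative, and both
variants are checked against the oracle below.

Correctness of the hand-derived backward recurrences is established
against an independent tape-based reverse-mode autodiff engine (in the
test suite) that implements the same surrogate rule as a custom
vector-Jacobian product: on random small networks covering every mode,
readout, loss and reset variant, the two agree to better than $10^{-6}$
(observed: machine precision).

Choices the underlying method description leaves open, decided here:

* **Loss.** Cross-entropy on the fusion logits (default) — the readout
  is a real-valued membrane-like quantity, i.e. a natural logit; MSE
  against one-hot targets is available.
* **Initialization.** Spatial matrices by width-scaled uniform (Glorot)
  draws; temporal taps at the window average $1/N_k$, so segment and
  classic modes start from comparable drive scales; fusion taps at
  $1/T$.
* **Optimizer.** Desk-scale default Adam, learning rate $10^{-3}$,
  batch 32 (`training_preset("desk")`). The GPU-scale benchmark
  hyperparameters are shipped as named presets for fidelity only.
* **T not divisible by `mem_len`.** Strict mode errors; zero-padding
  the final window changes drive magnitude, so it is opt-in
  (`pad = "zero"`).

## Spike encoders

`direct_encode()` injects normalized values as constant current.
`rate_encode()` realizes Poisson rate coding as per-step
Bernoulli($p =$ value) draws — the standard discrete-time
approximation. `latency_encode()` maps a value $v > 0$ to a single
spike at $t = \mathrm{round}((1-v)(T-1))$ — linear, earliest spike for
the strongest input — and emits nothing for $v = 0$: a zero-intensity
input should not inject the strongest-latency event. The linear mapping
and the $v=0$ convention are this package's choices; the method
description names the coding families without fixing either. The
bit-string notation (`parse_bitstring("010110")`) and an event-list CSV
format round out the I/O.

## Synthetic tasks: what they emulate and what they do not

No external datasets are used; two generator families produce exactly
the structure the working-memory mechanism claims to exploit.

* **Order task** (`make_order_task()`): two binary motifs A and B
  (drawn once per seed, spike density 0.3) are placed in the two halves
  of a $T = 32$, 16-neuron train — A-then-B for class 0, B-then-A for
  class 1 — each jittered by up to ±2 steps, plus background spikes at
  rate 0.02. Both classes contain both motifs exactly once, so
  per-neuron spike counts are identically distributed across classes
  (verified by a KS test at $n = 2000$): a time-blind readout cannot
  systematically beat chance, and only global order is informative.
  Motifs are centred in their halves, which requires
  `motif_len + 2*jitter <= T/2`; violating placements error rather than
  retry, since placement is deterministic per half.
* **Density task** (`make_density_task()`): the class-informative motif
  occupies exactly one aligned window of length `motif_len`, uniformly
  chosen; classes differ in *which* motif appears, never *when*. This
  produces the extreme uneven-density regime that windowed aggregation
  is meant to absorb.

Defaults ($n = 2000$, $T = 32$, 16 neurons, motif length 8, jitter 2,
noise 0.02) are sized so that the full five-repetition training protocol
runs in minutes on one CPU. The generators emulate temporal order and
density structure only; they do not reproduce the spatial statistics,
channel correlations or label noise of natural images or event-camera
streams, so passing the learning checks demonstrates the temporal
mechanism, not benchmark-scale vision performance.

## Cost models

`parameter_count()` implements the two closed forms above.
`state_memory_accesses()` formalizes the hardware-scheduling claim: a
classic schedule fetches and stores the membrane state every timestep
($2T$ accesses per neuron group per sample), while the windowed schedule
touches the store only at window boundaries
($2\lceil T/L \rceil$), an exact factor-$L$ saving when $L \mid T$.
The underlying claim is qualitative; the $2T$ vs $2\lceil T/L\rceil$
model is this package's formalization, and
`lif_run_instrumented()` validates it by actually running the dynamics
against an emulated backing store and counting — while producing
bit-identical traces to `lif_run()`. Input/output spike traffic is the
same under both schedules and is excluded; weight-memory traffic is not
modelled.

## Experiment harness

`validate_config()` / `run_experiment()` drive YAML-configured
experiments: per seed (and per working-memory length in a sweep),
generate data, split, build, train, evaluate; aggregate mean ± sd over
seeds, echoing the five-repetition protocol. Timing (training,
single-sample inference) is recorded but hardware-dependent, so it is
reported and never asserted, and it is kept out of the deterministic
metrics file. Two presets ship under
`system.file("extdata", "configs", package = "snnwm")`: the full-scale
order-task experiment and a desk-scale density sweep over
$L \in \{1, 2, 4, 8\}$ (512 samples, 8 epochs, 2 seeds) whose accuracy
trend is reported, not asserted — at this scale the density task is easy
at every $L$, so the sweep demonstrates the mechanism and determinism,
not a performance ranking.

## Numerical and degenerate-input conventions

* Threshold comparison is $\geq$; ties in the argmax prediction go to
  the lowest class index.
* Non-finite drives, non-binary spike matrices, shape mismatches and
  out-of-bound events are errors, not warnings.
* A training step that produces a non-finite loss aborts with the seed
  and configuration echoed.
* All generators, encoders and fits are pure functions of their
  arguments and seed; seeded helpers restore the caller's RNG state.

## Known limitations

* Dense layers only — no convolutional or residual stacks, no
  event-camera ingestion; those belong to benchmark-scale replication,
  which is out of scope here.
* Per-synapse trainable delays, recurrent connections, attention
  modules, adaptive thresholds and trainable $\tau$ are deliberately
  not implemented.
* The exponential surrogate is the only one provided.
* Training is single-threaded CPU R; it is sized for the synthetic
  tasks, not for image benchmarks.
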