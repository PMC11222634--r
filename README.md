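# hrmas

Recurrent spiking neural networks (RSNNs) are usually wired at random:
reservoir-style layers pick their recurrent connections by a probability,
not by optimization, and that choice caps what the network can learn. This
package is for computational-neuroscience and neuromorphic-computing work
that wants the recurrent wiring itself to be *searched*. It composes the
recurrent layer from small repeated **motifs** — a Sparsely-Connected
Recurrent Motif Layer (SC-ML), with full candidate connectivity inside each
motif and sparse corresponding-neuron links between adjacent motifs — and
optimizes motif size and per-synapse connection type with **HRMAS**, a
hybrid risk-mitigating architecture search.

The moving parts, all implemented here in plain R:

* **Dynamics** — discrete-time leaky integrate-and-fire neurons with
  first-order synapses (1 ms Euler steps):
  `a[t] = (1 − 1/τ_syn)a[t−1] + s[t]`,
  `u⁻[t] = (1 − 1/τ_m)u[t−1] + (R/τ_m)Σ w a[t]`, spike-and-reset at
  threshold.
* **Relaxation** — categorical choices (motif size `v ∈ V`; per-slot type
  excitatory / inhibitory / none) become softmax mixtures `α̂`, so the
  architecture trains by gradient descent; discretization takes argmaxes.
  Candidate slots number `(n/v)·v² + 2(n − v)` — linear in `n`, against
  `n²` dense (3,196 vs 640,000 at `n = 800`, `v = 2`).
* **Training** — surrogate-gradient backpropagation through time for
  weights and architecture logits, and a second-order bi-level update for
  the logits: validation-loss gradient at one-step-look-ahead weights minus
  a finite-difference mixed-derivative correction,
  `∇α̂ L_valid(α̂, w′) − (η/2ε)(∇α̂ L_train(w⁺) − ∇α̂ L_train(w⁻))`.
* **Intrinsic plasticity** — a SpiKL-IP-style homeostatic rule adapts each
  recurrent neuron's `R` and `τ_m` between architecture updates, descending
  the KL divergence from the neuron's rate distribution to an exponential
  with target mean `μ`; it holds firing near `μ` across an order of
  magnitude of drive and stabilizes the search against structural changes.
* **Synthetic tasks** — jittered spatiotemporal pattern classification and
  a teacher RSNN with a planted motif size, so everything is testable with
  no downloads.

## Worked example

Search an architecture for a jittered two-class spike-pattern task:

```r
library(hrmas)

ds <- make_pattern_task(n_classes = 2, n_in = 16, T_steps = 50,
                        jitter_sd = 4, noise_rate = 0.02,
                        n_per_class = 60, seed = 42)
ds
#> <spike_dataset> 120 samples x 16 channels x 50 steps, 2 classes (pattern)

sp  <- split_dataset(ds, frac = 2/3, seed = 43)   # train / held-out test
res <- hrmas_search(sp$a, sp$b, default_config(), seed = 44)
res
#> <search_result> motif size 4, test accuracy 1.000 (seed 44)
```

The search ran the alternating two-step optimization (bi-level architecture
updates plus weight updates, then an intrinsic-plasticity window), froze the
motif size at 4 neurons, discretized the connection types, retrained from
scratch and scored the untouched test set once — here perfectly. The
discrete architecture is a small sparse object:

```r
table(res$architecture$type_matrix[res$architecture$type_matrix != ""])
#>  E  I  N
#> 24 12 52
cat(arch_to_json(res$architecture))
#> {
#>   "n": 16,
#>   "motif_size": 4,
#>   "tying": "shared_topology",
#>   "slot_types": [3, 3, 1, 1, 3, 3, 3, 3, 3, 3, 1, 3, 2, 2, 2, 3, 1, 3],
#>   ...
```

Of the 88 candidate recurrent connections, 24 came out excitatory
(trainable), 12 inhibitory (fixed at −2) and 52 non-existent — the search
buys sparsity wherever a connection does not help validation loss. Ablation
variants (`hrmas_ablate()`: `no_ip`, `no_motif`, `no_inter_motif`,
`fully_connected`, `random`) and a command-line interface
(`inst/exec/hrmas` with `generate-data` / `search` / `retrain` / `eval` /
`ablate` subcommands) wrap the same functions.

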