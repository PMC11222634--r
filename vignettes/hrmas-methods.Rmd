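---
title: "Motif-structured recurrent spiking networks and their architecture search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-structured recurrent spiking networks and their architecture search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmas)
```

## The model

All simulations use the discrete-time leaky integrate-and-fire (LIF) neuron
with a first-order synapse, integrated by a fixed 1 ms Euler step, so every
time constant is expressed directly in steps. A presynaptic spike train
$s_j[t]$ is low-pass filtered into an unweighted postsynaptic current (PSC)

$$a_j[t] = \left(1 - \tfrac{1}{\tau_{syn}}\right) a_j[t-1] + s_j[t],$$

and the membrane potential of neuron $i$ integrates the weighted PSCs with
leak resistance $R$ and membrane time constant $\tau_m$:

$$u_i^-[t] = \left(1 - \tfrac{1}{\tau_m}\right) u_i[t-1]
  + \tfrac{R}{\tau_m} \textstyle\sum_j w_{ij} a_j[t],$$

with a spike $s_i[t] = 1$ and reset $u_i[t] = 0$ whenever
$u_i^-[t] \ge V_{th}$. Spike and reset share the same condition
(`>=` rather than a strict inequality for one and a Heaviside at zero for the
other), so the two can never disagree; exact threshold equality is
measure-zero in floating point. Initial conditions are the rest state
($u = a = 0$), there is no refractory period, feedforward connections act
without delay, and recurrent connections act with a one-step delay.

## The SC-ML layer and its search space

The hidden layer is a sparsely-connected recurrent motif layer (SC-ML): for a
motif size $v$ dividing the layer size $n$, neurons tile into $n/v$ motifs
with full within-motif candidate connectivity (self-loops included) and
mutual "corresponding-neuron" links between adjacent motifs
($r = i \pm v$, truncated at the layer edges — no wrap-around, in keeping
with the spatial-locality reading of the index rule). Every candidate pair
carries a categorical connection type: excitatory (trainable weight,
initialized at 0.2), inhibitory (fixed at $-2$, never trained), or
non-existent. The candidate-slot count is $(n/v)\,v^2 + 2(n - v)$, linear in
$n$ at fixed $v$ against $n^2$ for a dense recurrent matrix; at $n = 800$,
$v = 2$ that is 3,196 against 640,000.

Architecture choices are relaxed to softmax mixtures: one simplex over the
motif-size options and, per candidate slot, one simplex over the three types.
The forward pass runs the *mixture*: the effective recurrent matrix is the
probability-weighted sum over motif sizes and types. Discretization takes
the argmax of each simplex (ties resolve to the lowest index) and yields an
explicit sparse weight matrix; a one-hot mixture reproduces that discrete
network bit for bit, which the test suite asserts as an exact invariant.

**Parameter tying.** The motifs of an SC-ML share one topology, yet the
per-pair relaxation nominally gives every pair its own logits. The default
`shared_topology` mode ties type logits across motifs by relative position
($(i \bmod v,\, r \bmod v)$ for intra-motif slots, one logit row per
direction for inter-motif links), so the searched object is a single motif
template; weights remain untied per connection. An `untied` mode keeps the
literal per-pair indexing.

**Type-logit initialization.** Logits start uniform except that the
inhibitory logit is offset to $\log(w_{exc}/|w_{inh}|)$, making each slot's
*expected* initial weight exactly zero. With fully uniform logits the
$\tfrac13 w_{exc} + \tfrac13 w_{inh}$ mix is strongly negative, and the
earliest motif-size gradients then rank options by total inhibition load
rather than by fit — denser options lose regardless of merit. The zero-mean
start removes that artifact and measurably improves architecture recovery.

## Training and the bi-level architecture update

The loss compares output-layer PSCs against a desired trace: the target
class should fire at every step (its desired PSC is the saturating trace
$\tau_{syn}(1 - (1 - 1/\tau_{syn})^t)$), all other classes are silenced, and
$L = \sum_t \sum_o \tfrac12 (d_o[t] - a_o[t])^2$, averaged over the batch.
Classification reads the argmax of the accumulated output PSC.

Gradients are exact backpropagation through time over the retained forward
histories, with the non-differentiable spike replaced by a pluggable
surrogate kernel (`bump` Gaussian by default; `sigmoid` and `triangle`
alternatives), unimodal at $V_{th}$ and integrating to one. The same
backward code run in `smooth` mode — where the forward spike is a logistic
of width `width` and the kernel is its exact derivative — differentiates the
smooth graph exactly, which is how the suite checks every gradient against
central finite differences (relative error below $10^{-4}$; measured around
$10^{-8}$). Reset is treated as the multiplicative gate $u = u^-(1 - s)$ and
differentiated through the same kernel. When intrinsic plasticity is active,
the stored per-timestep $R_i[t]$, $\tau_i[t]$ enter the chain as
time-varying coefficients; their own dependence on past spiking is not
differentiated.

The architecture logits follow a one-step look-ahead bi-level update: with
$w' = w - \eta \nabla_w L_{train}$, the update direction is
$\nabla_\alpha L_{valid}(\alpha, w')$ minus the second-order correction
$\tfrac{\eta}{2\epsilon}\left(\nabla_\alpha L_{train}(w^+) -
\nabla_\alpha L_{train}(w^-)\right)$ with
$w^\pm = w \pm \epsilon \nabla_w L_{valid}(\alpha, w')$. By default
$\eta$ equals the weight learning rate and $\epsilon$ is scaled as
$0.01 / \lVert \nabla_w L_{valid} \rVert$; $\eta = 0$ falls back to the
first-order update exactly. Both weights and logits use Adam. The update is
computed in logit space; since the softmax Jacobian is applied consistently
to every term, this is the exact logit-space version of the
probability-space formula.

## Intrinsic plasticity

Between architecture updates, each recurrent neuron adapts its own $R$ and
$\tau_m$ to stabilize firing after structural change. The rate estimate is a
calcium trace, $\phi[t] = (1 - 1/\tau_{cal})\phi[t-1] + s[t]$,
$y = \phi/\tau_{cal}$. The rule descends the KL divergence between an
exponential rate distribution at the neuron's current mean rate and a target
exponential with mean $\mu$,
$D = \log(\mu/y) + y/\mu - 1$, chained through the deterministic LIF rate
map $y = 1/(\tau \log(Rx/(Rx - V_{th})))$:

$$\Delta\tau = \frac{1 - y/\mu}{\tau}, \qquad
  \Delta R = \frac{y \tau W (y/\mu - 1)}{R}, \qquad
  W = e^{1/(\tau y)} - 1,$$

applied as $\theta \leftarrow \theta - \gamma \Delta\theta$ with clamps
$R \in [0.1, 10]$, $\tau \in [2, 256]$ and a rate floor of $10^{-4}$ for
silent neurons (whose huge $W$ then drives a fast, clipped increase in
excitability). Two deliberate design choices matter:

* **A sensitivity-seeking formulation was rejected.** The Triesch-style
  sample loss $-\log(\partial y/\partial x) + y/\mu$ has a genuine
  singularity for a hard-threshold LIF: the input–rate map's slope diverges
  at threshold, so exact gradient descent drives $R$ toward the threshold
  from above and silences every neuron (verified symbolically and in closed
  loop). The exponential-to-exponential KL above has its fixed point exactly
  at $y = \mu$ and no singularity.
* **The update reads a doubly-filtered rate.** Under near-periodic firing
  the calcium trace ripples within each inter-spike interval
  ($\tau_{cal} = 16$ steps against a target period of $1/\mu = 20$), and the
  update's nonlinearity in $y$ rectifies that ripple into an 8–9% bias of
  the closed-loop fixed point. A second low-pass ($\tau_{avg} = 64$)
  removes it; the measured long-run rate then sits within a few percent of
  $\mu$ across a more than tenfold drive range, while fixed-parameter
  neurons over the same sweep range from silent to saturated.
* **$\tau$ regulates, $R$ ranges.** The $\tau$ update's stationary point is
  exactly $y = \mu$; the $R$ component (applied with a 10× smaller gain and
  clipped) performs coarse range-finding so that $\tau$'s regulation stays
  inside its clamp window. Both components are positive rescalings of the
  exact gradient, so descent of the objective is preserved.

IP runs during the search's second step (one mini-batch window per
iteration, pooling spikes across the batch by their mean) and is off by
default during post-search retraining; a configuration flag re-enables it.
$\mu$ defaults to 0.05 spikes per step — 50 Hz at the 1 ms step, a
plausible cortical working rate.

## The search protocol

Each search iteration alternates (1) one bi-level architecture update on a
validation batch plus one Adam weight update on a training batch, and (2)
the IP window. The schedule is incremental: a weight-only warm-up (10
iterations — architecture gradients taken at random weights mostly measure
drive level), then joint motif-size and type search (`stage1_iters`, 60 by
default), then motif size is frozen and types alone continue
(`stage2_iters`, 30). The freeze takes the argmax of a Polyak-style average
of the motif-size logits (EMA coefficient 0.9) rather than the last iterate,
damping mini-batch noise in a decision that cannot be revisited; after
freezing, the motif-size simplex is pinned one-hot and receives no further
updates. Finally the architecture is discretized, all weights are
reinitialized (He-normal feedforward draws, excitatory candidates back to
0.2), the network retrains on the full training set, and the held-out test
set is touched exactly once — the result object carries an access counter
the tests assert on.

The provided training set is split 50/50 into training and validation
subsets, stratified by class and deterministic under the run seed. All
randomness flows from one master seed through a fixed child-seed derivation,
so every result is exactly reproducible.

**Architecture learning rate.** At desk scale the search runs tens, not
thousands, of iterations; with an architecture learning rate far below the
weight rate the motif-size softmax never leaves uniform and the freeze
decision degenerates to a coin flip. The default is therefore
`lr_alpha = 0.1` against `lr = 0.005` — deliberately the opposite ordering
of what long-schedule differentiable-architecture-search practice uses.

**Ablation switches.** `no_ip` skips step 2; `no_motif` sets the motif size
to the layer size (all pairwise types searched, no motif structure);
`no_inter_motif` removes the corresponding-neuron candidate links;
`fully_connected` trains a dense all-excitatory recurrent layer with no
search; `random` samples discrete architectures uniformly from the same
space, trains each briefly, and retrains the best — the equal-budget
baseline.

## Synthetic tasks

Two generators make the whole pipeline testable without external data.

`make_pattern_task()` draws one random spatiotemporal spike template per
class and emits Gaussian-time-jittered copies with optional Poisson
background noise. A `timing_only` variant assigns channels round-robin so
every class shares identical per-channel spike counts and only *timing*
separates the classes; without it, channel-count profiles are
jitter-invariant and a rate readout can sidestep timing entirely, which is
exactly what the jitter-degradation property test needs to rule out.

`make_teacher_task()` builds a random discrete SC-ML network with a planted
motif size (types drawn excitation-dominant at 0.55/0.20/0.25, mirroring
the excitatory bias of cortical wiring; excitatory weights uniform on
[0.1, 0.5]), drives it with Poisson input spikes, and labels samples by the
teacher's readout argmax; draws in which any class falls below 10%
prevalence are rejected and redrawn. The teacher is attached to the dataset,
so tests can verify it scores perfectly on its own labels.

**What recovery does and does not show.** With 16 neurons and freely
trainable feedforward weights, the function classes of the two candidate
motif sizes overlap substantially — fully trained one-hot students differ by
only a few percent in validation loss — so the recovery signal available to
*any* search method is small relative to mini-batch noise. Under the default
conditions (options $\{2, 8\}$, planted size 8) the search recovers the
planted size in about 85% of runs (34/40 in a development measurement);
five-seed panels therefore usually, but not always, reach 4/5. Planting the
larger option is the well-posed direction: the larger motif's candidate set
nearly nests the smaller one's connectivity, so preferring the small motif
when it is the truth would additionally require a complexity penalty this
method does not include. Passing these tests shows the machinery
discriminates architecture quality on data built to contain such a signal;
it does not establish recovery rates on real recordings, where the signal
structure is unknown.

## Numerical choices and limitations

* Simulation horizons, layer sizes and schedule lengths default to
  desk scale (16 channels, 16 hidden neurons, $T = 50$, 200 samples,
  60 + 30 search iterations): a full search runs in seconds and the whole
  verification suite in about two minutes on one CPU. The named
  `table1-*` presets carry the benchmark-scale constants
  ($\tau_m$ 16/64 steps, $\tau_{syn} = 8$, $\tau_{cal} = 16$, layer sizes
  512/800, motif options $\{5,10,16,25,40\}$ or $\{2,4,8,16,32\}$) for runs
  at that scale.
* Surrogate width defaults to 0.5 potential units; the finite-difference
  checks use the logistic smooth mode at width 0.3.
* Exact softmax ties discretize to the lowest-index option, making
  discretization deterministic.
* Divergence (non-finite loss) aborts a search with a diagnostic rather
  than continuing.
* The asymptotic count of inter-motif links is $2(n - v)$ directed pairs by
  the corresponding-neuron index rule implemented here; loose $O(n/v)$
  statements for that quantity undercount it by a factor of $v$, and the
  package consistently reports the enumerated value.
* Batch gradients are averaged over the batch; IP pools batch spikes by
  their mean, a deliberate departure from strictly per-sample adaptation
  that keeps a single intrinsic state per neuron.
* HDF5 containers are not supported; datasets travel as the plain-text
  event-list TSV dialect (`write_dataset()` / `read_dataset()`), which
  round-trips bit-exactly and fails loudly on truncation.
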