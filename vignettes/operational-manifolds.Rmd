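---
title: "Operational manifolds, efficiency scores and drift diagnostics for spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational manifolds, efficiency scores and drift diagnostics for spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnmanifold)
```

## The model

Every spiking layer in this package is a population of discrete-time leaky
integrate-and-fire (LIF) neurons updated with a forward-Euler step. With leak
factor $\alpha = \Delta t / \tau_m$, membrane potential $V$, synaptic current
$I$ and spike indicator $S \in \{0, 1\}$, a step for one neuron is

$$V_{\text{pre}} = (1 - \alpha)\,V + I, \qquad
  S = \mathbb{1}\!\left[V_{\text{pre}} \ge V_{\text{th}}\right],$$

followed by exactly one reset, according to the configured mode: *hard*
(clamp to $V_\text{reset}$, the default) or *soft* (subtract $V_\text{th}$).
Written as a single recurrence the dynamics would contain both a subtractive
reset term and a clamp; applying both would reset spiking membranes twice, so
the package commits to reset-once-per-step by mode. Neurons that spike enter
an absolute refractory period of `t_ref` steps during which they do not
integrate and cannot fire; the default is `t_ref = 0` since the sweeps vary
only $(\tau_m, V_{\text{th}})$. The spike condition uses $\ge$, membranes
initialize exactly at $V_\text{reset}$ (an optional jitter would only blur
the deterministic tests and is not provided), and $\Delta t$ defaults to
1 ms, so $\alpha = 1/\tau_m$ with $\tau_m$ in milliseconds — consistent with
a sweep lower bound of $\tau_m = 1.001$ keeping $\alpha < 1$.

Units follow the field's conventions: $\tau_m$ and $\Delta t$ in ms,
$V_\text{th}$ and $V_\text{reset}$ in volts, rates in spikes per neuron per
timestep.

## Architectures, normalization, training

Two families are provided, mirroring common small spiking baselines. The MLP
family chains `linear -> batch norm -> LIF` blocks (reference hidden sizes
512/256/64 for a 784-input task; the desk-scale experiments here use 32/16)
into a `linear -> LIF` readout without normalization. The conv family stacks
two `conv(3x3, stride 1, pad 1) -> batch norm -> LIF -> maxpool(2x2)` blocks
(64 then 128 channels at reference scale), global average pooling, one fully
connected spiking block and the readout. All spiking layers share one neuron
configuration. Decisions accumulate the readout's output spike train as an
average over the $T$-step window; ties decode to the lowest class index, and
an all-silent readout is decoded (label 0) but flagged degenerate.

Batch normalization sits between the affine transform and the spiking
nonlinearity, with one set of parameters and running statistics shared across
timesteps (per-timestep statistics would make the module depend on the
horizon $T$). At initialization the inference transform is *exactly* the
identity: the running variance starts at $1 - \varepsilon$ so that
$1/\sqrt{\sigma^2 + \varepsilon} = 1$, which keeps untrained-network tests
analytic. Recurrent variants add a term $W_{\text{rec}} S^{t-1}$ to the last
hidden layer's pre-normalization activation, with $W_{\text{rec}}$
initialized near zero.

Training is backpropagation through time over the unrolled dynamics with the
arctangent surrogate: the spike indicator's derivative is replaced by

$$g(u) = \frac{s}{1 + (\pi s u)^2}, \qquad u = V_{\text{pre}} - V_{\text{th}},$$

with slope $s = 2$ by default (exposed in `training_config()`). Gradients
also flow through the reset term, so the backward pass computes exactly the
gradient of the smooth relaxation in which every Heaviside is replaced by
$\tfrac12 + \tfrac1\pi \arctan(\pi s u)$ — that is what makes the
finite-difference gradient check in the test suite exact to $10^{-4}$ rather
than approximate. The loss is cross-entropy on the softmax of the per-class
mean output spike counts, optimized with Adam at the conventional
$(\beta_1, \beta_2, \varepsilon) = (0.9, 0.999, 10^{-8})$ and learning rate
$10^{-3}$; none of these are reported quantities, so they stay at their
textbook values. Training applies the configured membrane policy between
batches and is fully reproducible under its seed.

## Encoding

Static images are rate coded: each pixel of intensity $p \in [0,1]$ emits an
independent Bernoulli($p$) spike per timestep — the standard discrete-time
reading of Poisson encoding — over $T = 10$ steps by default. Event streams
are binned into $T$ uniform half-open intervals
$[k \cdot \text{dur}/T, (k+1) \cdot \text{dur}/T)$ with polarity separated in
the channel dimension; the final instant maps into the last bin. Cells hold
binary occupancy by default (so downstream layers receive spikes, not
counts); a count mode is available behind a flag.

## The operational manifold

For a trained configuration $\theta = (\tau_m, V_{\text{th}})$ the mean
network firing rate is

$$\bar r(\theta) = \frac{1}{N} \sum_{\ell, i} \frac{1}{T}
  \sum_{t=1}^{T} S^{t}_{\ell,i},$$

with $N$ the number of neurons across all spiking layers *including the
readout* (the readout spikes like any other layer here; excluding it changes
$\bar r$ by under 10% at desk scale and no qualitative conclusion). The
manifold is

$$\mathcal{M} = \{\theta : r_{\min} \le \bar r(\theta) \le r_{\max}
  \ \text{and}\ A(\theta) \ge A_{\text{thr}}\}.$$

The bounds are task-driven; the defaults are $r_{\min} = 0.01$ and
$r_{\max} = 0.5$ spikes/neuron/timestep, with the accuracy floor expressed
relatively as $0.9 \times$ the best accuracy observed in the sweep (an
absolute mode is available). The default grid is 10 uniformly spaced points
with $\tau_m \in [1.001, 5]$ ms and $V_{\text{th}} \in [0.01, 3]$ V, fully
configurable; the desk-scale experiments use a 5×5 grid. `train_then_eval`
(a fresh network trained at every grid point with the same base seed) is the
default sweep mode; `eval_only` re-evaluates one trained network under each
configuration.

A grid cell is a *boundary* cell if it is in $\mathcal{M}$ and at least one
axis-adjacent neighbour is outside. Out-of-grid neighbours count as outside —
off-grid behaviour is unmeasured, so the grid edge is never certified
interior. One refinement: an axis of length 1 is a collapsed, unswept
dimension and contributes no neighbours, so a single-row grid behaves as the
one-dimensional sweep it actually is.

## Energy proxy and composite scores

Computational cost is estimated in synaptic operations:
$\text{SOP} = \sum_\ell \sum_t N^{(\ell)}_{\text{in}}(t) \, f^{(\ell)}_{\text{fanout}}$,
where $N_{\text{in}}$ counts the spikes entering a layer's synapses at step
$t$ and the fan-out is the number of output units for a dense layer and
$k_h k_w \cdot C_{\text{out}}$ for a conv layer. Two documented
approximations: conv fan-out ignores image-boundary truncation (the proxy is
constant across a sweep, so rankings are unaffected), and spikes are counted
after any pooling that sits between two layers (after global average pooling
the averaged spike mass feeds the classifier, and the pooled binary count is
used).

Over a sweep, accuracy and SOP are min-max normalized with the observed
extrema (a flat dimension maps to all zeros — no cost signal). Two scalar
scores summarize the trade-off:

$$\text{BES}_\lambda = A_{\text{norm}} - \lambda E_{\text{norm}}, \qquad
  \text{EAS}_\beta = \frac{(1+\beta^2) \, A_{\text{norm}} (1 - E_{\text{norm}})}
  {\beta^2 (1 - E_{\text{norm}}) + A_{\text{norm}}}.$$

EAS is the $F_\beta$ composite of normalized accuracy and inverse energy. As
in $F_\beta$, the argument *outside* the $\beta^2$ weight is the emphasized
one; placing accuracy there makes $\beta > 1$ stress accuracy and the EAS
ranking converge to the accuracy ranking as $\beta \to \infty$, which is the
score's stated intent (a transcription with the two denominator terms
exchanged would converge to the energy ranking instead). The 0/0 corner is
defined as 0. Defaults $\lambda = 0.5$ and $\beta = 5$. `score_sweep()` also
reports the Pareto front of $(A_{\text{norm}}, 1 - E_{\text{norm}})$ under
standard dominance.

## Reset versus carry

At inference, the *reset* policy reinitializes every membrane to
$V_\text{reset}$ before each sample; *carry* propagates the final state
$V^T$ into the next sample. Policy curves re-encode the test split at every
horizon $T$ with the evaluation seed (shorter horizons are genuine
re-encodings, not truncations). Carry evaluation streams the test set in one
fixed seeded shuffle, recorded in the result, starting from a fresh state at
the head of the stream. Reset evaluation is order-invariant and is batched.
Class-conditional output histograms average the readout's spikes per
timestep over all test samples of one class under the chosen policy.

## Perturbation collection and drift diagnostics

The perturbation protocol progressively disorders a correctly classified
input by applying $k$ uniformly random frame transpositions (a fresh
permutation of the clean tensor each round, $k$ growing by `swap_increment`
per round) and re-evaluating from a reset state, until the prediction flips;
at the flip, the clean and perturbed activities of the final hidden spiking
layer are stored with the swap count. The schedule is monotone in expected
disorder and capped at $3T$ swaps, which guarantees termination; samples
that never flip are discarded, misclassified clean samples are skipped.
Collection stops at `max_pairs` (default 2000) or dataset exhaustion. Because
the desk-scale test split is small, the pipeline draws a dedicated, larger
evaluation set for this stage.

Pairwise Pearson correlations are computed between the layer's binary spike
trains; pairs involving a zero-variance train are undefined, reported as
`NA`, and excluded from summaries (their count is reported). Per condition,
matrices are averaged elementwise and eight statistics extracted from the
defined upper-triangle coefficients: mean, median, standard deviation,
skewness (standardized third central moment), *excess* kurtosis, the 99th
percentile by linear interpolation, and the counts of coefficients above
0.75 and 0.9. The per-sample mode used for the classifier's feature table
summarizes each matrix separately.

Feature relevance is ranked by mutual information in bits between the
quantile-binned feature (10 bins, deterministic and seedless) and the binary
condition label; a gradient-boosted tree ensemble (xgboost, single thread,
seeded stratified 80/20 split) provides held-out accuracy and normalized
gain importances.

## Synthetic tasks: what they emulate, and what they do not

The static generator assigns each class an oriented-bar template (distinct
angle and anchor) and adds i.i.d. Gaussian pixel noise, clipped to $[0,1]$.
Template classes rather than digit look-alikes: the package's claims concern
spiking-regime structure, not digit recognition, and separable templates
keep training desk-scale. The default contrast 0.4 and noise SD 0.35 are
chosen so that a trained small MLP sits at roughly 0.95–0.97 test accuracy —
sub-ceiling, like the image benchmarks the generator stands in for, so that
genuinely ambiguous samples exist. That property is load-bearing: the
perturbation protocol only ever stores a pair when a prediction flips, and a
task solved with wide margins yields none. The event generator emits
class-specific moving-edge trajectories with both polarities plus uniform
background noise. The correlated-train generator mixes, per step and neuron,
a shared source train (probability $c$) with an independent Bernoulli draw,
so $c = 0$ gives independent trains and $c = 1$ identical ones.

What the generators do *not* emulate: within-class shape variability,
spatial noise correlations, class imbalance, or the temporal statistics of
real event cameras. Passing tests show the machinery recovers the regime
geometry and drift signatures under controlled conditions; they do not show
benchmark-level accuracy transfers.

Two desk-scale findings differ from benchmark-scale expectations and are
reported as such by the acceptance checks rather than smoothed over. First,
with batch normalization the synaptic drive is zero-centered, so a
hard-reset neuron's per-step firing probability is capped near 0.5 and
training suppresses it further; the sweep's high-$\tau_m$/low-$V_\text{th}$
corner therefore measures $\bar r \approx 0.4$, below the default
$r_{\max} = 0.5$, i.e. this MLP never becomes *clearly* saturated inside the
default bounds (the silent corner, non-empty membership and 4-connectedness
all hold). Second, for the common-input conditions the mean/median of the
correlation distribution separate clean from noisy almost perfectly, so tree
importances concentrate there rather than on the higher-order statistics
that dominate in subtler, real-data drift.

## Numerical choices and degenerate inputs

Prediction ties break to the lowest class index; max pooling breaks ties to
the first position scanned. Min-max normalization of a constant vector
returns zeros. `eas()` defines 0/0 as 0. Correlation summaries error only
when *every* pair is undefined. `collect_pairs()` may legitimately return an
empty set (reported, not an error). Training requires `t_ref = 0` (the
refractory gate is not differentiable) and batches of at least two samples
(batch statistics). Encodings, generators, training, splits and the boosted
ensemble all consume explicit seeds; the pipeline derives per-stage seeds
from one global seed as `(seed * 101 + offset) mod (2^31 - 1)` so any stage
can be reproduced in isolation.

## Problem sizes

The bundled experiments are sized for a single CPU: 4 classes of 12×12
images (40 train / 20 test per class), a 144–32–16–4 MLP, $T = 10$, 20
epochs of Adam, a 5×5 $(\tau_m, V_{\text{th}})$ grid trained point-by-point,
5-seed policy curves at $T \in \{1, 10\}$, a 400-sample dedicated draw for
perturbation pairs, and 1000 correlated-train samples per condition for the
drift classifier. The same code runs larger configurations unchanged.

## Known limitations

The SOP proxy ignores memory traffic, routing and leakage, so scores order
operating points rather than estimate joules. Manifold bounds are
task-driven and should be re-examined per task; the defaults encode a
sensible band, not a universal constant. The trainer is plain R matrix code:
adequate for desk-scale studies, not a substitute for GPU-scale training.
Conv training supports the two-block architecture described here; deep
residual/VGG-style backbones are out of scope.
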