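# snnmanifold

Tools for studying how leaky integrate-and-fire (LIF) neuron hyperparameters
and inference-time state handling shape the behaviour of spiking neural
networks (SNNs). The package is aimed at computational-neuroscience and
neuromorphic-computing researchers who want to reason about *operating
regimes* — silent, balanced, saturated — rather than single tuned operating
points, and to do so reproducibly on a laptop.

## What it computes

**LIF simulation and training.** Discrete-time forward-Euler LIF dynamics
with hard/soft reset and refractory handling,

$$V^{t+1}_{\text{pre}} = (1-\alpha)V^t + I^t,\quad
  S^t = \mathbb{1}[V^{t+1}_{\text{pre}} \ge V_{\text{th}}],\quad
  \alpha = \Delta t/\tau_m,$$

plus surrogate-gradient backpropagation through time for small MLP and
convolutional SNNs (arctangent pseudo-derivative
$g(u) = s/(1 + (\pi s u)^2)$, batch normalization before each spiking
nonlinearity, Adam, cross-entropy on time-averaged output spike counts).
The backward pass is verified against finite differences of the smooth
relaxation in the test suite.

**Operational manifold.** Grid sweeps over $(\tau_m, V_{\text{th}})$ measure
test accuracy $A(\theta)$ and the mean firing rate
$\bar r(\theta) = \tfrac1N \sum_{\ell,i}\tfrac1T\sum_t S^t_{\ell,i}$;
the manifold $\mathcal M$ is the region with
$r_{\min} \le \bar r \le r_{\max}$ and $A \ge A_{\text{thr}}$, and its
boundary is the set of member cells with an outside 4-neighbour.

**Efficiency scores.** A synaptic-operation (SOP) energy proxy
$\sum_\ell\sum_t N^{(\ell)}_{\text{in}}(t)\,f^{(\ell)}_{\text{fanout}}$ and
two composites of min-max-normalized accuracy and energy: the weighted
difference $\text{BES}_\lambda = A_{\text{norm}} - \lambda E_{\text{norm}}$
and the $F_\beta$-style
$\text{EAS}_\beta = (1+\beta^2)A_{\text{norm}}(1-E_{\text{norm}}) /
(\beta^2(1-E_{\text{norm}}) + A_{\text{norm}})$, plus the Pareto front of the
trade-off.

**Reset vs carry.** Inference-state policies between samples (reinitialize
membranes, or carry $V^T$ into the next input), accuracy-versus-horizon
curves, and class-conditional output-spike histograms.

**Drift diagnostics.** Progressive frame-permutation perturbations collected
at the first prediction flip, pairwise Pearson correlations of the final
hidden layer's spike trains, eight distribution statistics (mean, median,
SD, skewness, excess kurtosis, p99, tail counts above 0.75/0.9),
mutual-information ranking and a gradient-boosted clean-vs-noisy classifier.

Seeded synthetic generators (oriented-bar image classes, moving-edge event
streams, common-input correlated spike trains) make every stage runnable
with no external data.

## Worked example

```r
library(snnmanifold)

# 4-class synthetic task: oriented bars + pixel noise, 12x12
task  <- make_static_task(synthetic_task_config(seed = 42))
train <- encode_dataset(task$train, n_steps = 10, seed = 5)
test  <- encode_dataset(task$test,  n_steps = 10, seed = 6)

# small MLP-SNN, shared LIF configuration, surrogate-gradient training
net <- build_network(
  architecture_spec("mlp", input_shape = 144, n_classes = 4, hidden = c(32, 16)),
  neuron_config(tau_m = 2, v_th = 1), seed = 1
)
fit <- train_network(net, train, training_config(epochs = 20, seed = 1))

ev <- evaluate_network(fit, test)
c(accuracy = ev$accuracy, mean_rate = ev$mean_rate, sop = ev$sop)
#>     accuracy    mean_rate          sop
#> 9.625000e-01 1.842548e-01 8.071440e+05
```

The trained model classifies 96% of held-out samples while each neuron fires
on ~18% of timesteps, at a cost of ~0.8M synaptic operations over the test
set. Sweeping the neuron hyperparameters maps the operating regimes (a 3×3
grid here for brevity; the bundled experiments use 5×5 and the default
protocol is 10×10):

```r
sw <- run_sweep(
  sweep_task(train, test, architecture_spec("mlp", 144, 4, hidden = c(32, 16))),
  sweep_grid(seq(1.001, 5, length.out = 3), seq(0.01, 3, length.out = 3)),
  base_seed = 1, train_config = training_config(epochs = 20, seed = 1)
)
mf <- manifold(sw, manifold_spec())
tidy(mf)
#> # A tibble: 9 × 8
#>   tau_m  v_th accuracy mean_rate total_spikes    sop in_manifold on_boundary
#>   <dbl> <dbl>    <dbl>     <dbl>        <dbl>  <dbl> <lgl>       <lgl>
#> 1  1.00  0.01    0.988   0.475          19772 946884 TRUE        TRUE
#> 2  1.00  1.50    0.475   0.0599          2491 752452 FALSE       FALSE
#> 3  1.00  3       0.25    0.00635          264 725404 FALSE       FALSE
#> 4  3.00  0.01    0.975   0.401          16664 909900 TRUE        TRUE
#> 5  3.00  1.50    0.488   0.109           4515 775436 FALSE       FALSE
#> 6  3.00  3       0.275   0.0250          1042 735972 FALSE       FALSE
#> 7  5     0.01    0.975   0.384          15992 900420 TRUE        TRUE
#> 8  5     1.50    0.862   0.118           4922 779568 FALSE       FALSE
#> 9  5     3       0.35    0.0339          1410 741236 FALSE       FALSE
```

Low $\tau_m$ with high $V_{\text{th}}$ collapses activity (row 3: rate
0.006, chance accuracy — the silent regime); high $\tau_m$ with low
$V_{\text{th}}$ drives dense firing (row 7: rate 0.38 — approaching
saturation); the manifold collects the configurations that stay balanced
*and* accurate. Scoring the sweep picks operating points on the
accuracy–energy frontier:

```r
sc <- score_sweep(sw, lambda = 0.5, beta = 5)
attr(sc, "best_eas")[, c("tau_m", "v_th", "accuracy", "sop", "bes", "eas")]
#> # A tibble: 1 × 6
#>   tau_m  v_th accuracy    sop   bes   eas
#>   <dbl> <dbl>    <dbl>  <dbl> <dbl> <dbl>
#> 1     5  0.01    0.975 900420 0.588 0.861
```

`autoplot()` methods draw the sweep heatmaps, manifold map, policy curves
and output histograms; `evaluate_policy_curve()`, `collect_pairs()`,
`correlation_feature_table()`, `mutual_information_scores()` and
`condition_classifier()` cover the reset/carry comparison and the drift
diagnostics. A thin command-line wrapper around the same pipeline lives at
`inst/cli/snnmanifold.R` (commands `synth`, `train`, `sweep`, `score`,
`policy`, `diagnose`).

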