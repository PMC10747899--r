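---
title: "Methods: hybrid swarm tuning of a recurrent anomaly detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid swarm tuning of a recurrent anomaly detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ambulatory heart-rate monitoring produces long univariate series (beats per
minute sampled every 0.5 s) in which arrhythmic episodes appear as
contiguous stretches of shifted, more variable readings. `gipso` frames
their detection as supervised binary classification of each time step from
the window of the 15 preceding observations, and treats the choice of the
classifier's training hyperparameters — learning rate, dropout, epoch
budget, and the recurrent architecture itself — as a box-constrained
optimization problem solved by a hybrid particle swarm.

The package implements the complete harness: search space, optimizer,
classifier, data handling, evaluation, a multi-run statistical comparison
protocol, and per-lag attribution.

## The classifier

The model is a deliberately small Elman network. At step $t$ of the window
the activation of a recurrent layer is

$$a_t = b + W h_{t-1} + U x_t, \qquad h_t = \tanh(a_t),$$

with input weights $U$, recurrent weights $W$ and bias $b$; layers are
stacked (up to three, 8–15 units each) with inverted dropout applied to a
layer's output where it feeds the next layer. The final hidden state of
the top layer drives a single sigmoid unit giving the probability that the
current step is anomalous. A probability at or above the decision
threshold (0.5 by default) labels the step anomalous.

Design choices the formulation leaves open, fixed here once:

* **Activation**: $\tanh$ for hidden layers, sigmoid output — the
  canonical Elman choice for binary sequence classification.
* **Output head**: one sigmoid unit rather than a two-unit softmax; both
  are equivalent for a binary target and one unit keeps the parameter
  count minimal.
* **Weight fitting**: full backpropagation through time, minibatches of
  32, Adam with the tuned learning rate ($\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).
* **Early stopping**: patience of one third of the requested epochs
  (rounded up); the returned weights are those of the best-validation
  epoch, so a restored model is never worse on validation than the final
  epoch.
* **Standardization**: inputs are z-scored with the mean and standard
  deviation of the *training* split only, so the chronological test split
  leaks nothing into training.

## The search space

Seven dimensions encode the tunable quantities: learning rate
$[10^{-4}, 10^{-2}]$, dropout $[0.05, 0.2]$, epochs $[30, 60]$, layer
count $[1, 3]$, and one neuron-count slot per possible layer, each
$[8, 15]$ (half the lag count up to the lag count). The vector is fixed
length so every swarm agent has the same dimension while architectures
vary: slots beyond the decoded layer count are carried in the position but
ignored at decode time. Optimizers move through a purely real-valued box;
integer dimensions are rounded only when a position is decoded, which
preserves the velocity semantics of the swarm update. Any real 7-vector
decodes after clipping, so the objective is total on the box.

## The optimizer

Plain PSO moves each particle $i$ by

$$v_{id} \leftarrow w\, v_{id} + c_1 r_1 (p_{id} - x_{id})
  + c_2 r_2 (p_{gd} - x_{id}), \qquad x_{id} \leftarrow x_{id} + v_{id},$$

with per-dimension uniform draws $r_1, r_2$, personal best $p_i$, global
best $p_g$, velocities clamped to $\pm 10\%$ of each dimension's range,
and the inertia weight annealed linearly from $w_{\max} = 0.9$ to
$w_{\min} = 0.4$ over the iteration budget ($c_1 = c_2 = 2$; the classic
constants, used because the swarm variant under study modifies the
mechanism, not these values). Within the loop the weight is evaluated at
the number of *completed* iterations, so the first movement uses the full
initial inertia.

The hybrid (GIPSO) adds a genetic step after each PSO iteration:

1. **Crossover**: a child is built from the global best and a uniformly
   chosen other agent; each parameter independently blends
   $c_j = \alpha a_j + (1 - \alpha) b_j$ (per-parameter
   $\alpha \sim U(0,1)$) with probability $p_c = 0.1$, and otherwise
   copies the best agent. $p_c$ is read as a per-parameter blend
   probability — the only reading under which a small $p_c$ acts as a
   combination-strength control.
2. **Mutation**: each parameter independently mutates with probability
   $p_m = 0.1$; a triggered parameter moves by $\pm\, m_d \cdot
   \mathrm{rnd}$ with $m_d = 0.1$, $\mathrm{rnd} \sim U(0,
   \text{range width})$ and a uniformly chosen sign, clipped to the box.
   (A variant magnitude of $0.5\,\mathrm{rnd}$ is available behind
   `gipso_config(half_rnd = TRUE)`, default off.) The trigger rule is a
   design decision exposed in configuration, as the mechanism's
   description fixes only the magnitude.
3. **Replacement**: the child replaces the worst-fitness agent (lowest
   index on ties, for determinism) with zero velocity and *unset*
   fitness; it is first evaluated after its first move in the next
   iteration, so the hybrid spends exactly the same evaluation budget as
   plain PSO: `pop_size * (iterations + 1)` evaluations. Giving the
   newcomer zero velocity (rather than inheriting the replaced agent's)
   was chosen so the child starts as a pure exploitation point.

A real-coded GA baseline (tournament selection with $k = 2$, the same
blend crossover and mutation operators, elitism of one with the elite's
fitness carried over so budgets stay equal) is included for comparison.

A property worth knowing: on a unimodal benchmark (the 7-D sphere) the
worst-replacement mechanism *costs* exploitation at small budgets, because
converging low-rank particles keep being recycled into near-copies of the
global best; the hybrid's advantage shows on multimodal landscapes
(rastrigin), where the benchmark suite asserts its median superiority over
plain PSO across 30 paired runs. Both behaviors are reproducible with
`benchmark_objective()` and `optimize_swarm()`.

## Data protocol

Windows pair the 15 preceding values with the *current* step's label —
causal prediction, so an episode's onset step itself is inherently hard
(none of its lags have seen the shift yet). Windowing is per series;
windows never span series boundaries. The chronological 70/10/20 split is
contiguous and order-preserving (train and validation sizes floored, the
remainder to test); the final 20% is reserved strictly for the single
held-out evaluation, which the experiment driver enforces with an access
counter (`test_evaluations` in the result).

## The tuning objective and the experiment

Each objective evaluation decodes a position, builds and trains the
classifier, and returns the validation error rate $1 - \text{accuracy}$
(minimized), with Cohen's kappa recorded as the tracked indicator:

$$\kappa = \frac{z_o - z_e}{1 - z_e},$$

observed agreement $z_o$ against chance agreement $z_e$ from the marginal
products — the appropriate headline number under heavy class imbalance. A
training failure is penalized with the worst possible fitness 1.0 and a
warning, never an abort.

A full experiment repeats tuning over independent runs (30 by default; run
$r$ seeds the optimizer with `base_seed + r` while the data seed and the
model-training seed stay fixed, so runs are paired across optimizer
variants for the signed-rank test). Each variant's best run is refit on
train+validation (the validation split still serves as the early-stopping
monitor) before its one test evaluation; refitting is the default reading
of "reserved only for testing" and can be disabled with `refit = FALSE`.

## Statistical comparison

Per-algorithm best-objective samples are screened with Shapiro–Wilk at
$\alpha = 0.05$; non-normal samples (the usual case for metaheuristic
outcomes) gate the comparison to the nonparametric Wilcoxon signed-rank
test of the control against each competitor on paired runs. The
signed-rank p-value is *exact* — the full null distribution over all
$2^n$ sign assignments, computed by convolution over doubled midranks so
ties are handled exactly — for up to 25 nonzero differences, and the
tie-corrected normal approximation with continuity correction beyond.
Summaries report best, worst, mean, median, and the sample standard
deviation (denominator $n - 1$, the reporting norm) with its square as the
variance.

## Attribution

`feature_importance()` estimates each lag's Shapley contribution to the
model output. A coalition's value is the mean model output over a
background window set with the coalition's lags fixed to the sample's
values (marginal imputation). The estimator samples random feature
*orderings* and accumulates each lag's marginal contribution along the
walk from the background to the full sample; this makes local accuracy —
attributions summing to the sample's output minus the mean background
output — hold exactly at any sampling budget, while the per-lag values
converge to the Shapley value as orderings accumulate. An exact
enumeration over all $2^D$ coalitions is available for small $D$ and
serves as the oracle in the tests. The background defaults to 100
training windows drawn with a fixed seed.

## The synthetic generator

The generator emulates what the harness needs from a labeled recording:
an autoregressive heart-rate level around a resting baseline of 80 bpm
(AR(1) with coefficient 0.8, innovation sd 1.5 bpm) interrupted by
contiguous arrhythmic episodes that shift the level by +25 bpm and
inflate the innovation sd by 6 bpm. Episode boundaries follow a
two-state Markov chain whose stay probabilities are solved from two
interpretable quantities: the stationary anomalous fraction (default
0.85, matching the heavy imbalance of the motivating test split of 442
normal vs 2454 anomalous windows) and the expected episode count per
series (default 20 over 1800 steps, i.e. arrhythmic runs of roughly 40 s)
— onsets are then Poisson in the discrete-time sense. The defaults were
set so that the episode shift clearly exceeds the within-state spread
(the anomaly is learnable from a lag window) and episodes are short
enough that every chronological split contains both classes; a
50-series Monte-Carlo test asserts the realized anomalous fraction lands
within five percentage points of the target.

What the generator does **not** emulate: real ECG-derived rate series
have beat-detection artifacts, non-stationary baselines (circadian and
activity drift), heterogeneous arrhythmia morphologies, and
patient-to-patient variation. Passing the synthetic suite therefore
demonstrates that the pipeline's plumbing, optimization and statistics
behave correctly — not that any particular accuracy transfers to
clinical recordings.

## Problem sizes in the tests

Unit tests run on small fixtures (hundreds of windows, networks of a few
units, 2–12 epoch budgets). The benchmark acceptance suite uses the study
configuration (population 6, 8 iterations, 30 runs) on 7-D sphere and
rastrigin. The end-to-end suite tunes on two 1800-step series with
population 4, 3 iterations, 3 repeats and a 10-epoch cap — sizes chosen so
the whole pipeline, including 96 full network trainings, runs on a single
CPU in a few minutes while still exercising every stage.

## Known limitations

* Plain Elman cells only; gated variants (LSTM/GRU) are out of scope.
* The comparator metaheuristics beyond PSO and the GA baseline are not
  reimplemented; `optimize_swarm`'s objective interface is the plug-in
  point for external optimizers.
* The exact Shapley mode is exponential in the number of lags and
  intended only as a small-instance oracle.
* Headline accuracies on the motivating public dataset depend on an
  external download and long stochastic training; the package verifies
  their published arithmetic (confusion-matrix round-trips) rather than
  re-measuring them.
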