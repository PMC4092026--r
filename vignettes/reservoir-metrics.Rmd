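---
title: "Reservoir metrics, plasticity rules, and what predicts readout accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir metrics, plasticity rules, and what predicts readout accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidmetrics)
```

## The question this package addresses

Reservoir computing trains only a linear readout on top of a fixed (or
unsupervised-adapted) recurrent network, so the burden of producing linearly
separable state vectors falls entirely on the reservoir's design. Several
metrics have been proposed to judge a reservoir before committing to readout
training: **class separation** of its state clouds, **kernel quality** (the
rank of its state matrix), a **Lyapunov exponent estimate** of its dynamical
regime, and the **spectral radius** of its weight matrix. `liquidmetrics`
implements a spiking liquid-state-machine testbed for asking how well each
metric actually predicts time-series classification accuracy, across three
connectivity models and three synaptic plasticity rules.

## The model

### Reservoir

The reservoir is a network of `L = 135` Izhikevich simple-model neurons
(4:1 excitatory:inhibitory), each integrating

$$\dot v = 0.04v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with reset $v \leftarrow c$, $u \leftarrow u + d$ at the 30 mV spike peak.
Excitatory neurons use the regular-spiking preset
$(a,b,c,d) = (0.02, 0.2, -65, 8)$ and inhibitory neurons the fast-spiking
preset $(0.1, 0.2, -65, 2)$. Integration is forward Euler at
`dt = 1` ms — the standard resolution for this model; halving `dt` changes
individual spike times by at most a step but not the state statistics, and
the simulator accepts any `dt` for sensitivity checks.

Inputs are min–max normalised to $[0,1]$ (training-set statistics, test
values clipped, constant features mapped to 0.5), scaled by 20, and injected
as current into a fixed random subset of neurons — each feature fans out to
$\lceil 0.3L \rceil$ neurons. Each input frame is held for
`duration / n_frames` ms of the 150 ms sample window. Synapses are static
delta impulses with no delay: a spike in neuron $j$ at step $t$ adds
$W_{ij}$ to neuron $i$'s current at step $t+1$.

Each neuron's spike train is low-pass filtered with a causal exponential
kernel and read at the window end,
$x_i = \sum_k e^{-(T - t_k)/\tau}$ with $\tau = 30$ ms, giving the state
vector the readout and the state-based metrics consume. The filter form and
constant are package choices (only "a low-pass filter" is prescribed by the
modelling tradition this follows); $\tau = 30$ ms weights roughly the last
third of the window.

### Connectivity

Three generators produce the directed adjacency before weights are drawn:

* **uniform** — every ordered non-self pair connected with `p = 0.1`;
* **scale_free** — Barabási–Albert preferential attachment
  (`igraph::sample_pa`, `m = 5` attachments per new node), each undirected
  attachment oriented by a fair coin;
* **lattice** — neurons on a 15×3×3 grid, ordered pair at Euclidean distance
  $D$ connected with probability $C e^{-(D/\lambda)^2}$, `C = 0.3`,
  `lambda = 2`.

These defaults give mean in-degrees of roughly 13 (uniform), 5 (scale-free)
and 3 (lattice); they are deliberately kept at their conventional per-model
values rather than equalised, so the connectivity factor also varies density.
Synaptic weights are Gaussian by presynaptic type —
$\mathcal N(6, 2^2)$ rectified non-negative for excitatory,
$\mathcal N(-6, 2^2)$ rectified non-positive for inhibitory — which drives
mean network firing near 20 Hz under benchmark input, and Dale's sign
convention is enforced everywhere thereafter.

### Plasticity

An unsupervised pre-training phase simulates each training sample once
(`plasticity_epochs = 1`) and updates the weights after each sample; weights
are then frozen before readout training. Updates act on the signed weight
and are clamped to $[0, 10]$ (excitatory) or $[-10, 0]$ (inhibitory), so
signs never flip and the zero pattern is never altered.

* **BCM** (rate-based): per synapse,
  $\Delta w = \eta\, y(y - \theta)\,x/\theta - \varepsilon w$, where $x, y$
  are the pre- and postsynaptic filtered activities,
  $\theta = \bar y^2 / y_0$ is the sliding threshold ($\bar y$ an
  exponential moving average over a 10-sample horizon, floored at 0.05 for
  numerical safety), and $y_0 = 1$ in filtered-state units (about 30 Hz).
  Activity above threshold potentiates, below depresses, and the sliding
  threshold regulates each neuron's rate toward $y_0$. The constants
  $\eta = 0.05$, $\varepsilon = 0.1$ were calibrated once so the homeostatic
  equilibrium is reached within the pre-training phase and leaves the weight
  matrix in the sub-unit spectral-radius regime that BCM-adapted reservoirs
  are reported to occupy; note that applying a negative Hebbian term to the
  signed weight weakens excitation *and* strengthens inhibition, both of
  which lower the postsynaptic rate — the homeostatically correct direction
  for both synapse types.
* **Bi-phasic STDP**: the classic two-exponential window,
  $A_+ e^{-\Delta t/\tau_+}$ for in-order pairs ($\Delta t > 0$),
  $-A_- e^{\Delta t/\tau_-}$ for out-of-order pairs, with
  $A_+ = 0.05$, $A_- = 0.055$, $\tau_\pm = 20$ ms. A simultaneous pair
  ($\Delta t = 0$) contributes nothing (the two branches are not defined
  there; it is a measure-zero tie at any finite resolution).
* **Tri-phasic STDP**: a difference of Gaussians centred at
  $\Delta t = +15$ ms,
  $0.25\,e^{-(\Delta t - 15)^2/200} - 0.1\,e^{-(\Delta t - 15)^2/2000}$:
  a narrow potentiating bump for closely in-order activity flanked by
  depression for uncorrelated and for late activity, the window shape
  observed between hippocampal CA3 and CA1. Its integral is negative, so
  sustained uncorrelated firing depresses on balance.

STDP accumulates the window over **all** spike pairs of a synapse within a
±50 ms horizon (not nearest-neighbour pairing). Internally this is computed
as $C F C^\top$ with $C$ the neuron-by-spike-time count matrix and $F$ the
window evaluated on all time differences; an exhaustive nested-loop oracle
in the test suite pins the equivalence.

### Readout

One linear unit per class over the state vector plus a bias input of 1,
one-hot targets, trained by Least Mean Squares:
$w \leftarrow w + \eta (d - y)x$, 20 shuffled epochs. Classification is
arg-max over units with ties to the lowest class index. The step size is
$\eta = 10^{-3}$: with these state magnitudes
($\mathbb E\lVert x\rVert^2 \approx 150$) the LMS stability condition
$\eta < 2/\mathbb E\lVert x\rVert^2$ makes the superficially conventional
$10^{-2}$ oscillatory (measured: train accuracy 0.35 vs 0.71 on identical
states), so the smaller step is used. A ridge/pseudo-inverse readout is
deliberately not offered in the experiment path — the point is the iterative
LMS readout.

### Metrics

For each run the four metrics are computed from the training-split states:

* **Class separation**: mean pairwise distance between distinct class
  centroids divided by (1 + mean within-class distance to centroid). The
  `+1` guards the zero-variance case. The inter-class term averages over
  distinct pairs, so two point classes 4 apart score exactly 4.
* **Kernel quality**: numerical rank of the $L \times N$ state matrix —
  singular values above $\max(L, N)\,\epsilon\, \sigma_{max}$ (the standard
  numerical-rank convention; no tolerance is prescribed by the tradition).
  Bounded by $\min(L, N)$, so 135 is the ceiling here.
* **Lyapunov estimate**: for each sample, find its nearest neighbour in
  input space (frame-averaged input vectors) and average
  $\ln(\lVert x_j - x_{j'}\rVert / \lVert u_j - u_{j'}\rVert)$, scaled by
  $kL$ with $k = 1$ and $L = 135$. The constant is undetermined, so values
  are comparable only within this estimator. Pairs with zero input distance
  — or zero state distance, where the log is undefined — are skipped.
* **Spectral radius**: largest absolute eigenvalue of the adapted weight
  matrix. A numerically failed eigendecomposition is recorded as value 0
  with a validity flag; grid correlations include such zeros (mirroring how
  failed computations distort the reported scatter plots), while
  distribution summaries exclude them, and a valid-only correlation is also
  reported, clearly labelled as an extension.

## The tasks and the synthetic generators

**Benchmark (tri-function signal).** One scalar signal in which a sine of
random period (uniform in 10–50 steps), the chaotic tent map
$x \leftarrow 2\min(x, 1-x)$, or a random constant is active at each step;
with probability 0.05 per step the active generator is redrawn uniformly
among all three (so the rate of visible switches is $2/3 \times 0.05$).
Values lie in $[0,1]$. The signal is cut into non-overlapping 15-step
windows labelled by majority generator (ties to the earliest in the
window); window length, the labelling rule and the redraw convention are
package conventions — the source tradition streams the signal without
stating a segmentation.

**Speaker surrogate.** A nine-class, twelve-feature stand-in for the classic
Japanese-vowel utterance data: per class, a stationary AR(1) Gaussian
process around a class mean drawn on a sphere of radius 2, per-class AR
coefficients spread over 0.55–0.87, innovation s.d. 1, frame counts uniform
in 7–29, split sizes 270/370. It reproduces the *shape statistics* the
pipeline cares about (frame counts, dimensionality, separable-but-
overlapping classes) but none of the spectral structure of real speech —
passing tests on it says the pipeline works, not that real-speech accuracy
is reproduced. A reader for the real whitespace-delimited files
(`read_japanese_vowels()`) is provided but never required.

## The experiment grid and its problem size

`run_grid()` executes every (rule × topology × seed) combination — the
default study is 4 × 3 × 10 = 120 reservoir runs on one shared dataset —
with per-run seeds derived from the master seed by a fixed counter scheme,
one-row-per-run results as a tibble, optional CSV checkpointing, and
failures recorded without stopping the grid. `summarize_grid()` gives the
box-plot statistics per cell; `correlate_metrics()` gives each metric's
Pearson correlation with test accuracy.

The default benchmark problem size is 240 training and 120 test windows
(a 5 400-step signal). This is a deliberate reduced-scale choice: it keeps
a full 120-run grid in the few-minutes range on one core while using the
full 135-neuron reservoir per run; the original-scale 50 000-step signal is
one `benchmark = list(n_train = ..., n_test = ...)` override away.

## What reproduces, and what does not

With the package defaults the suite reproduces: the kernel-quality ceiling
at the reservoir dimension; the tight coupling between the Lyapunov estimate
and kernel quality (Pearson r ≈ 0.9 across the grid — the two metrics
measure much the same property of the dynamics); and the BCM
spectral-radius regime (median ≈ 0.7 over valid BCM runs, below but
approaching 1, while other rules sit far above 1).

The *magnitudes* of the four metric-versus-accuracy correlations do not
reproduce the weak values reported for the benchmark task (≈ 0.26 and
below). Here they are strong (|r| ≈ 0.5–0.6), because grid accuracy
variance is dominated by between-cell structure: uniform connectivity gives
full-rank states and the best accuracy, while BCM's homeostatic collapse of
recurrence gives low-rank states and slightly worse accuracy, so rank-like
metrics and accuracy co-move. Weak correlations would require per-rule
accuracy differences small relative to within-cell noise, which this
parameterisation — with every stated constant fixed and the remaining BCM
constants frozen against the spectral-radius regime rather than against the
correlation table — does not produce. The acceptance suite asserts the
reported values anyway and the corresponding test block is expected to
fail; it is kept failing rather than weakened, as an honest record of the
discrepancy.

## Known limitations

* Izhikevich presets are fixed to regular-spiking/fast-spiking; no
  parameter heterogeneity across neurons.
* No synaptic delays, conductances, or short-term plasticity; plasticity
  never rewires (weights only).
* The Lyapunov estimate's constant is arbitrary (k = 1), so its scale is
  internal to this package.
* The tent map in binary floating point collapses to 0 after ~50 iterations
  within one segment; at the default switching rate, segments that long are
  rare (< 7%) and the values remain valid members of $[0,1]$.
* Spectral-radius "failures" are rare under LAPACK's dense eigensolver, so
  the invalid-as-zero pathway is exercised far less than under the
  approximate iterative methods the original setting used; tri-phasic runs
  here usually yield valid (large) radii instead.
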