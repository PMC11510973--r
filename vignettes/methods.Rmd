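---
title: "Methods: WPLI brain networks and bimodal graph classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WPLI brain networks and bimodal graph classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`wplinet` implements a complete analysis chain for studying motion
sickness with simultaneous EEG and fNIRS recordings:

1. **Preprocessing** — zero-phase Butterworth filtering, EEG sub-band
   decomposition, and cerebral oxygen exchange (ΔCOE) computation.
2. **Connectivity** — weighted phase lag index (WPLI) matrices per
   segment, per EEG band and for the ΔCOE series.
3. **Network analysis** — thresholding into binary functional brain
   networks under degree and small-world constraints, graph metrics,
   key-node identification, and Mann–Whitney group comparisons.
4. **Classification** — node feature extraction, bimodal graph fusion,
   and a graph convolutional network (GCN) with TopK pooling evaluated
   by stratified cross-validation.
5. **Synthesis** — a generator that plants known phase-lag coupling so
   that every stage above can be validated without recording hardware.

The montage is fixed by the targeted acquisition setup: 14 EEG channels
(AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4) at 128 Hz
and 6 prefrontal fNIRS channels at 10 Hz, analyzed in 5-minute segments
labeled by the Fast Motion Sickness (FMS) scale: a score of 1 labels a
segment non-motion-sickness (NM), any higher score motion sickness (MS).

# Preprocessing

EEG is band-pass filtered to 0.5–45 Hz with an order-4 Butterworth
filter applied forward and backward (`signal::filtfilt`), which doubles
the magnitude roll-off and cancels phase distortion — important because
WPLI is a phase statistic. The four analysis bands are delta (0.5–4 Hz),
theta (4–8 Hz), alpha (8–12 Hz), beta (12–32 Hz). The delta band starts
at 0.5 Hz rather than 0 Hz because the broadband high-pass makes content
below 0.5 Hz unattainable.

fNIRS channels are reduced to the cerebral oxygen exchange series

$$\Delta COE = \Delta C_{HbR} - \Delta C_{HbO},$$

then band-passed to 0.01–0.2 Hz (configurable). The hemodynamic
oscillations of interest sit below 0.1 Hz; the upper edge removes
cardiac and respiratory residue.

Artifact removal procedures for real recordings (ICA for EEG motion
artifacts, spline-based fNIRS corrections) are acquisition-specific and
are deliberately not reimplemented; `artifact_hook()` marks where they
belong in the chain and enforces the shape-preserving contract a real
method would have to obey. Synthetic data needs no artifact handling.

# Weighted phase lag index

For two band-limited series the instantaneous cross-spectrum is
$S(t) = a_x(t)\,\overline{a_y(t)}$ with $a$ the analytic signal
(FFT-based Hilbert transform). The WPLI is

$$\mathrm{WPLI} = \frac{\lvert E[\operatorname{Im} S]\rvert}{E[\lvert\operatorname{Im} S\rvert]},$$

the expectation running over the time samples of one segment, after
trimming 5% of samples at each end to suppress Hilbert edge effects.
WPLI is insensitive to zero-lag (volume-conduction) coupling because
such coupling contributes no imaginary cross-spectral mass. Numerical
conventions: when $E[\lvert\operatorname{Im} S\rvert] < 10^{-12}$
(e.g. identical inputs) the index is defined as 0 — no imaginary
coupling means no phase-lag evidence. An optional epoch-averaged
estimator (non-overlapping windows, per-epoch analytic signals) is
available via `n_epochs`; the default single-segment estimator is used
throughout because segments are long (38 400 EEG samples).

The implementation is validated against an independent brute-force
oracle (explicit $O(n^2)$ DFT sums, explicit time loop) to $10^{-10}$,
and against closed forms: a constant-lag tone pair gives exactly 1,
identical series give 0, independent noise stays below 0.1 at full
segment length.

# Functional brain networks

A connectivity matrix is binarized with a strict threshold
($a_{ij} = 1$ iff $w_{ij} > t$). The default per-band thresholds are
0.36 (delta), 0.42 (theta), 0.40 (alpha), 0.26 (beta), and 0.35 (fNIRS).
`select_threshold()` can instead search a grid on the group-average
matrix and return the **largest** threshold that still satisfies both
constraints: mean node degree at least $\ln N$, and small-world index
$\sigma > 1$. Largest-feasible maximizes sparsity (fewest spurious
edges) under the constraints; infeasibility raises an error that reports
the constraint values across the grid.

Metrics follow the standard unweighted-graph definitions: node degree;
clustering coefficient $C_i = 2E_i/(k_i(k_i-1))$ with $C_i = 0$ for
$k_i < 2$; nodal global efficiency $E_{glob}(i) = \frac{1}{N-1}
\sum_{j \ne i} 1/d_{ij}$ with $1/\infty = 0$ for disconnected pairs;
nodal local efficiency as the global efficiency of the neighbor-induced
subgraph (Latora–Marchiori); normalized betweenness (divided by
$(N-1)(N-2)/2$). Nodal efficiency definitions are the standard ones,
adopted because the field's usual formulations leave them implicit.
Key nodes are flagged where normalized betweenness exceeds the mean plus
one standard deviation (a top-$k$ rule is available); this specific rule
is a package choice — betweenness-based hub identification is standard
but no universal cutoff exists.

The small-world index is $\sigma = (C/C_{rand})/(L/L_{rand})$ against
degree-preserving rewired surrogates (default 100, seeded;
`igraph::keeping_degseq`). A complete graph is its own rewiring class,
so $\sigma = 1$ exactly; Erdős–Rényi graphs scatter around 1; ring
lattices with shortcuts exceed 1.

Group differences use the two-sided Mann–Whitney test: exact for small
tie-free samples, normal approximation with tie correction otherwise,
starred at 0.05/0.01/0.001.

# Node features and bimodal fusion

Each node carries 13 features: nine signal statistics of its
band-limited (or ΔCOE) series — mean absolute value, variance, max, min,
RMS, excess kurtosis, skewness, total spectral power of the broadband
series, and relative power within the node's own band — plus four graph
features: degree, clustering coefficient, nodal global efficiency, nodal
local efficiency. The split of spectral power into *total* and
*relative-band* components fixes the feature count at 13 where a single
"PSD" entry would leave it at 12; the list is configurable. A constant
signal has kurtosis and skewness defined as 0. Features are z-scored per
feature across the **training split only**; the fitted scaler is stored
in the model and applied unchanged to held-out data.

The fused graph stacks the 14-node EEG band network and the 6-node fNIRS
network block-diagonally (both unaltered) and adds bridge edges of
weight 1 between spatially overlapping channels. The default bridge map
follows the prefrontal optode placement against the 10–20 frontal
electrodes: Ch1↔AF3, Ch5↔F7 (left), Ch2 and Ch3↔{AF3, AF4} (midline),
Ch4↔AF4, Ch6↔F8 (right). It is overridable; the exact pairing is a
package choice because only the left/midline/right placement is
specified by the acquisition geometry.

# The classifier

Graph convolution uses the symmetric-normalized propagation rule with
self-loops, $X' = \mathrm{ReLU}(\tilde D^{-1/2}\tilde A\tilde D^{-1/2}
X W)$, $\tilde A = A + I$. The fused architecture is:

* two parallel branch convolutions (13→30), one per modality block, on
  the block adjacencies (bridges excluded at this stage, so each branch
  sees its own unaltered network);
* a fusion convolution (30→60) on the full bimodal adjacency;
* TopK pooling 20→10: scores $s = Xp/\lVert p\rVert$, keep the $k$
  best (ties to the lower index for determinism), gate kept features by
  $\tanh(s)$;
* a deep convolution (60→90) on the pooled subgraph (renormalized with
  self-loops);
* TopK pooling 10→1 and a linear read-out 90→2.

Unimodal baselines reuse the same stack with a single branch and pool
sizes $n \to \lceil n/2\rceil \to 1$ (14→7→1 for EEG, 6→3→1 for fNIRS),
mirroring the 20→10→1 halving of the fused model. Parallel branches
(rather than one convolution over a concatenated graph) follow from the
requirement that the first layers capture independent per-modality
features.

Training minimizes softmax cross-entropy with Adam. L2 regularization is
applied as **decoupled** weight decay (AdamW-style: the decay term is
subtracted from the parameters directly rather than added to the Adam
gradient). This is a deliberate choice: with coupled decay the Adam
normalizer amplifies the decay direction whenever early task gradients
are small — which is the normal situation here, since the signal passes
two $\tanh$-gated pooling stages at initialization — and training
collapses to the constant classifier. Decoupled decay regularizes
without that failure mode. Defaults: learning rate $10^{-3}$, weight
decay $5\cdot10^{-4}$, 200 epochs, batch 16, all exposed in
`gcn_config()`. Forward and backward passes are exact dense-matrix
computations (graphs have ≤ 20 nodes); analytic gradients are verified
against central finite differences to $10^{-4}$ relative error in the
test suite. Everything is deterministic given the seed.

Evaluation uses stratified k-fold cross-validation (default 10): class
proportions per fold stay within one sample of the global proportions,
metrics are accuracy, binary F1 on the MS class, recall, and precision,
reported per fold with mean ± sd. `grid_search()` crosses hyperparameter
grids, selects by mean F1, and breaks ties by accuracy then smaller
weight decay.

# The synthetic generator

No signal-level generative model is given for the real recordings; all
generator distributions are package choices designed to exercise the
estimators, not claims about physiology.

* **EEG**: each channel is a sum over bands of unit-RMS narrow-band
  Gaussian oscillators (order-4 Butterworth bandpass of white noise)
  with band amplitudes 1.0/0.8/0.7/0.6 (delta/theta/alpha/beta), plus
  pink (1/f) noise at `noise_sd` (default 0.3) — a crude but standard
  caricature of the EEG spectrum.
* **fNIRS**: HbO is a unit-RMS slow oscillator (0.02–0.1 Hz) plus a
  sub-0.01 Hz drift and white noise; HbR is anti-correlated with HbO
  (factor −0.5) plus independent noise, so ΔCOE carries the oscillator
  with gain 1.5. The oscillator band starts at 0.02 Hz rather than
  0.01 Hz because slower components contribute fewer than three cycles
  per 5-minute segment and only inflate estimator variance.
* **Coupling**: a coupling entry makes the follower channel's band
  component a fractionally-delayed copy of the leader's (frequency-domain
  phase rotation at the band center frequency), mixed in proportion to
  the coupling strength. A lagged copy of a shared oscillator guarantees
  a constant-sign imaginary cross-spectrum, hence a WPLI that approaches
  1 as strength → 1 — analytically checkable, unlike coupled stochastic
  oscillators.
* **States**: by default MS segments have denser prefrontal fNIRS
  coupling and sparser beta-band EEG coupling than NM segments, with
  delta/theta/alpha couplings identical across states (null bands).
  `signal_split = "alternate"` plants the MS signature in only one
  modality per MS segment (alternating), so that neither modality alone
  separates the classes — the regime in which fusion must outperform
  either branch.
* FMS scores are 1 for NM and uniform on 2–6 for MS; only the >1
  dichotomy is used downstream.

What the generator does **not** emulate: motion and ocular artifacts,
raw fNIRS light intensities (concentrations are emitted directly),
volume conduction, non-stationarity within a segment, and inter-subject
variability. Passing tests therefore demonstrate correctness of the
estimators and the learning machinery on planted structure — not
performance on real recordings.

# Problem sizes and numerical choices

Test-suite and acceptance-script runs use these sizes, chosen to give
stable statistics at desk scale:

* WPLI oracle equivalence: 100 random pairs of 1 000 samples, tolerance
  $10^{-10}$; null level: 100 independent-noise pairs at full 5-minute
  length.
* Graph-metric oracle equivalence: 200 random graphs with $N \le 14$.
* Planted-structure recovery: 20 replicate 5-minute segments (ranking
  AUC of one coupled alpha pair at strength 0.85 against all uncoupled
  pairs); Mann–Whitney power over 10 replicate datasets of 30 NM + 30 MS
  fNIRS segments.
* Classifier: 136 segments (61 NM / 75 MS) of 60 s — the full study
  counts at a shorter segment length, which leaves the planted
  connectivity contrast intact while keeping dataset construction fast;
  stratified 10-fold CV at 100 epochs for the headline run, 5-fold at 80
  epochs for the three-seed fused-vs-unimodal comparison (the ordering
  margin is large), 80 epochs for the permuted-label chance check.

Other numerical conventions: strict inequality at the binarization
threshold; disconnected pairs contribute 0 to efficiency; TopK ties
break toward the lower node index; zero-variance features are left
unscaled; the 0/0 WPLI case is 0; EDF round-trips are exact only to
16-bit quantization of the channel range.

# Known limitations

* The synthetic conditions are favorable by construction; real-data
  performance claims are out of scope.
* ICA and fNIRS motion-artifact algorithms are interface hooks only.
* Connectivity is undirected; no directed or weighted-bridge variants.
* The EDF reader supports continuous 16-bit recordings with integer
  sampling rates only — sufficient for fixtures and the supported
  devices, not a general EDF implementation.
* Training is CPU-only and dense; adequate for 20-node graphs, not for
  high-density montages.
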