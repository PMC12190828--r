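---
title: "Delayed-phase image encoding and spike-train decoding for cultured neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed-phase image encoding and spike-train decoding for cultured neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnncode)
```

# The problem

Cultured ("in vitro") biological neural networks grown on high-density
microelectrode arrays (HD-MEAs) can be stimulated electrically and read out
at up to 1024 channels, but they cannot see: any visual task first requires
an encoding that turns an image into pulse trains a living culture will
tolerate. Living cultures impose hard constraints — few usable stimulation
electrodes (8 here), a bounded stimulation rate (intense high-frequency
input can silence a culture), and biphasic charge-balanced pulses (500 mV,
500 µs per phase). `bnncode` implements a complete desk-scale version of
such a system: a convolutional feature extractor, a delayed-phase pulse
encoder, a phenomenological spike-train simulator standing in for the
culture, a multinomial logistic-regression decoder over binned evoked
responses, and a spike-time-tiling-coefficient (STTC) functional
connectivity analysis.

# Image to feature maps

The extractor is a six-layer stack: three convolutional layers (5×5
kernels, stride 1, zero "same" padding, ReLU) with 12, 14 and 8 filters,
each followed by 2×2 max pooling with stride 2. A temporary
flatten + 3-way softmax head is attached for training (Adam, learning rate
5e-4, cross-entropy, up to 50 epochs with early stopping on validation
loss, patience 5, best weights restored) and discarded afterwards. Two
geometric decisions close gaps the architecture leaves open:

* **Input side = 40 px.** Three 2× poolings must end at 5×5, which forces
  40 → 20 → 10 → 5. Images of any other size are bilinearly resampled on
  load.
* **Per-map min–max normalization.** Each of the eight final 5×5 maps is
  scaled to [0, 1] so the latency transform below receives a bounded
  input; a constant map maps to all zeros (not NaN), which also keeps the
  degenerate all-zero input well defined.

Each 5×5 map is one receptive field, hard-wired to one of the 8
stimulation electrodes.

The synthetic image generator supplies three visually distinct colour
classes (filled disc, elongated bar, disc-with-handle — stand-ins for the
apple/car/cup categories of small object-image datasets) with per-image
colour, position and scale jitter on a noisy background. It emulates
class-distinct silhouettes and moderate within-class variability; it does
not emulate photographic texture, lighting, 3-D pose or background
clutter, so a high extractor validation accuracy here shows the pipeline
is wired correctly, not that the extractor would excel on photographs.

# Feature maps to pulse programs

Each pixel value $p_i \in [0,1]$ of a receptive field is turned into a
latency

$$t_i = t_{\max}\,(1 - \arctan(\delta\, p_i)),$$

so stronger features fire earlier, and is then offset by a positional
delay $\Delta t_i = (i/n_{rf})$ s for row-major pixel index
$i = 0,\dots,24$. Three parameters are reconstructed from the printed
constraints of the protocol rather than given directly, and the package
fixes them as follows:

* $\delta = \tan(1)$ (default), so the latency spans exactly
  $[0, t_{\max}]$; for a user-supplied larger $\delta$ negative latencies
  are clamped to 0.
* $t_{\max} = 1$ s and delay span 1 s: the only scaling under which
  latency (≤ 1 s) plus positional delay (≤ 0.96 s) fills the 2 s
  stimulation window.
* Subthreshold-membrane-oscillation (SMO) period $T = 200$ ms, phase 0:
  the cosine peaks at $kT$ then define exactly 10 slots in 2 s, and
  snapping pulses to peaks simultaneously enforces the 200 ms minimum
  inter-pulse interval and the 5 Hz maximum stimulation rate, and yields
  the 8×10 binary matrix view.

Raw times are aligned to the nearest peak (ties to the earlier peak;
times past the last peak at 1.8 s snap onto it, the window being
half-open), and duplicate aligned times within a channel merge into one
pulse — the compression step that caps each channel at 10 pulses. A
significance floor (default $p \ge 0.05$ emits a pulse; set 0 to disable)
reproduces the class-dependent sparseness of encoded programs. Program
dissimilarity is the Euclidean distance between the 8×10 binary matrices.

# The simulated culture

No desk-scale model reproduces a living culture; the simulator is a
phenomenological stand-in with the reported statistical structure, and is
itself first-class, tested code:

* **Spontaneous activity**: per-channel homogeneous Poisson background
  (default 0.5 Hz) plus network-wide synchronized bursts (2/min, 60%
  participation, ~100 ms envelope), with a 2 ms per-channel refractory
  period.
* **Evoked activity**: an inhomogeneous Poisson superposition. A pulse at
  $t_p$ on electrode $e$ adds on channel $c$ an expected $G_{ec}$ spikes
  with density $G_{ec}/\tau \cdot e^{-(t-t_p-\ell)/\tau}$ after a 2 ms
  latency $\ell$. The kernel time constant $\tau = 50$ ms makes the
  evoked rate at 0.2 s post-pulse < 2% of its peak, matching the observed
  return to baseline within 0.2 s. The refractory period is not imposed
  on this superposition: it would thin coincident evoked spikes and break
  the exact mean-recovery property (expected extra count per pulse equals
  the gain) that the tests verify.
* **Gains**: drawn log-normally per (electrode, channel) with 60%
  sparsity, giving each stimulation electrode a distinct channel
  signature so distinct programs evoke separable patterns.
* **Plasticity drift**: a per-stage multiplier $d^{s}$ on the
  class-separable component of the gain matrix (the deviation from the
  channel-wise mean), the phenomenological counterpart of
  training-induced improvement. $d = 1$ disables it.

The raw-signal path (Gaussian noise plus a stereotyped biphasic waveform
at each event; band-pass 300–3000 Hz zero-phase 4th-order Butterworth;
threshold 5.5 × robust noise sd, estimated as median(|x|)/0.6745; 2 ms
refractory) mirrors standard extracellular spike detection, with the
filter realization and robust estimator chosen as field standard since
only the band edges and the 5.5 multiplier are prescribed.

What passing tests show: the pipeline's statistics behave as designed
under Poisson-like activity with exponential evoked transients. What they
do not show: robustness to real cultures' non-stationarity, electrode
drift, bursting pathologies, or true synaptic plasticity.

# Decoding

Each 2 s trial is binned into 10 windows of 200 ms per recording
electrode after discarding spikes within 10 ms of *any* stimulation pulse
(the printed rule says "after stimulation"; blanking every pulse is the
conservative reading). The concatenated counts are reduced by PCA (keep
95% variance, capped at n−1 components) and classified by a multinomial
logit in which the last class — the spontaneous pattern — is the
reference whose coefficients are implicit. The fit minimizes the mean
cross-entropy plus a small ridge (1e−6) on non-intercept coefficients via
damped Newton steps (iteratively reweighted least squares with step
halving), so the loss trace is monotone non-increasing; tests verify the
optimum against an independent BFGS minimization of an independently
coded objective. The ridge exists because separable synthetic data makes
the unpenalized maximum-likelihood estimate diverge.

Two degenerate-input contracts matter:

* A zero-variance feature matrix (a blank chip without neurons) bypasses
  PCA with zero components; the intercept-only logit on balanced classes
  then yields exactly equal class probabilities, the tie breaks
  deterministically to the first class, and the balanced 10-pattern test
  scores exactly 10% — the chance floor, reproduced without randomness.
* Prediction ties always break to the lowest class index.

The staged protocol delivers each of 9 programs 50 times. Stage $s$
trains on its 15-trial block (1–15, 16–30, 31–45) of every pattern plus
the stage's spontaneous segments, and tests on the 5 trials immediately
after that block (16–20, 31–35, 46–50). Written out, 45 training + 15
disjoint test trials cannot fit in 50, so the first two stages' test
trials are later reused as training for the next stage — the reading
consistent with a continuous recording in which "five firing data after
each stage" are evaluated. A `pooled = TRUE` flag trains a single decoder
on all stages instead of refitting per stage.

# Connectivity

The STTC between two trains uses coincidence tiles of half-width
Δt = 10 ms, with tiles merged by interval union and clipped at the
recording edges. Degenerate cases are defined rather than left undefined:
an empty train gives 0 with a warning, and denominators are clamped away
from 0 by 1e−12.

Representative channels (40) are chosen by K-means on electrode
coordinates (10 restarts, fixed seed), one channel per centroid with a
next-nearest rule for duplicates; clustering on coordinates preserves the
spatial layout, and an activity-weighted variant was deliberately left
out of scope. Edge significance is decided against spike-time jitter
surrogates (uniform ±50 ms, 100 repetitions, one-sided α = 0.05): jitter
destroys millisecond-scale coincidence while preserving rates, which is
exactly the null needed for a coincidence statistic. Modules come from
consensus clustering: 100 weighted Louvain runs under random node orders,
co-assignment matrix thresholded at 0.5, reclustered until stable (≤ 10
rounds). The within-module degree z-score uses the population standard
deviation over a module's nodes (so a star hub whose degree is exactly
mean + 2 sd scores z = 2), with singleton or zero-spread modules set to
z = 0; the participation coefficient is $1 - \sum_s (K_{is}/K_i)^2$ with
isolated nodes at 0. Before/after comparisons use Welch t-tests per
metric, with identical degenerate samples reported as t = 0, p = 1.

One notation point: the symbol used for node strength elsewhere also
names "the module of node i" in the z-score definition; internally the
two are kept as distinct quantities (`strength` vs the partition).

# Seeds, sizes and limits

Every stochastic operation takes an integer seed; the pipeline fans a
single global seed out through stable component tags, so one integer
reproduces a whole run bit-identically. Test and example problem sizes
are chosen as the smallest that exercise each property cleanly: extractor
fixtures of 4–8 images per class with 2–10 epochs, sessions of 9 × 50
trials at 16–64 channels, connectivity graphs of 12–20 nodes with 25–100
surrogates, and STTC calibration over 200 independent 600 s Poisson
pairs. The full-scale defaults (1024 channels, 40 representatives, 100
surrogates, 50 epochs) remain the module defaults.

Known limitations: the simulator has no biophysics, no spike-timing
dependent plasticity, and no electrode geometry; the extractor is tiny by
design and trained on silhouettes; decoding offers no alternative
classifiers; connectivity is undirected (no transfer entropy or Granger
causality) and computes no small-world statistics. The serialization
formats are deliberately plain text (CSV/JSON/GraphML) for portability
and inspectability.
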