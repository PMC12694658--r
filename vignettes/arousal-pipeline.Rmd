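---
title: "Estimating electrodermal arousal from LiDAR reflection intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating electrodermal arousal from LiDAR reflection intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidarousal)
```

## The problem

Electrodermal activity (EDA) — skin conductance driven by eccrine sweat
glands — is one of the most direct physiological indices of sympathetic
arousal, but it is conventionally measured with electrodes on the fingers,
which rules it out for applications such as driver monitoring. An active
near-infrared range sensor (LiDAR) pointed at the forehead observes the
intensity of backscattered light, which is modulated by skin hydration and
sweat-duct activity. If those reflectivity fluctuations track the phasic
EDA component, arousal can be estimated without skin contact.

`lidarousal` implements the complete analysis for testing that idea:
signal cleaning, phasic/tonic decomposition, a rank-percentile arousal
statistic, k-class labeling, feature-based and sequence-based estimation
from LiDAR input windows, and evaluation under both random-split and
leave-one-subject-out (LOSO) validation. Because no public recording set
exists for this paradigm, the package ships a first-class synthetic-data
generator that emulates the laboratory protocol, so every downstream stage
is testable end to end.

## The arousal factor

The target statistic is a *rank-percentile arousal factor* computed per
sliding segment of the phasic EDA signal:

1. take a context window of length $T_c$ (default 100 s);
2. z-normalize the context (population standard deviation);
3. average the last $T_t$ seconds (default 10 s) — the *terminal window* —
   to obtain the current value $m$;
4. the factor is the empirical percentile of $m$ in the context, shifted
   to a symmetric scale:
   $$f \;=\; \frac{100}{N}\,\bigl|\{\,x_i \le m\,\}\bigr| \;-\; 50
   \;\in\; [-50, +50].$$

$f = +50$ marks a strongly positive arousal change (the recent level
exceeds everything in the context), $0$ a neutral course, $-50$ a strongly
negative one. Because only ranks enter, the factor is invariant under any
positive affine rescaling of the signal, which absorbs the extreme
inter-individual differences in absolute EDA amplitude.

Ties are counted with the $\le$ rule above; a `midrank` variant (ties at
half weight) is available behind a flag and off by default. A perfectly
constant context has no rank distribution and is rejected as a degenerate
signal rather than silently mapped to an extreme. One subtlety worth
stating: since the current value is the terminal *mean*, a strictly
increasing ramp yields $f = +45$ for a 10%-length terminal window (the
mean sits at the centre of the terminal stretch), and $f = +50$ exactly
only in the limit of a one-sample terminal.

For classification the factor is discretized into $k$ equal-*width* bins
over $[-50, +50]$ (the upper edge belongs to the last class). Equal width,
not equal mass: the factor distribution is bell-shaped around zero, so the
extreme classes are rarer and the class-count imbalance ratio grows with
$k$ — which is why balanced accuracy is used downstream.

## Cleaning and decomposition

Both channels get the identical cleaning chain — zero-phase 4th-order
Butterworth low-pass (default cutoff 3 Hz at 20 Hz sampling) followed by a
centered running-mean detrend (default window 120 s). The EDA channel is
additionally decomposed into a tonic component (zero-phase low-pass at
0.05 Hz by default, the conventional skin-conductance-level band) and a
phasic residual, so tonic + phasic reconstructs the cleaned signal at
machine precision. Finally each channel is z-normalized per participant;
tonic and phasic are expressed in the same normalized units so the
conservation identity survives normalization.

Numerical choices:

* filters are applied forward-backward over an odd-reflected extension of
  roughly twelve cutoff periods, because plain forward-backward filtering
  carries no initial-condition handling and its edge transient at a
  0.05 Hz cutoff lasts on the order of $10\,f_s/f_c$ samples;
* the running-mean detrend removes a linear ramp exactly in the interior
  and drops no samples;
* z-scores use the population (1/N) standard deviation throughout.

A recovery caveat that matters for testing: the tonic estimator absorbs
*all* sub-cutoff power, including the slow envelope that a stochastic
train of skin conductance responses (SCRs) genuinely has (response-rate
and amplitude fluctuations, the rest-to-stimulation level step). The
phasic estimate therefore correlates near-perfectly with the simulator's
latent phasic only for a stationary, deterministic response train; under
stochastic elicitation part of the latent phasic lives in the tonic band
by construction. The unit tests assert both regimes (r > 0.95
deterministic, r > 0.8 stochastic).

## The synthetic-data generator

`sim_config()` / `generate_dataset()` emulate the study protocol: a 5 min
dark-screen rest followed by 240 visual stimuli of 5 s each, both channels
sampled at 20 Hz, five subjects by default — 1500 s and 30,000 samples per
channel per subject. The generative model, chosen as the minimal structure
that reproduces the qualitative shape of real recordings:

* **Tonic level**: $\text{SCL}(t) = s_0 e^{-\lambda t}$ with $s_0 = 8$
  a.u. and $\lambda = 2\times10^{-4}\,\mathrm{s^{-1}}$ — the slow decline
  seen over a prolonged session as general arousal habituates.
* **Phasic responses**: each stimulus elicits an SCR with probability 0.7
  after a 1 s latency; the response kernel is the bi-exponential
  $a\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ with rise $\tau_r = 0.75$ s and
  decay $\tau_d = 4$ s (the conventional SCR shape), normalized so $a$ is
  the peak amplitude, drawn as $\mathcal{N}(0.5, 0.15^2)$ truncated at
  zero. Amplitudes shrink by 0.5% per elicited response (stimulus-level
  habituation). Optional per-stimulus arousal weights scale the amplitude.
* **LiDAR channel**: $\text{baseline} + g\,\text{phasic}(t - \ell) +
  \text{drift} + \varepsilon$, with a subject-specific gain
  $g \sim \mathcal{N}(\mu_g, \sigma_g^2)$, a 0.2 s lag, a slow sinusoidal
  intensity drift and white sensor noise. Linear coupling is an idealized
  stand-in for the (unknown) mapping from sweat-duct activity to
  near-infrared reflectivity.

Every latent component (tonic, phasic, noise, gain) is stored on the
recording, enabling exact conservation checks and parameter-recovery
tests. A single global seed expands into per-subject substreams, so
recordings are bit-reproducible and enlarging the cohort does not perturb
existing subjects.

What the generator deliberately does **not** model: skin optics, motion
and distance artifacts (the emulated setup head-mounts the sensor),
valence, nonlinear or state-dependent coupling, and realistic
inter-individual response topology beyond the gain. Tests that pass on
this generator therefore demonstrate the *pipeline's* correctness and the
qualitative train/test phenomenology — not that real LiDAR recordings
carry the signal.

## Models

Two families, mirroring the two ways the problem is usually attacked:

* **Feature-based**: a fixed, ordered 12-feature summary of each 10 s
  LiDAR input window (moments, least-squares slope, autocorrelations at
  lags 1/5/10, first ACF zero crossing, zero-crossing rate, spectral
  centroid and entropy) feeds classical learners — Extra Trees, Random
  Forest, k-NN, Gradient Boosting, SVM, logistic regression for
  classification; Extra Trees, Random Forest, Gradient Boosting, XGBoost
  for regression. Library defaults plus a fixed seed; the models are
  deliberately not tuned. Autocorrelations use the unbiased
  normalization, so a sinusoid at a full-period lag scores 1 regardless
  of window length. Features undefined on degenerate windows are imputed
  as 0 and flagged. (A LightGBM family is declared for completeness but
  unavailable in this build.)
* **Sequence-based**: GRU, LSTM, a 1-D CNN and a temporal convolutional
  network (TCN) consume the raw 200-sample window through a small,
  fully-tested neural-network engine written for this package (im2col
  convolutions, BPTT recurrences, reverse-mode gradients verified against
  central differences). Defaults follow convention for small baselines:
  GRU/LSTM hidden size 64; CNN with three conv blocks (kernel 5, channels
  16/32/64, max-pool 2); TCN with four dilated causal blocks (kernel 3,
  dilations 1/2/4/8, 32 channels). Training uses Adam at learning rate
  0.001 for 75 epochs — cross-entropy with batch size 32 for
  classification, mean-squared error with batch size 128 for regression —
  with seeded initialization and minibatch order, so training is exactly
  reproducible.

Regression is trained on the unit factor scale $[0, 100]$; predictions
are clipped to that range and reported on the centered scale
$[-50, +50]$. The models never see factor or class values at prediction
time.

An important interpretation constraint resolved here: the factor's
context is 100 s, but the model input is only the *terminal 10 s* of the
LiDAR channel. The models therefore estimate a context-relative quantity
from a context-free window — feasible to the extent that context
distributions are stable across segments.

## Validation and metrics

* **Random split**: 75/25 over segments, subject-blind — the
  within-subject upper bound.
* **LOSO**: one fold per subject; measures cross-subject generalization.
  Fold predictions are pooled before computing headline metrics; per-fold
  (macro) values are reported alongside. A class absent from a fold's
  test labels is dropped from that balanced-accuracy mean and logged.

Classification reports balanced accuracy (BA, the mean of per-class
recalls) and the chance-corrected *normalized improvement*
$$\mathrm{NI} = \frac{\mathrm{BA} - c}{1 - c}, \qquad c = \tfrac1k,$$
which is 0 at chance and 1 at perfection for every $k$. Regression
reports MAE, RMSE and $R^2$ on the centered scale, Pearson $r$ with its
t-transform p-value, and Bland–Altman agreement: bias = mean difference,
SD = sample (n−1) standard deviation, limits of agreement
$\text{bias} \pm 1.96\,\mathrm{SD}$.

## Two methodological caveats the simulations expose

**Noise-fingerprint leakage.** With a dense segment stride (default 10
samples = 0.5 s), adjacent LiDAR windows share 90%+ of their samples. A
subject-blind random split then places near-duplicates of most test
windows in the training set, and memorizing models can return the
temporal neighbour's factor — *even when the LiDAR channel is pure noise*
(NI ≈ 0.2 instead of 0 in a fully decoupled simulation). With
non-overlapping input windows the null lands at chance, as it should.
Random-split results on densely strided segments must therefore be read
as within-subject interpolation bounds, never as generalization
estimates; the package's null-coupling tests use non-overlapping windows
for exactly this reason.

**Sign-invariant features rescue LOSO.** Flipping the sign of the
coupling gain across subjects does *not* by itself break cross-subject
generalization: SCRs are unipolar, so magnitude features (variance,
autocorrelation structure) still carry the factor regardless of the
gain's sign. Only when sensor noise drowns those magnitude cues — leaving
the signed features that do not transfer across sign flips — does LOSO
collapse while the random split stays high, reproducing the qualitative
random-vs-LOSO gap that motivates subject-held-out evaluation.

## Problem sizes used by the test suite

The suite exercises scaled-down sessions chosen as the package's own test
conditions: most unit tests use two subjects with a 100 s rest and 60
stimuli; the coupling-recovery check uses the full five-subject protocol
(1500 s per subject) with the default dense stride (~14,000 segments);
the null and split-gap checks use five subjects with larger strides
(~600–3,000 segments). The idealized-coupling condition fixes gain 3,
channel noise 0.005, no drift, and *matched-band processing*
(detrend window 20 s, tonic cutoff 0.01 Hz): the factor can only be
recovered from LiDAR if the band the factor's context sees is the band
the LiDAR channel retains, so the short detrend window takes over the
tonic role for both channels symmetrically.

## Limitations

* The linear, single-lag coupling model is the strongest idealization;
  real reflectivity responses are likely nonlinear and time-varying.
* The tonic/phasic split by frequency is simpler than deconvolution-based
  decompositions; it is adequate here because the factor uses ranks, not
  SCR event amplitudes.
* Sequence models run on a compact CPU engine; at the default 75 epochs
  they are slower than framework implementations, and the architectures
  are small fixed baselines, not tuned.
* Nothing in the synthetic evaluation speaks to whether real LiDAR
  intensity carries electrodermal information — that is an empirical
  question for real recordings.
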