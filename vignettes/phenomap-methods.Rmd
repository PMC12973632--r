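---
title: "phenomap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenomap: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

This vignette explains the science and the engineering behind each stage of
the pipeline: what is being modeled, which parameters matter and why they
default to what they do, what the synthetic generators emulate (and do not),
and where genuinely open design questions were settled.

## 1. Sleep staging

### The model

A mouse telemetry recording carries EEG and EMG at 500 Hz and an activity
count at 1 Hz. Staging operates on 20-s epochs through three factors:

* **delta ratio** — epoch EEG power in 0.5–4 Hz divided by a
  recording-level baseline delta power. Slow-wave (delta) activity is the
  signature of NREM sleep.
* **theta-to-delta ratio** — epoch theta power (6–9 Hz, the scoring band)
  over epoch delta power. Theta dominance marks REM; note this scoring
  band is deliberately distinct from the 4–8 Hz theta band of the
  seven-band periodogram scheme used for reporting spectra.
* **EMG ratio** — epoch EMG power over a recording-level baseline. Muscle
  tone is high in wake, moderate in NREM, and near-absent in REM
  (atonia).

Each factor carries per-stage membership functions anchored at the stated
maximum-probability points (delta 0.5 → wake/REM, 1.0 → NREM; theta/delta
1.3 → wake/NREM, 3.0 → REM; EMG 1.1 → REM/NREM, 2.4 → wake). Only the
peaks are specified by the source procedure; the interpolation between
them is open. We chose **triangular memberships** — linear decay from a
stage's anchor to the neighboring stage's anchor and constant 1 beyond the
outermost anchor on the stage's own side — as the minimal interpolation
consistent with the stated peaks. The shape lives entirely behind
`scoring_params()` so alternatives can be swapped in.

The three factor memberships are combined as an equally weighted mean
(whether the upstream software combines factors additively or
multiplicatively is unknown; equal-weight additive was chosen and is
confined to one function). Epochs whose summed activity count reaches 0.1
have their wake score forced to the maximum *before* normalization, so
EEG/EMG evidence cannot override observed movement. Boundary conventions
are fixed and documented: membership and activity comparisons use ≥,
artifact amplitude and the 1% exclusion use strict >.

### Baselines: the central reconstruction

The source procedure never defines the denominators of the delta and EMG
ratios (they are internals of the vendor scorer). We reconstruct them as
the **median** of the per-epoch delta (and EMG) power over all
non-artifact epochs. The median is robust to artifacts, and under a
realistic stage mix — mice spend slightly more than half of all epochs in
NREM across 24 h — it lands on the NREM cluster, which is exactly the
normalization under which the published anchors make sense (NREM delta
ratio ≈ 1, wake and REM ≈ ≤ 0.5; NREM EMG ratio ≈ 1, wake ≈ 2.4). This is
the module's most consequential assumption and is isolated so it can be
replaced.

### Transition thresholds as hysteresis

The six stated stage-pair "transition probabilities" (e.g. wake→NREM 90%,
REM→wake 70%) are interpreted as **evidence thresholds for leaving the
current stage**, not as Markov priors: they are asymmetric, near 1, and
their semantics match switch resistance. Decoding is forward-greedy: start
at the first scorable epoch's best stage; at each epoch, switch to the
argmax candidate only if its score reaches the threshold for that specific
transition. A Viterbi-style global decoder is a possible alternative; the
forward-greedy form was chosen because the stated thresholds are local
rules, and determinism and auditability matter more here than global
optimality.

One deliberate deviation deserves emphasis: the thresholds are compared
against the candidate stage's **membership score** (bounded by 1), not
against the sum-normalized posterior. With triangular memberships sharing
anchors across stages, a perfectly stage-typical epoch still grants a
competing stage membership 1 on one factor, which caps the normalized
posterior near 0.6 — below every stated threshold, so posterior-scale
thresholds could never fire for any epoch. On the membership scale a
clean stage-typical epoch scores ≈ 1 and transitions behave as intended.

Ties in the argmax are broken by a fixed canonical stage order (W, S, P),
so results cannot depend on the storage order of internal tables.

### Artifacts

An epoch is an artifact if any EEG or EMG sample magnitude exceeds 0.5 mV
(the per-recording threshold used for most recordings in the source
procedure); a recording with more than 1% artifact epochs is excluded
outright and yields an exclusion report instead of a hypnogram. Artifact
epochs inside a kept recording retain the label `ARTIFACT`, do not update
the decoder state, are excluded from baseline medians and z-score moments,
and break bout runs.

## 2. RBD-like events

RMS-EMG is computed per epoch from the raw EMG samples, z-scored over all
non-artifact epochs of the recording, and a REM epoch whose z strictly
exceeds 2 is an RBD-like event (REM without atonia). Choices worth
stating:

* the z-score uses the **population** SD (divide by *n*), the spreadsheet
  convention of the original Excel workflow; `zscore_rms(population =
  FALSE)` switches to the sample SD.
* "higher than 2 SD" is strict (>), not ≥.
* statistics are per 20-s epoch, not per merged bout, because the source
  counts events in the 20-s signal grid — epoch = event.
* artifact epochs are excluded from the z moments (the source is silent;
  including saturated epochs would inflate the SD and mask true events).
* animals with no REM epochs at all are flagged and excluded from RBD
  statistics rather than given a 0/0 ratio.

A useful structural fact: if a fraction *p* of epochs sits at wake-level
EMG, the largest attainable z for those epochs is √((1−p)/p) — about 1.25
when wake occupies 39% of the recording. RBD-like events are therefore
only detectable as z > 2 because phasic REM EMG bursts exceed the typical
wake tone; the synthetic generator encodes exactly that.

## 3. Spectra

Band powers use Welch averaging: 1024-point (2^10) Hamming-tapered
segments with 50% overlap — at 500 Hz a ~2-s segment inside each 20-s
epoch, read off the stated "10/1024 FFT order". Powers integrate
one-sided PSD bins whose center frequency lies in [f_lo, f_hi), so shared
edges are never double-counted (4 Hz belongs to theta in the periodogram
scheme). The seven bands (delta 0.5–4, theta 4–8, alpha 8–12, sigma
12–16, beta 16–24, low gamma 24–49, high gamma 51–80 Hz) are expressed
relative to the 0.3–80 Hz total, so the 49–51 Hz notch and the 0.3–0.5 Hz
margin count toward the denominator but no band — band sums are ≤ 100 by
construction. Relative powers are invariant to global amplitude scaling,
and agree with a rectangular-window DFT oracle to within 2 percentage
points on broadband test signals whose tones sit on the DFT grid away
from band edges (off-grid tones make the *oracle* leak through its own
rectangular-window sidelobes; the comparison is designed so the oracle is
exact).

## 4. Photometry

The normalization chain is fixed in the stated order: downsample to
500 Hz by non-overlapping window averaging → F/F0 against a 5-s centered
moving baseline → z-score per 1-min window → average over the 20-s
scoring epochs. Details:

* the 1017→500 Hz ratio is non-integer, so windows are fractional
  (area-weighted through cumulative sums); this preserves the mean of the
  consumed input exactly, which integer truncation would not.
* "F/F0" is taken literally (a unitless ratio around 1); `dff_moving(mode
  = "delta")` provides (F−F0)/F0 since the two conventions differ only by
  a constant and a scale within any z-scored window.
* 1-min z windows are anchored to the recording start, not wall clock;
  zero-variance windows yield zeros with a warning.
* partial edge epochs of the ~30-min session are dropped, not padded.
* **no isosbestic regression or subtraction is applied anywhere.** The
  isosbestic channel is processed identically and serves as a statistical
  comparator (its stage contrasts should be ≈ 0); animals whose sensor
  channels do not differ from the isosbestic are excluded, mirroring the
  source's exclusion rule.

A consequence worth knowing: the 5-s moving baseline removes any
*sustained* stage-level offset within ~2.5 s of its onset, so what the
chain actually measures is phasic structure — transient rate and
amplitude — plus onset/offset dynamics at stage boundaries. Effects
injected as slow constant shifts are largely invisible by design; this is
a property of the published chain, not of this implementation.

## 5. Brain maps (DAB ROI densities)

Sections are converted to 8-bit gray, inverted (255 − I) because DAB
deposits are dark on a light background — without inversion, density
would anticorrelate with staining — then divided by the whole-image mean
signal (output mean exactly 1), and downsampled into 5×5-pixel ROI blocks
(ragged edges truncated). Normalization-then-ROI ordering and
conversion-then-normalization were chosen where the source is silent. The
"30 µm²" ROI figure printed in the source conflicts with 5×5 blocks of
6.25-µm² pixels and is not used computationally; the ROI is defined
purely by the block factor.

Per ROI, groups are compared with a vectorized one-way ANOVA (validated
against `aov` in the tests); Dunnett comparisons against the control group
use the multivariate-t familywise adjustment; and the onset map reports
the earliest timepoint whose control contrast is significant at that
timepoint *and every later one*. p-values are reported raw across ROIs to
match the source's maps (a Benjamini–Hochberg option exists, off by
default). Cross-animal registration is the caller's responsibility; the
module checks only shape equality.

Two honest caveats. First, whole-image mean normalization redistributes a
large focal effect: darkening 15% of the image raises the global mean, so
unaffected ROIs in affected animals drift slightly *below* 1 and can show
opposite-sign "effects" — visible in synthetic studies and inherent to
the published normalization. Second, with five ordered timepoints an
early-timepoint Dunnett contrast is spuriously significant in ~5% of
truly-affected ROIs, shifting the detected onset one step early by
chance; onset percentages should be read with that base rate in mind.

## 6. Cluster counting

The threshold "95%" is read as the image's 95th signal percentile,
computed as an order statistic (quantile type 1) so the mask is exactly
invariant under monotone intensity transforms; `mode = "fraction_of_max"`
gives the alternative reading. Touching clusters are split with a
distance-transform watershed (EBImage) with a 3-px neighborhood radius to
damp over-segmentation. Size classes follow the printed bounds exactly,
including their mixed units: ≤ 1 px excluded as specks, > 15,000 µm²
(i.e. > 2,400 px at 6.25 µm²/px) excluded as artifacts, small (1, 50] px,
medium (50, 200] px, large > 200 px — half-open on the left so 50 and 200
are never double-counted. Densities are counts per tissue area. Whether
ImageJ's binary watershed would segment identically is not claimed; the
contract is the distance-transform behavior verified against a flood-fill
oracle on non-touching blobs and on the overlapping-disc fixture.

## 7. The statistical decision tree

`gated_anova()` implements the study's rule: Bartlett's test on the group
variances gates between classical one-way ANOVA with Tukey all-pairs
(p > 0.05) and Brown-Forsythe + Welch ANOVA with Dunnett-vs-control
(p < 0.05); two groups redirect to a t-test. The Dunnett adjustment is
computed from the multivariate-t distribution of the max-|t| statistic
(numerical integration to ~1e-4, locally seeded so results are
reproducible); with one comparison it reduces exactly to the pooled
two-sample t-test, and the tests cross-check it against a 200,000-draw
Monte-Carlo oracle and against `multcomp`. The classical (pooled-variance)
Dunnett is used on both branches; an unequal-variance T3 variant is a
known omission. Unbalanced two-way sex×group designs test the interaction
as the sum-contrast marginal (type-III-style) improvement over the
additive model.

ROUT outlier detection is implemented for the constant (mean-only) model,
the case the study applies it to: robust center = median, robust scale =
the 68.27th percentile of absolute residuals with the n/(n−1) correction,
per-point t p-values with n−1 df, and a Benjamini–Hochberg
false-discovery step at Q (default 5%). It is applied per group rather
than pooled (the source is silent; pooling would let group differences
masquerade as outliers).

## 8. Behavioral indices

All indices are deterministic arithmetic with validation. One convention
deviates from the printed text: the sucrose preference index defaults to
sucrose/(sucrose+water) ∈ [0, 1], because the literal "ratio of water to
sugar consumption" contradicts the reported direction of the effect (a
reduced index with reduced sucrose intake); the literal ratio remains
available behind `literal = TRUE`. The operant log walk matches each
retrieval to the most recent unretrieved delivery and counts latencies
≤ 10 s; animals with zero correct pokes in two consecutive sessions are
flagged for exclusion.

## 9. What the synthetic generators emulate — and what they do not

`sim_config()` fixes the study conditions: a semi-Markov stage process
(explicit geometric dwells, because real sleep bouts span many epochs and
the bout statistics need that structure) whose stationary mix puts NREM
just above half of all epochs (wake ≈ 39%, NREM ≈ 54%, REM ≈ 7%) — the
regime in which the median baselines land on the NREM cluster and the
published anchors are meaningful. Per-stage EEG is a delta + theta
sinusoid pair over an AR(1) noise floor, placed well inside the anchors'
constant-membership regions (NREM delta-dominant, REM theta-dominant at
theta/delta ≈ 5, wake mixed at ≈ 0.8); EMG is a sinusoidal carrier with
stage-dependent tone, wake tone drawn per epoch from a range (movement
variability), and REM atonia except a configurable fraction of RBD-like
epochs carrying phasic bursts at the top of the wake range — strong
enough to clear z = 2 against the whole-recording moments, as real
RBD-like events must be. Atonia-loss is injected into non-bout-initial
REM epochs: REM onset is defined by atonia, and the modeled events are
phasic EMG within established REM episodes (a bout whose first epoch
already had wake-level EMG would be indistinguishable from wake at onset
by any EMG-based scorer). Activity is Poisson in wake and zero otherwise.

Photometry channels share a baseline, slow drift and noise; sensor
channels add stage-class-dependent mean shifts and exponential transients
(τ = 0.4 s, the sub-second kinetics of the dopamine/ACh sensors), with
dopamine transients elevated and ACh reduced in RBD-like epochs. The
isosbestic carries no stage dependence, so its recovered contrasts bound
the pipeline's bias. Section images are Gaussian background texture with
group-wise darkening in a known pixel block from a chosen timepoint
onward, and exact-pixel-area clusters placed with minimum separation.

What passing these tests does **not** show: real EEG is broadband and
nonstationary rather than a two-tone mixture, so the ≥ 90% synthetic
scoring accuracy is an upper bound, not a field estimate; real EMG
artifacts, electrode drift, bleaching and section misregistration are not
modeled; and the photometry generator's transients are memoryless, unlike
real release events. The generators are designed to make the *logic* of
every stage falsifiable against known truth, not to be biophysically
realistic.

## 10. Numerical choices and problem sizes

Determinism is enforced throughout: every stochastic generator takes a
seed, the Dunnett integration runs under a locally saved-and-restored RNG
state, and scoring the same recording twice is bit-identical. Degenerate
inputs have defined behavior rather than NaN surprises: all-zero epochs
flag NaN band powers with a warning, zero-SD z-scores return zeros with a
warning, zero-variance ANOVA cells error or return NaN p as documented,
and recordings shorter than one epoch are rejected.

The test and acceptance workloads use 1–2-h recordings at the full 500 Hz
(accuracy and RBD recovery over 20 seeds), 30-min photometry sessions at
1017 Hz over 20 seeds, 200 null section studies for the 5% calibration,
50 random blob images, and 500-seed null calibrations for the statistical
tests — sizes chosen so the full suite exercises every claim at
meaningful power while remaining a few minutes of compute on one CPU.
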