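---
title: "Methods: closed-loop reflex operant conditioning in silico"
author: "reflexop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop reflex operant conditioning in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexop)
```

## The protocol this package computes

Operant conditioning of the H-reflex trains a person to raise or lower the
excitability of a spinal reflex pathway. Each trial follows the same
contingency: ongoing EMG in the target muscle (soleus) and its antagonist
(tibialis anterior) must stay inside configured ranges continuously for a
hold period, and a minimum interval must have elapsed since the previous
stimulus; only then is a constant-current pulse delivered to the tibial
nerve. The evoked response contains an early M-wave (direct motor-axon
activation, the *reference* response) and a later H-reflex (the
monosynaptic reflex arc, the *target* response). In training runs the
participant sees immediately whether the H-reflex fell on the rewarded side
of a criterion threshold, together with a cumulative success rate.

`reflexop` implements every computational stage of that loop — background-
level estimation, contingency gating, epoch measurement, recruitment-curve
and distribution analysis, criterion setting, and session bookkeeping — and
closes the loop against a virtual participant instead of hardware.

## Background-level estimation

The background level is the mean rectified value of the high-pass-filtered
signal in a trailing sliding window, computed per frame.

* **High-pass filter.** The published protocol does not specify the filter
  family or cutoff. We use a causal 2nd-order Butterworth high-pass,
  default cutoff 10 Hz: it removes DC electrode offset and motion artifact
  while leaving the surface-EMG band (tens to hundreds of Hz) intact.
  The filter is applied block-by-block with carried state, and filtering a
  partitioned stream is bit-identical to filtering the concatenation — the
  property that makes live and offline analyses agree exactly, and which
  the test suite checks on random partitions (including single-frame
  blocks).
* **Window.** The window length is likewise unpublished; we default to a
  200 ms trailing window — responsive enough for bar feedback, long enough
  to smooth over individual motor-unit bursts. During the first 200 ms of
  a run the mean is taken over the samples available.
* **Units.** Signals are held in millivolts at the skin after dividing out
  the amplifier gain (default 500), so range settings are physiologically
  interpretable.

## The stimulation gate

The gate is a small state machine per frame: an in-range timer that
advances only while *both* muscles are inside their (inclusive,
possibly one-sided or blank) ranges and resets to zero otherwise, and an
inter-stimulus timer. A stimulus fires when the in-range timer reaches the
hold duration (default 2 s) and the inter-stimulus timer reaches the
mode's minimum interval (default 5 s normally, 3 s in stimulus-test mode,
where the range contingency is waived entirely). Both timers reset on
firing, so every trial requires a fresh, uninterrupted hold; whether
pre-stimulus in-range time should carry over is not specified anywhere, and
resetting is the conservative reading of "continuously in range".
Timing is quantized to one processing frame; the batch gate (`run_gate()`)
is an algebraically equivalent segment-jumping scan of the per-frame rule,
and the tests verify equality against a literal frame-by-frame fold.

## Response measurement

Epochs span 50 ms before to 100 ms after the stimulus, covering typical
soleus M-wave (≈6–25 ms) and H-reflex (≈25–50 ms) latencies. Measurement
windows are half-open `[start, end)` intervals in ms post-stimulus,
defaulting to reference = [6, 23) and target = [28, 45); in practice they
are adjusted per participant and persisted. Window edges are mapped to
frames as `floor(start·fs/1000) … floor(end·fs/1000) − 1`. Sizes are
peak-to-peak (max − min) or mean rectified amplitude of the windowed
segment. The stimulus artifact is excluded simply by starting the
reference window after 0 ms; no artifact blanking is applied.

## Aggregation and criteria

* **Recruitment curves.** During a recruitment-curve run the stimulus
  current is raised every 4 trials (2 mA steps from 5 to 41 mA by
  default), so consecutive groups of 4 trials are pooled and paired with
  their intensity; `M_max`/`H_max` are the largest pooled reference and
  target sizes. A trailing partial group is averaged over its actual size.
* **Percentile convention.** Criterion thresholds interpolate linearly
  between order statistics (`stats::quantile()` type 7). The convention is
  declared so thresholds are reproducible bit-exactly.
* **Criterion.** With target percentile P (default 66), down-conditioning
  succeeds when the size is at or below the P-th percentile of the
  defining sample; up-conditioning when at or above the (100−P)-th.
  Ties at the threshold count as success — the deterministic,
  participant-favorable choice; the original software's tie behavior is
  unpublished.
* **Reference stability.** A run is flagged when its mean M-wave deviates
  from the nominal value by more than ±15% (the protocol only requires it
  be "roughly constant"; 15% is our declared default), and per-trial
  deviations locate the onset of any drift.

## The virtual participant

The simulator emulates the statistical structure of the real signals, not
their biophysics:

* **Background EMG** is Gaussian white noise band-passed to 20–250 Hz and
  scaled so its expected mean rectified value equals the participant's
  drive level; the scale factor comes from the half-normal mean
  (E|X| = σ·√(2/π)) and the filter's numerically computed noise gain.
* **Drive behavior** follows an Ornstein–Uhlenbeck-like relaxation (τ =
  2 s, relative SD 15%) around the standing level (0.025 mV), so holds
  succeed most of the time but occasional range exits occur — the
  trial cadence this produces (≈5–6 s/trial) matches a practiced
  participant.
* **Evoked responses** are biphasic sine-under-Hann templates whose
  discrete peak-to-peak amplitude is normalized to exactly 1, so a
  programmed amplitude is recovered exactly by a peak-to-peak measurement
  when noise is disabled (the round-trip identity the tests assert at
  1e-9).
* **Recruitment** uses logistic forms: M(I) = M_max·σ(s_m(I−i50_m)) rises
  and saturates; H(I) = e·H_max·σ(s_h(I−i50_h))·(1−σ(s_c(I−i_coll)))
  rises then falls, with the multiplicative suppression standing in for
  antidromic collision. Only these qualitative shapes are constrained by
  observation; the functional forms are modeling choices and every
  parameter is configurable. Defaults (M_max 6 mV, H_max 3 mV, midpoints
  12/18/28 mA) put the M-wave plateau near 30 mA and the H-reflex peak
  near 20 mA, matching a typical adult soleus recruitment at these
  currents.
* **Plasticity** multiplies an H-reflex excitability state by (1 ∓ r) on
  each reinforced trial (r = 0.005 by default, clipped to [0.2, 2.0]);
  r = 0 disables conditioning. Real conditioning changes the reflex by a
  percent or two per session over weeks; the default rate deliberately
  compresses that course so a directional effect is measurable within a
  single simulated session. It models the phenomenon, not a mechanism.
* **Per-trial response noise** defaults to 15% SD (multiplicative,
  truncated at zero); the real trial-to-trial variance is not published,
  so this is a declared assumption.

What passing closed-loop tests do **not** show about real data: the
simulator has no stimulus artifact, no slow electrode drift or gel
drying, no postural or diurnal nonstationarity, no motor-unit structure,
and its noise is exactly band-limited Gaussian. Results on it validate the
computational engine, not clinical efficacy.

## The closed loop

`simulate_run()` advances the virtual participant and the processing
pipeline in one-second generation chunks: raw signal is synthesized,
filtered and windowed with carried state; the gate is scanned per frame;
on a stimulus the evoked templates are injected into the raw stream, the
affected span of the background trace is recomputed (the trace bump after
each stimulus naturally resets the hold, as it would live), the epoch is
measured, and — in training mode — the classification feeds back into the
participant's excitability before the next trial. Chunked storage keeps
each of these operations local, so runs scale linearly in duration;
the tests verify that the live, incrementally computed trace is identical
(to 1e-9) to re-processing the persisted recording in one pass.

Session orchestration follows the published templates: baseline = RC,
3×(CT, 75), RC; conditioning = RC, (CT, 20), 3×(TT, 75), RC; follow-up
sessions mirror either. In a conditioning session the criterion is adopted
from the 20-trial control run and re-adopted after every training run, and
each adoption is auto-logged. A full protocol is 6 baseline + 24 (30 with
neurological impairment) conditioning + 4 follow-up sessions.

## Persistence

Run containers are RDS payloads (raw signals, events, trial table, config
snapshot) with a human-readable JSON sidecar, named
`YYYYMMDD-HHMM_<ID>_<MODE><NN>`; the name carries the session date-time,
participant ID, mode code (ST/VC/RC/CT/TT) and sequential run number.
The original system's exact binary format and the name's delimiter layout
are not reproduced — the name's *content* is. Run numbers are gap-free
across modes, writing never overwrites (it is a hard error), and a session
started within the last three hours of a relaunch is continued rather than
recreated. All timestamps are injectable, so tests are deterministic.

## Numerical choices and degenerate inputs

* Quantile type 7; ties at criterion thresholds are successes.
* Hold/interval thresholds use a 1e-12 slack so that exact multiples of
  the frame duration fire on the expected frame.
* A zero-trial success rate is undefined and returned as a zero-length
  vector (displayed blank).
* An epoch that would extend past the recording is rejected with a
  diagnostic, never truncated.
* A blank range bound imposes no restriction; an empty window after
  discretization is an error.
* The gate makes no assumption about a maximum wait per trial; closed-loop
  runs carry a generous time guard that stops a run with a warning if the
  participant never satisfies the contingency.

## Problem sizes used in the test suite

The suite exercises the full protocol constants (75/20-trial runs, pools
of 4, the 5–41 mA ladder) and uses 20-seed replications for the
statistical properties: recruitment recovery uses low-noise sweeps (2%
response noise, per the calibration used to validate parameter recovery),
and the directional-conditioning comparison runs paired full conditioning
sessions with plasticity enabled versus disabled. Criterion calibration
uses 10,000 defining and 10,000 fresh log-normal draws. These sizes were
chosen so the entire suite completes in a few minutes on a laptop while
keeping every statistical check adequately powered.

## Known limitations

* No automatic latency/window detection; windows are set explicitly.
* No automated stimulus-intensity servo; recruitment sweeps follow a
  declared ladder and conditioning runs a fixed intensity.
* No gait-cycle or alternative contingency criteria.
* The GUI of a live system is out of scope; feedback state (background
  bar, success flag, cumulative rate) is exposed as data a front-end
  could render.
* Exact binary compatibility with any particular acquisition platform's
  file format is out of scope.
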