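---
title: "Detecting running gait events from wearable accelerometers"
author: "gaitstride"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting running gait events from wearable accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstride)
```

## The problem

Spatiotemporal running gait analysis needs two events per step: initial
contact (IC), when the foot first touches the ground, and toe off (TO), when
it leaves it. Their difference is the ground contact time (GCT). On an
instrumented treadmill these events are read off the vertical ground
reaction force (vGRF) with simple thresholds; outside the laboratory only
body-worn accelerometers are available, and the signals they produce vary
with speed, foot strike pattern, surface and runner. `gaitstride` implements
threshold-free, automation-oriented detectors for a foot-mounted and a
low-back-mounted tri-axial accelerometer, the force-plate gold standard for
validating them, a sliding-window engine that emulates real-time processing,
and the agreement machinery (event matching, skipped-step accounting,
Bland-Altman limits of agreement, per-condition summaries) needed to compare
the methods.

## Signal model and assumptions

All detectors share a small set of biomechanical assumptions:

* **Cadence bounds.** The time between contralateral ICs lies between
  0.25 s and 0.50 s (240 down to 120 steps/min), and between 0.5 s and
  1.0 s for ipsilateral (same-foot) ICs. Reported preferred running
  cadences cluster in 150-192 steps/min, so these bounds are deliberately
  generous.
* **Stance floor.** TO occurs no earlier than 0.1 s after IC.
* **Axis conventions.** Foot: ML + right, AP + posterior, VT + superior.
  Raw back: ML + right, VT + superior, AP + posterior; gravity alignment
  (below) re-expresses the back signal with AP + anterior.
* **Steady-state running.** Trials are trimmed to continuous running
  (`trim_trial()`: 15 s per end of a 90 s treadmill trial, or the first and
  last 5% of an overground trial) before detection. The detectors assume
  every analysis window may contain gait; see *Limitations*.

Preprocessing applies a fourth-order zero-lag (forward-backward)
Butterworth low-pass at 10 Hz to every channel. Because R's
`signal::filtfilt()` does not match initial filter states, `lowpass()`
filters relative to the first sample and pads both ends by 0.5 s of odd
reflection; DC then passes exactly and the edge transient is below 1e-9.

**Gravity alignment (back only).** The trial-mean acceleration vector is
taken as the gravity estimate - over whole strides the motion component
averages out - and the minimal (axis-angle) rotation carrying it onto +VT is
applied to all samples, after the raw-axis remap (including the AP sign
flip) which is itself a proper rotation. Heading about VT is left untouched:
detection uses only VT and the ML sign, neither of which depends on heading.
Alignment refuses trials whose mean acceleration magnitude falls outside
[0.5, 1.5] g, since such a sensor is evidently not measuring gravity at
rest-plus-motion. A static-calibration alignment would also be defensible;
the trial-mean variant needs no extra data and is what the package uses.
The foot signal is never aligned: its IC feature is the resultant
magnitude, which is rotation-invariant.

## Detection

**Force (gold standard).** IC is the first sample at or above 10 N after a
below-threshold interval; TO is the last sample at or above 25 N within
that loaded region. Loaded regions shorter than 0.1 s are treated as noise
and dropped entirely, and consecutive ICs must be at least 0.25 s apart
(0.5 s in single-foot-plate mode). Event times are sample times - no
sub-sample interpolation - so force and accelerometer events share one
discrete time base.

**Foot.** IC candidates are local maxima of the resultant
$\sqrt{ML^2+AP^2+VT^2}$; TO candidates are local minima of VT (equivalently
peaks of $-VT$). **Back.** IC candidates are local maxima of VT (the impact
peak is visible at the low back for steps of both sides); TO candidates are
again minima of VT.

No absolute g threshold appears anywhere. A candidate peak is admitted when

1. its topographic prominence exceeds $k \times$ the window's MAD-based
   spread (`peak_prominence_factor`, default $k = 1$; MAD rather than SD
   because impact peaks inflate an SD), with a floor of 10% of the window's
   range so that filter ripple on near-constant windows is never admitted;
2. (IC only) its height exceeds the window median by the same margin -
   zero-lag filtering of a large impact leaves symmetric ringing lobes
   whose prominence can be inflated when the resultant folds a VT
   undershoot upward, and those lobes hug the median while true impacts
   stand clear of it;
3. (foot IC only) the resultant falls to the window median or below within
   0.15 s before the peak (late-swing quiescence; rejects mid-stance
   oscillation). "At or below" rather than strictly below, because in a
   noise-free window the baseline *equals* the median.

Every admitted candidate is emitted, including pairs closer than the
cadence floor and TO candidates with no IC in the window - candidate
*selection* is entirely the consolidation stage's job. All three rules are
invariant to positive rescaling of the window, preserving the central
design goal of accommodating runners whose signals never reach a fixed
magnitude.

## Sliding-window engine and consolidation

Windows `[k*shift, k*shift + window_size)` advance by `shift` (the "change
in window start time") until less than 1 s of data remains; a final partial
window of at least 1 s is still processed. Candidates are pooled uniquely
by (kind, frame index) - overlapping windows re-detect the same peak at the
same frame, so duplicates collapse deterministically. The supported
parameter grid spans {50, 100, 200} Hz x {1, 2, 5} s x
{0.005, 0.01, 0.02, 0.1, 0.5, 1} s; the package default
(200 Hz, 2 s, 0.02 s) is the accuracy/throughput compromise used in all
examples, and `grid_run()` reproduces the full 54-cell sweep.

Consolidation walks IC candidates in consecutive triples. When two
consecutive candidates are closer than the site's minimum separation, each
is checked for cadence viability and, if both or neither are viable, the
greater candidate magnitude (resultant for foot, VT for back, vGRF for
force) wins; ties go to the earlier candidate, and the winner is
re-examined against the next candidate. A candidate closer than the
minimum separation to the previously *retained* IC is dropped outright.
Viability means: not closer than the minimum separation to the previously
retained IC nor to the next potential IC. An earlier design also
disqualified candidates whose neighbour gaps *exceeded* the maximum
separation, but that rule proved wrong: a genuine 6 g impact was discarded
because its distance to a trailing noise candidate was 1.03 s (just over
the 1.0 s ipsilateral maximum), handing the step to the noise candidate. A
gap larger than the maximum signals a missed detection, not an implausible
contact, so only the minimum bounds disqualify.

Per retained IC, TO candidates at or before the IC are removed; among those
in `[IC + 0.1 s, next IC)` (bounded by the maximum separation after the
last IC), the greatest $-VT$ magnitude is retained, ties to the earlier.
ICs with no admissible TO are kept and flagged as IC-only steps rather than
dropped, since IC and TO retention are evaluated separately. Events within
0.1 s of the trial edges are flagged provisional and excluded from method
comparisons. Consolidation is idempotent, and with the default overlapping
windows the final event table is invariant to shifting the window grid by
0.005 or 0.01 s.

**Step side (back only).** The mean ML acceleration over ±0.05 s
(`side_window`) around each retained IC encodes the stance side: positive
(rightward) means a right step under the default convention
(`side_sign_right = "+"`), a mean of exactly zero deterministically yields
left, and an interval extending beyond the trial yields unknown. The sign
convention is configurable because the rule is convention-sensitive on real
sensors; on synthetic trials with a constructed ML signature it is exact.

`measure_output_rate()` emulates streaming throughput (1 / wall time per
frame from first window appearance to final evaluation). Its values are
hardware-dependent and never enter pass/fail logic; the only portable
statement is directional - larger shifts process faster.

## The synthetic generator

`simulate_trial()` produces co-registered foot, back and force trials with
exact ground-truth labels. Step times sit on a jittered grid (Gaussian
jitter, SD 1% of the step period, clamped) so windows never phase-lock to
events, with alternating sides. Defaults encode a typical steady-state
treadmill trial: cadence 170 steps/min, GCT 0.68 of the step period
(~0.24 s), 60 s duration, 200 Hz accelerometers, 1000 Hz force plate,
0.05 g channel noise, 8 g foot impact peaks, 3 g TO dips, 0.3 g ML side
signature, 700 N body weight. The stance vGRF is a double-hump (rearfoot)
or single-hump (forefoot) profile scaled to body weight whose first and
last stance samples sit at 50 N, pinning the 10 N up-crossing and the last
≥25 N sample to the true IC and TO samples exactly; waveform shape between
the crossings is deliberately schematic. The back trial is emitted in the
raw sensor convention, tilted 8° in the sagittal plane, so the alignment
step is genuinely exercised.

What the generator does *not* emulate: soft-tissue resonance, drift,
inter-step waveform variability beyond timing jitter and additive white
noise, asymmetric gait, or any biomechanical consequence of speed, surface
or foot strike beyond the impact-width and vGRF-shape switches. Passing
tests therefore demonstrate that the machinery recovers events whose
generating structure matches its assumptions - they do not certify accuracy
on real runners, which in the validation literature is established against
force plates.

## Problem sizes and tolerances in the test suite

The suite validates (sizes chosen as a sensible desk-scale workload): exact
equivalence of the force detector with an independent brute-force scan on
1000 randomized 2 s vGRF trials; zero skipped truth steps and ≥95% of
events within 0.03 s (IC) / 0.05 s (TO) on twenty 60 s trials spanning
150-192 steps/min at 0.05 g noise; window-phase invariance on noise-free
12 s fixtures; consolidation invariants and idempotence over 120 randomized
candidate pools; perfect, strictly alternating sides on noise-free trials
with exact label flip under the inverted convention; Bland-Altman closed
form to 1e-12; and recovery of an injected +0.05 s back-foot IC offset
within two standard errors on a six-subject cohort. `scripts/acceptance.R`
re-runs the same machinery end to end and writes the measured quantities as
JSON.

## Known limitations

* **Signal-free segments produce junk candidates.** With no absolute
  threshold, a window containing only noise has a noise-scale adaptive
  floor, so a trial tail after the last step can yield spurious
  low-magnitude "steps" (reported as extra steps, never as skips). Real
  use trims trials to continuous running, which removes the situation; the
  acceptance report includes the observed extras honestly.
* **Side assignment on real sensors is imperfect** (reported wrong-side
  rates on real data are substantial); the synthetic ML signature makes it
  exact here, so side tests validate the rule's mechanics, not its field
  accuracy. An optional alternation-enforcement pass was considered and
  rejected: the package counts wrong sides rather than hiding them.
* **The exact per-window operator chain of the source methods is not
  printed anywhere**; the operators above (resultant impact peak, VT
  impact peak, -VT extremum, median-clearance and quiescence checks) are
  this package's declared reading, not a byte-level transcription of the
  original MATLAB.
* **Output rate is hardware-bound** and excluded from all assertions.
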