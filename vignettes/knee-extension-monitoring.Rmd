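---
title: "Monitoring knee-extension rehabilitation from surface EMG and accelerometer tilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring knee-extension rehabilitation from surface EMG and accelerometer tilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemon)
```

## The measurement problem

Seated knee-extension exercise is a staple of quadriceps rehabilitation: the
subject sits, extends the knee from the resting position (0°) towards a fully
stretched-out leg (90°), holds the peak position for a few seconds, and
returns. Clinicians want three quantities per session:

* **ROM** — the range of motion, $\mathrm{ROM} = |\theta_{\max} -
  \theta_{\min}|$, of the knee-extension angle $\theta(t)$;
* **MAV** — the mean absolute value of the surface EMG,
  $\mathrm{MAV} = \frac{1}{N}\sum_{n=1}^{N}|x(n)|$;
* **RMS** — its quadratic mean,
  $\mathrm{RMS} = \sqrt{\frac{1}{N}\sum_{n=1}^{N}x(n)^2}$,

computed for the two heads of the quadriceps most involved in patellar
stabilisation, the vastus lateralis (VL) and vastus medialis (VM), and
compared with clinician-set target thresholds to produce a binary
pass (1) / not-pass (0) bio-feedback signal per target family.

`kneemon` implements the full evaluation pipeline over a two-channel EMG
recording and an accelerometer-derived knee-angle trace, plus a seeded
simulator used to validate every stage end to end.

## Signal conditioning

Surface EMG is conditioned by three causal IIR sections applied in order:

* high-pass, 4th-order Butterworth, corner 10 Hz — removes motion artifact
  from electrode-wire movement and slow skin-potential drift;
* low-pass, 4th-order Butterworth, corner 500 Hz — removes wide-band noise
  above the useful surface-EMG band;
* a biquad notch at 50 Hz with quality factor 30 — removes mains (AC
  baseline) interference, with optional harmonic notches at 100/150 Hz.

The corner frequencies mirror a conventional analogue sEMG front end; the
digital realisation lets the whole chain be verified numerically. The design
contract, asserted by tests directly on the coefficients, is: at least 20 dB
attenuation at DC and at the notch frequency, and no more than 3 dB of ripple
across the 20–400 Hz passband excluding ±2 Hz around the notch. Filter order
4 and Q = 30 are standard sEMG practice; with the default 2000 Hz sampling
rate (comfortably above twice the 500 Hz corner) all poles sit well inside
the unit circle.

Causal single-pass filtering is the default because the system it models is
a real-time monitor; `zero_phase = TRUE` switches to forward–backward
filtering for offline analysis and is flagged in the recording's metadata.

```{r filters}
chain <- design_filter_chain(filter_chain_spec())
round(filter_chain_gain_db(chain, c(1e-6, 10, 50, 100, 400)), 2)
```

## Features

MAV and RMS are computed in non-overlapping 250 ms windows by default. The
window length is a free parameter (the source protocol does not state one);
250 ms is a common sEMG choice, long enough for a stable amplitude estimate
at 2000 Hz (500 samples) and an integer multiple of the 100 ms angle-sample
period, which keeps window edges alignable with angle timestamps. A trailing
window shorter than half the nominal length is dropped rather than reported
from too few samples.

Repetition-level features are the mean of the window features whose midpoint
falls inside the repetition interval ("active-segment" scope). A whole-trial
scope is available (`feature_scope = "trial"`) for sensitivity checks,
because published per-session averages do not state which convention their
instrumentation used; active-segment is the default since rest periods
dominate a session's duration and would otherwise dilute the EMG averages
roughly tenfold.

## Angle, ROM and repetition segmentation

The knee angle comes from accelerometer tilt: with the shank quasi-static,
the measured specific force is gravity, and the knee-extension angle is the
angle between the measured gravity vector and its direction in the sitting
calibration pose. Samples whose magnitude falls outside 0.5–1.5 g indicate
free fall or shaking and are rejected rather than converted. Angles are
clipped to [−15°, 105°], slightly beyond the nominal 0–90° operating range;
values outside raise a data-quality warning.

Repetitions are segmented with a Schmitt trigger on a smoothed trace:

1. the trace is smoothed with a centred 0.9 s moving average;
2. the resting angle $\theta_{rest}$ is the median of the first 2 s;
3. a repetition opens when $\theta$ rises above $\theta_{rest}+10°$ and
   closes when it falls below $\theta_{rest}+5°$ (the 10° opening threshold
   matches the clinical floor for a countable extension movement, and the
   5° hysteresis prevents chatter at the threshold);
4. the active core is then extended outward to the nearest local minimum of
   the smoothed trace (within a 3 s margin, bounded by the midpoint to the
   neighbouring repetition) so that the interval covers the full
   rest-to-rest cycle and $\theta_{\min}$ reflects the rest posture;
5. repetitions with ROM below 10° are discarded; a trailing cycle still
   active when the trace ends is discarded as incomplete, which is exactly
   the behaviour wanted when a session is stopped early for safety.

Two numerical choices deserve a note. Extrema of a noisy trace are biased
outward — the maximum of ~40 hold samples with 0.5° noise overshoots the
true plateau by about 1°, and the rest minimum undershoots similarly, so raw
per-repetition ROM would be biased high by roughly 2°. Reading extrema off
the 0.9 s smoothed trace cuts the sample noise by √9 and the net ROM bias to
about 0.5°, while leaving a 4 s plateau's height untouched (the smoothing
window is much shorter than the plateau). Ties at the peak resolve to the
first sample attaining the maximum.

The *sustained contraction* (the hold at the peak, target 3–6 s in the
protocol) is measured as the total time at or above 90% of that repetition's
peak angle. For an ideal 2 s rise / 4 s hold / 2 s fall trapezoid this yields
4.4 s — the 0.9 threshold adds ~0.2 s of ramp on each side of the plateau —
and the rise/sustained/fall durations tile the repetition interval to within
one sample period. The 0.9 fraction is configurable; there is no published
tolerance for "holding at the peak position", so the fraction is a design
choice made once.

## The session engine

`run_session()` executes the monitoring workflow: condition the EMG, extract
windowed features, segment repetitions from the angle trace, attach
repetition-level features, average across repetitions, and compare against
the targets. Pass/fail semantics:

* a family passes when its session average **meets or exceeds** the
  threshold (ties pass — for a rehabilitation target, reaching the target is
  success; `strict_comparison = TRUE` flips this);
* the MAV and RMS families require **both** VL and VM to meet their
  thresholds (`channel_rule = "either"` relaxes this) — the conservative
  reading of a single displayed flag per family;
* the hold-duration target is recorded (`hold_within_target`) but does not
  gate passing: the pass criteria are the MAV, RMS and ROM thresholds only;
* `completed` is TRUE exactly when the detected repetition count equals
  `reps_per_set * n_sets`; an early stop keeps all fully completed
  repetitions and reports `completed = FALSE`.

Outputs are deterministic: identical inputs and configuration produce
byte-identical result files.

## The simulator

The simulator generates the kind of recording the pipeline assumes, with
known ground truth:

* **angle** — trapezoidal excursions (2 s rise, 4 s hold, 2 s fall, default
  peak 88°) separated by rest, plus white Gaussian sensor noise (default
  σ = 0.5°). The inter-repetition rest defaults to the prescribed 60 s and
  may be compressed to 2 s so that a five-repetition session spans ~52 s in
  tests without changing the signal structure.
* **EMG** — per channel, amplitude-modulated band-limited (20–450 Hz)
  unit-variance Gaussian noise: the standard surrogate for surface EMG. The
  envelope is `gain × (θ(t)/peak)^envelope_exponent`, decays exponentially
  during the hold (default 0.02 /s) to mimic fatigue, and rides on wide-band
  baseline noise (σ = 0.005 V) plus a 50 Hz power-line sinusoid (0.01 V
  amplitude). Those two noise levels are package choices — low enough that
  repetition-level features are dominated by the modulated EMG, high enough
  that the notch demonstrably matters. Peak envelope gains default to
  0.19 V (VL) and 0.13 V (VM), the amplitude scale of healthy subjects under
  a 1 kg ankle load, and the VL gain must be ≥ the VM gain, reproducing the
  consistent VL > VM amplitude ordering seen in loaded knee extension.

Everything is deterministic per seed, and simulation never perturbs the
caller's RNG stream. Subject presets (`healthy`, `bone_joint`, `neuro`)
scale gains, peak angle and peak-to-peak variability to echo the qualitative
contrast between healthy subjects and the two patient groups; they are
conveniences for demos and tests, not physiological models.

What the simulator does **not** emulate: motor-unit firing structure,
electrode lift-off and other non-stationary artifacts, EMG onset genuinely
preceding movement (available but off by default), torque/load dynamics, or
day-to-day electrode placement variability. Pipeline guarantees validated on
simulated data therefore cover the signal-processing contract, not clinical
accuracy on real patients.

```{r pipeline}
rec <- simulate_recording(simulation_config(seed = 7, rest_s = 2))
cfg <- session_config(mav_threshold_v = 0.01, rms_threshold_v = 0.01,
                      rom_threshold_deg = 60)
run_session(rec$emg, rec$angle, cfg)
```

Validation scale: the recovery checks in the test suite run 100 seeded
five-repetition sessions with 0.5° angle noise and compressed 2 s rests —
about 52 s of trace per session — and require the detector to find exactly
five repetitions in at least 99 of them with a mean per-repetition ROM error
of at most 1°. These sizes give stable statistics while keeping the whole
suite inside a half a minute.

## Reporting

`summarize_subject()` collapses sessions to one row per subject (average
ROM, MAV and RMS per channel), `aggregate_group()` takes fieldwise means
over a group and week (optionally pooling patient groups), and
`progress_report()` computes last-minus-first deltas with an improvement
band: deltas within ±0.001 V (EMG) or ±0.1° (ROM) are classified
"unchanged", since differences at the last printed digit of the measurement
are not meaningful. The package bundles the published per-subject reference
table (six healthy subjects; six patients in two diagnosis groups, measured
first and last week of a month of rehabilitation) as
`reference_summaries()`; the test suite verifies that every group-level mean
recomputes exactly, at printed precision, from those per-subject rows.

```{r reporting}
ref <- reference_summaries()
a_first <- aggregate_group(ref[ref$group_label == "bone_joint" &
                               ref$week_label == "first", ])
a_last <- aggregate_group(ref[ref$group_label == "bone_joint" &
                              ref$week_label == "last", ])
cat(render_report(progress_report(a_first, a_last), "Bone/joint group"))
```

## Known limitations

* The tilt model assumes a quasi-static shank; fast extensions add a
  centripetal/tangential acceleration component that biases the angle. A
  gyroscope fusion would fix this and is out of scope.
* The angle-threshold detector assumes movement returns near rest between
  repetitions; continuous oscillation without rest would merge cycles.
* MAV/RMS thresholds are absolute volts and therefore electrode- and
  gain-dependent; no normalisation (e.g. %MVC) is attempted because the
  monitoring protocol it models uses raw amplitudes.
* Group aggregation is purely descriptive — means over members — with no
  between-group inference.
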