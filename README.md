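# kneemon

Evaluation pipeline for seated knee-extension rehabilitation exercise,
monitored with two-channel surface EMG over the vastus lateralis (VL) and
vastus medialis (VM) muscles and an accelerometer-derived knee-extension
angle. The package is for engineers and researchers building or validating
quadriceps-rehabilitation monitors: it turns raw recordings into the three
quantities clinicians track per session, compares them with target
thresholds, and reports per-subject and per-group progress.

The core quantities, per session:

* range of motion: `ROM = |θ_max − θ_min|`, where `θ(t)` is the
  knee-extension angle in degrees (0° = sitting rest, 90° = stretched-out
  knee), sampled every 100 ms;
* mean absolute value of the EMG: `MAV = (1/N) Σ |x(n)|`;
* root mean square of the EMG: `RMS = sqrt((1/N) Σ x(n)²)`;

computed per channel in 250 ms windows after digital conditioning
(4th-order Butterworth high-pass at 10 Hz, low-pass at 500 Hz, 50 Hz notch).
Repetitions — rest, rise, sustained hold near the peak, fall — are
segmented from the angle trace with a hysteresis detector, and the session
passes a target family (MAV, RMS, ROM) when its repetition average meets
the clinician-set threshold: 1 = passing, 0 = not passing.

A seeded simulator generates coupled angle + EMG recordings (trapezoidal
trajectories; amplitude-modulated band-limited Gaussian EMG with fatigue
decay, baseline noise and 50 Hz contamination) so the whole pipeline is
testable end to end with known ground truth.

## Worked example

```r
library(kneemon)

# one five-repetition session: 88 deg peaks, 0.5 deg sensor noise,
# rests compressed to 2 s
rec <- simulate_recording(simulation_config(seed = 7, rest_s = 2))

cfg <- session_config(mav_threshold_v = 0.01, rms_threshold_v = 0.01,
                      rom_threshold_deg = 60)
run_session(rec$emg, rec$angle, cfg)
#> <session_result> subject anonymous: 5 repetition(s), completed = TRUE
#>   avg ROM 88.5 deg | MAV VL/VM 0.0897/0.0614 V | RMS VL/VM 0.1127/0.0770 V
#>   pass flags: MAV=1 RMS=1 ROM=1
```

All five repetitions were found; the average ROM (88.5°) is within half a
degree of the simulated 88° peak, the VL channel carries more amplitude
than VM as expected for loaded knee extension, and all three averages clear
their thresholds, so every pass flag is 1.

Group-level reporting over the bundled per-subject reference table:

```r
ref <- reference_summaries()
a_first <- aggregate_group(ref[ref$group_label == "bone_joint" &
                               ref$week_label == "first", ])
a_last  <- aggregate_group(ref[ref$group_label == "bone_joint" &
                               ref$week_label == "last", ])
cat(render_report(progress_report(a_first, a_last), "Bone/joint group"))
#> Bone/joint group (last - first):
#>   mean_rom_deg     85.5000 ->   87.1667  delta  +1.6667  [improved]
#>   mean_mav_vl_v     0.0723 ->    0.0913  delta  +0.0190  [improved]
#>   mean_mav_vm_v     0.0693 ->    0.0853  delta  +0.0160  [improved]
#>   mean_rms_vl_v     0.1033 ->    0.1330  delta  +0.0297  [improved]
#>   mean_rms_vm_v     0.0987 ->    0.1237  delta  +0.0250  [improved]
```

The bone-and-joint patient group improved on every tracked quantity over
the month, gaining 1.7° of average ROM.

A command-line wrapper with `simulate`, `process` and `report` subcommands
is installed at `inst/cli/kneemon`:

```sh
Rscript inst/cli/kneemon simulate --out-dir demo --seed 3
Rscript inst/cli/kneemon process --emg demo/emg.csv --angle demo/angle.csv --out demo
```

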