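# tonopulse

Quantifies how the cardiac (blood-pulsation) phase modulates intraocular
pressure (IOP) readings taken with air-puff tonometry.

IOP pulses within each heartbeat as choroidal blood volume changes (the
*ocular pulse*). An air-puff tonometer samples the pressure at whatever
instant the measurement is triggered, so repeated readings of the same eye
differ systematically with the cardiac phase at the trigger. `tonopulse`
implements the full analysis chain for measuring that coupling from two
ordinary data streams — the high-speed Scheimpflug deformation movie the
tonometer records, and a finger pulse-oximeter trace — plus a synthetic-data
module that generates both with known ground truth, so the whole pipeline is
testable without clinical recordings.

## What it computes

Per measurement, a feature vector:

| feature | meaning | units |
|---|---|---|
| w(1), w(2) | first / second applanation time (momentary corneal flattening on indentation and recovery) | ms |
| w(3) | maximum corneal deformation at the apex | mm |
| w(4) | corneal vibration frequency (> 100 Hz) | Hz |
| w(5) | IOP, read from the device | mmHg |
| w(6) | cardiac phase at the trigger, binned to 30° | deg |

w(1)–w(4) come from the images: 3×3 median filtering, Canny-style edge
detection with hysteresis, 5th-degree polynomial contour completion,
decomposition of contour motion into resting shape + whole-eye response +
corneal reaction *L*<sub>HC</sub>, then threshold/peak/spectral feature
measurement. w(6) comes from systolic-peak detection and peak-to-peak phase
interpolation of the pulse trace.

Per subject *v*, the coupling is located by a phase-shift Pearson
correlation scan over a 10° grid of artificial shifts φ:

r<sub>v</sub>(j; φ) = pearson( w<sub>k,v</sub>(j),
cos(w<sub>k,v</sub>(6) − φ) ),  k = 1…K

whose argmax over φ estimates the phase lag between the finger pulse and
the IOP maximum (the minimum sits 180° away with r<sub>min</sub> =
−r<sub>max</sub>, identically). Significance is Student's *t* on K−2 df;
grossly aberrant subjects ("thick errors", max |r| < 0.3) are rejected
before pooling. See `vignettes/tonopulse-methods.Rmd` for the model,
parameter defaults and numerical choices.

## Worked example

```r
library(tonopulse)
res <- run_pipeline(run_config(n_subjects = 10, n_meas_per_subject = 6,
                               seed = 1))
print(res$summary)
#> <cohort_summary>
#>   10 subjects; non-synchronization IOP spread 0.79 mmHg
#>   retained 10 subjects (preset 'thick'): r_max 0.94 +/- 0.06 (pop. sd; sample sd 0.06)
#>   recovered pulse-to-IOP phase lag: 78 deg; 9/10 retained subjects significant at p < 0.05
```

This generates a synthetic 10-subject × 6-measurement cohort under the
package's documented study conditions (group phase lag 60 ± 40°, 0.75 mmHg
IOP modulation, 0.25 mmHg reading noise), runs the scan per subject, and
summarizes. The *non-synchronization spread* (0.79 mmHg here) is the
largest per-subject standard deviation of the IOP readings — how far
readings wander when the trigger is not synchronized to the heartbeat. The
recovered lag of a single cohort (78°) scatters around the injected 60°
with the population spread; averaging replicate cohorts pins the group
mean (see below). Rendering mode (`synthetic_mode = "render"`) additionally
draws every measurement as a 140-frame image sequence and measures it back
through the imaging stages.

Bundled under `inst/extdata/` are reference tables from the original
clinical measurement campaign (per-subject feature means, correlation
extrema); the test suite checks the package's summary statistics against
them: mean w(5) of the reference subject 15.25 ± 0.61 mmHg, pooled maximum
correlation over retained subjects 0.78 ± 0.19, largest per-subject IOP
spread 2.31 mmHg.

A thin CLI over the same functions lives at `inst/cli/tonopulse.R`
(subcommands `synth`, `extract`, `scan`, `run`).

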