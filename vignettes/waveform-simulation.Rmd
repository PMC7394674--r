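---
title: "Simulating arterial pressure waveforms for pulse-contour monitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating arterial pressure waveforms for pulse-contour monitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The problem

Manikin-based patient simulators script vital signs — heart rate (HR),
systolic and diastolic blood pressure (SBP/DBP) — but do not expose a
continuous arterial pressure waveform. Minimally invasive hemodynamic
monitors, on the other hand, take exactly that waveform as their input (as
an analog voltage on a transducer line) and derive flow-side quantities from
its contour. Bridging the two lets trainees see goal-directed-therapy
parameters on the same monitors they use clinically.

`pulsewave` implements that bridge entirely in software. The full loop is:

1. a **vitals source** supplies (HR, SBP, DBP) once per second, from a
   scripted scenario file or a synthetic generator;
2. a **pulse template** — a normalized single-beat waveform — is resampled
   to the commanded HR and amplitude-scaled so its maximum is SBP and its
   minimum is DBP;
3. the **waveform engine** concatenates those beats into a continuous
   pressure stream at a fixed output rate (250 Hz by default), via a
   producer/consumer pipeline with a bounded ring buffer;
4. the **signal output** stage maps pressure linearly to the monitor's
   analog convention, 0 mmHg at 0 V to 500 mmHg at 5 V, and quantizes to
   12-bit DAC codes (0–4095);
5. a **contour analyzer** plays the monitor's role at desk scale: it
   detects beats, recovers per-beat SBP/DBP/PP/MAP, windowed HR and pulse
   pressure variation (PPV), and verifies the round trip against the
   commanded vitals.

## The synthesis model

The core assumption is fixed morphology: every beat is an affine, resampled
copy of one reference beat. With template samples $n_i \in [0,1]$
(min exactly 0, max exactly 1), a beat at heart rate $f$ (bpm), output rate
$F$ (Hz), and pressures $(P_s, P_d)$ is

$$
p_i = P_d + n^{(f)}_i\,(P_s - P_d), \qquad
i = 1, \dots, \operatorname{round}(60F/f),
$$

where $n^{(f)}$ is the template linearly interpolated onto a uniform phase
grid of $\operatorname{round}(60F/f)$ points (rounding half away from zero,
stated explicitly so sample counts are reproducible) and re-pinned to span
$[0,1]$ exactly. Exact pinning makes the per-beat extrema land on the
commanded pressures exactly, which is what the amplitude round trip tests.

This can vary only the amplitude and rate of the wave, not its shape: no
pathology-specific contours (valve disease, arrhythmia), and no respiratory
modulation — consequently PPV of any steady run is exactly 0, and the
analyzer's PPV output is only exercised against scripted amplitude changes.

### The template

A real reference recording is not shipped; `make_synthetic_template()`
builds a parametric normal beat: a raised-cosine systolic upstroke peaking
at `systolic_fraction` (default 0.3) of the beat, an exponential diastolic
decay with time constant $(1-s)/3.2$ (so the end-of-beat value is
$e^{-3.2} \approx 0.041$), and a Gaussian dicrotic wave on the downstroke
(relative amplitude 0.15, centred 35% into the decay) marking aortic valve
closure. The width of the dicrotic wave, $(1-s)/16$, is chosen so the wave
forms a genuine secondary maximum, as on a real beat. The default template
carries the metadata of the emulated reference acquisition — 250 Hz
sampling, 47 bpm source heart rate, hence
$\operatorname{round}(250 \cdot 60/47) = 319$ samples.

Both template endpoints are required to be at most 0.05 (near end-diastole),
so concatenated beats are continuous: the jump at any beat junction of a
constant-vitals run is bounded by 5% of pulse pressure. When vitals change
between beats the junction additionally reflects the commanded step; that
discontinuity is the scenario's, not the synthesis'.

## Timing and the streaming contract

The engine's virtual clock advances in integer output samples, so runs are
bit-reproducible. The vitals source is polled every `poll_period` (1 s, the
cadence of the emulated simulator feed); each poll is validated — HR clamped
into the transmitted-variable limits [0, 350] bpm, pressures into the
representable [0, 500] mmHg, SBP ≤ DBP rejected — and published to the
consumer. Under the default **beat-atomic** policy a beat is synthesized
entirely from the newest vitals at its onset; a change never lands mid-beat.
The **immediate** policy instead retargets the amplitude map
sample-by-sample (beat length stays fixed at onset, since a started beat
cannot change duration). Beat-atomic is the default because it avoids
waveform discontinuities inside a beat.

`hr = 0` is a legal input meaning "no beats": the engine emits a flatline at
the current DBP (the decay target of an unperfused arterial tree) until the
next poll, and logs a warning.

R executes on a single thread, so the three pipeline roles — coordinator,
vitals poller, waveform consumer — are interleaved cooperatively on the
virtual clock rather than preemptively scheduled. The data-flow contract is
the one a threaded implementation must honour: a bounded single-producer /
single-consumer ring buffer (default capacity four template cycles,
blocking producer, with an overwrite policy available to emulate dropout),
and publish-before-consume ordering of polls. `mode = "concurrent"` routes
every template sample through that buffer; `mode = "deterministic"` is the
straight-line reference. The suite asserts the two streams are identical
sample-for-sample, which is exactly the property a real-time port has to
preserve.

## Output mapping

Pressure maps linearly to voltage, $v = p \cdot 5/500$, clamped (with a
warning) rather than erroring so the output stage can never crash a running
stream. Quantization uses $\mathrm{code} = \operatorname{round}(v \cdot
(2^{12}-1)/5)$, half away from zero: full scale is code 4095. Some DAC
chips divide by $2^{12}$ instead; the convention here is fixed and tested,
and the worst-case pressure error of the map-quantize-decode round trip is
half an LSB, $0.5 \cdot 500/4095 \approx 0.061$ mmHg.

## The analyzer

The analyzer is a deliberately generic beat-statistics oracle — openly
defined formulas only, no proprietary pulse-contour algorithm, no flow-side
estimates (CO, SV, SVR, SVV). Beats are segmented at diastolic troughs:
local minima separated by at least the refractory period $60/350$ s (one
beat at the 350 bpm HR ceiling). Two robustness refinements: an amplitude
gate rejects shallow minima such as the dicrotic notch (a candidate must
lie within 25% of the local range above the local minimum, both over a
window of ±max(1 s, 3 refractory periods) — local, so drifting pressures in
e.g. a hemorrhage scenario do not mask troughs), and when two candidates
fall within one refractory period the deeper wins. The local window means
detection is reliable for rates above roughly 30 bpm; slower rhythms than
that are outside the generator's range anyway.

Per beat: SBP = max, DBP = min, PP = SBP − DBP, and MAP by the textbook
approximation DBP + PP/3 (determinate, rather than the time integral). HR
is 60 over the mean beat period; PPV is the standard clinical definition
$100\,(PP_{max}-PP_{min})/((PP_{max}+PP_{min})/2)$ over a trailing window
(default 10 s, a typical monitor averaging window).

`roundtrip_report()` automates the verification that on the real bench was
done by eye on the monitor screen: per steady segment (≥ 5 analyzed beats,
excluding the transition beat after each change), the maximum absolute
error of recovered SBP, DBP and HR against the commanded values. The
package's core acceptance property is that a steady run at 250 Hz recovers
pressures within 0.5 mmHg and HR within 2 bpm — the pressure budget is
dominated by the half-LSB quantization error, the HR budget by the
beat-length rounding (e.g. at 70 bpm the synthesized period is 214/250 s,
i.e. an effective 70.09 bpm).

## Synthetic scenarios

`make_synthetic_scenario()` scripts the study conditions: `steady`
(70 bpm, 120/80 mmHg), `hemorrhage-ramp` (linear fall 120/80 → 70/50 mmHg
with compensatory tachycardia 70 → 120 bpm), and `hypotension-step` (abrupt
drop to 80/50 mmHg, 110 bpm at half time). Optional per-segment additive
Gaussian jitter (seeded, clamped post hoc into the vitals contract) is the
simplest reproducible stand-in for beat-to-beat variability. What the
generator does *not* emulate: baroreflex feedback, arrhythmia,
respiratory-cycle modulation, morphology change with pressure. Passing
round-trip tests therefore demonstrate the fidelity of the interface — not
that any clinical algorithm would behave identically on real patient waves.

## Numerical choices and problem sizes

- Beat-length and quantizer rounding: half away from zero, everywhere.
- Scenario segment boundaries are half-open: a segment takes effect exactly
  at its start time. The feed's behaviour between 1 s updates is not
  observable on the emulated link, so both step-hold (default) and linear
  ramp interpolation are provided.
- Pressure limits: the scripted SBP/DBP have no inherent ceiling, so the
  representable range of the output mapping ([0, 500] mmHg) is adopted as
  the validation clamp — values beyond it cannot be encoded in 0–5 V.
- Waveform files store floats at 6 significant digits, making write/read
  round trips bit-stable at that precision; DAC codes are exact integers.
- Test problem sizes: property suites run 1000 random 8 s scenarios for the
  voltage-range invariant, 20 for deterministic/concurrent equivalence, and
  a 60 s steady run for the round-trip fidelity check — together they keep
  the full suite under a minute while still exercising every branch of the
  pipeline (flatline, clamping, truncated final beats, buffer wrap).

## Worked example

```{r example, eval = FALSE}
library(pulsewave)

scenario <- make_synthetic_scenario("steady", duration = 60)
template <- default_template()
run <- run_pipeline(scenario, template)
glance(run)

wf <- as_voltage(run$waveform)
analysis <- analyze_waveform(
  tibble::tibble(t_s = wf$t_s, p_mmhg = decode_pressure(wf$dac_code)),
  fs = 250
)
glance(roundtrip_report(scenario, analysis))

autoplot(run)
autoplot(analysis)
```

## Known limitations

- Fixed beat morphology; only amplitude and rate vary.
- No respiratory modulation, so PPV/SVV physiology cannot be exercised; SVV
  and all flow-side quantities are out of scope.
- The beat detector is tuned to the shipped morphology class; arrhythmia or
  heavily damped traces would need a different detector.
- Wall-clock (true real-time) operation and I²C bus behaviour are not
  modelled; the DAC driver surface is a recording mock by design.
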