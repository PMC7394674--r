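# pulsewave

Simulation-based medical education scripts vital signs on a manikin
simulator, but advanced hemodynamic monitors do not read vital signs — they
read a continuous arterial blood-pressure waveform on an analog transducer
line and derive everything else from its contour. `pulsewave` synthesizes
that waveform in software: scripted (HR, SBP, DBP) values in, a continuous
250 Hz pressure wave and its DAC voltage codes out, with a pulse-contour
analyzer closing the loop so the commanded vitals can be verified against
what a monitor would recover. It is aimed at simulation engineers and
educators who want to feed pulse-contour monitors (or test their own
analysis code) without a patient, and without hardware.

## The model

Every beat is an affine, phase-resampled copy of one normalized reference
beat (fixed morphology). With template samples `n_i` spanning [0, 1]
exactly, heart rate `f` (bpm) and output rate `F` (Hz):

- beat length: `round(60 F / f)` samples (half away from zero),
- amplitude: `p_i = DBP + n_i (SBP − DBP)`, so `max p = SBP`, `min p = DBP`
  exactly,
- output mapping: `v = p × 5 V / 500 mmHg`, quantized to 12-bit codes
  `round(v × 4095 / 5)`; worst-case round-trip error half an LSB
  (≈ 0.061 mmHg).

Vitals are polled once per second (HR clamped into [0, 350] bpm, pressures
into the representable [0, 500] mmHg), and each beat is synthesized
atomically from the newest poll at its onset. A bounded ring-buffer
producer/consumer pipeline (`mode = "concurrent"`) reproduces the
deterministic virtual-clock stream sample-for-sample. The analyzer recovers
per-beat SBP/DBP/PP/MAP, windowed HR and pulse pressure variation using
openly defined formulas only — it is not a reimplementation of any
proprietary pulse-contour algorithm.

## Worked example

```r
library(pulsewave)

scenario <- make_synthetic_scenario("steady", duration = 60)  # 70 bpm, 120/80
template <- default_template()                                # 250 Hz, 47 bpm
run <- run_pipeline(scenario, template)
glance(run)
#> # A tibble: 1 × 7
#>   n_beats n_samples fs_out mode          duration_s n_warnings complete
#> 1      71     15000    250 deterministic         60          0 TRUE

wf <- as_voltage(run$waveform)        # adds volts and dac_code columns
head(wf, 3)
#>     t_s p_mmhg beat_index volts dac_code
#> 1 0       80            1 0.8        655
#> 2 0.004   80.0          1 0.800      655
#> 3 0.008   80.1          1 0.801      656

# analyze the quantized pressures a monitor would reconstruct
analysis <- analyze_waveform(
  tibble::tibble(t_s = wf$t_s, p_mmhg = decode_pressure(wf$dac_code)),
  fs = 250
)
glance(analysis)
#> # A tibble: 1 × 5
#>   n_beats hr_bpm ppv_pct window_s    fs
#> 1      70   70.1       0       10   250

glance(roundtrip_report(scenario, analysis))
#> # A tibble: 1 × 4
#>   sbp_max_abs_err dbp_max_abs_err hr_max_abs_err n_segments
#> 1          0.0244          0.0244         0.0935          1
```

Reading the numbers: a 60 s steady scenario at 70 bpm yields 71 beat onsets
and 15 000 samples (250 Hz × 60 s). The first sample sits at the diastolic
pressure, 80 mmHg → 0.8 V → code 655. After quantization the analyzer
recovers the commanded pressures within 0.025 mmHg and the heart rate
within 0.1 bpm (the HR offset comes from the beat length rounding to whole
samples: 214/250 s ≈ 70.09 bpm); PPV is 0 because no respiratory modulation
is synthesized. `autoplot(run)` and `autoplot(analysis)` draw the waveform
and the recovered per-beat pressures.

A command-line front end over the same functions lives in
`inst/scripts/pulsewave-cli.R` (subcommands `make-scenario`,
`make-template`, `run`, `analyze`).

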