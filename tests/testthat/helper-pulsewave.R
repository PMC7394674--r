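# Shared fixtures, built in code.

# One default template for the whole suite (319 samples, 250 Hz, 47 bpm).
tpl_default <- default_template()

# A two-segment step scenario used across modules.
two_segment_scenario <- function(interpolation = "hold", duration = 60) {
  vitals_scenario(
    data.frame(t_s = c(0, 30), hr_bpm = c(60, 90),
               sbp_mmhg = c(120, 90), dbp_mmhg = c(80, 60)),
    duration = duration, interpolation = interpolation
  )
}

# Random scenario draw used by the stochastic properties: kind, jitter
# magnitudes and the generator seed all derive from one integer, and the
# jitter is large enough that pressures can exceed the representable
# 0-500 mmHg range before the generator clamps them.
draw_random_scenario <- function(seed, duration = 8) {
  set.seed(seed)
  kind <- sample(c("steady", "hemorrhage-ramp", "hypotension-step"), 1)
  sds <- runif(3) * c(20, 200, 100)
  make_synthetic_scenario(kind, duration = duration, noise_sd = sds,
                          seed = seed)
}
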