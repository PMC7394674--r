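test_that("beat resampling yields round(fs * 60 / hr) samples", {
  expect_length(resample_beat(tpl_default, hr = 60, fs_out = 250), 250)
  expect_length(resample_beat(tpl_default, hr = 120, fs_out = 250), 125)
  expect_length(resample_beat(tpl_default, hr = 350, fs_out = 250), 43)
  # identity: resampling at the template's own rate and HR returns it verbatim
  expect_identical(resample_beat(tpl_default, hr = 47, fs_out = 250),
                   tpl_default$samples)
  expect_error(resample_beat(tpl_default, hr = 0, fs_out = 250), "hr")
})

test_that("resampled beats keep the normalized-range and endpoint invariants", {
  for (hr in c(30, 47, 70, 113, 350)) {
    b <- resample_beat(tpl_default, hr = hr, fs_out = 250)
    expect_equal(range(b), c(0, 1))
    expect_lte(b[1], 0.05)
    expect_lte(b[length(b)], 0.06)  # interpolation near the wrap point
  }
})

test_that("amplitude scaling is the affine map hitting SBP and DBP exactly", {
  expect_equal(scale_beat(c(0, 1, 0.25), sbp = 120, dbp = 80), c(80, 120, 90))
  expect_equal(scale_beat(c(0, 0.5, 1), sbp = 1, dbp = 0), c(0, 0.5, 1))
  expect_equal(scale_beat(0.5, sbp = 120, dbp = 80), 100)
  expect_error(scale_beat(c(0, 1), sbp = 80, dbp = 90),
               class = "pulsewave_pressure_error")
})

test_that("synthesize_beat composes resampling and scaling", {
  b <- synthesize_beat(tpl_default, hr = 60, sbp = 120, dbp = 80,
                       fs_out = 250)
  expect_length(b, 250)
  expect_equal(max(b), 120)
  expect_equal(min(b), 80)

  # double identity: unit pressures at the reference HR return the template
  expect_identical(
    synthesize_beat(tpl_default, hr = 47, sbp = 1, dbp = 0, fs_out = 250),
    tpl_default$samples
  )

  b350 <- synthesize_beat(tpl_default, hr = 350, sbp = 90, dbp = 60,
                          fs_out = 250)
  expect_length(b350, 43)
  expect_equal(range(b350), c(60, 90))
})

test_that("ring buffer keeps FIFO order under both overflow policies", {
  rb <- ring_buffer(4, "block")
  expect_equal(rb_push(rb, 1:3), 3L)
  expect_equal(rb_push(rb, 4:6), 1L)      # only one slot left
  expect_equal(rb_size(rb), 4L)
  expect_equal(rb_pop(rb, 2), c(1, 2))
  expect_equal(rb_push(rb, 7:8), 2L)      # wraps around
  expect_equal(rb_pop(rb, 4), c(3, 4, 7, 8))
  expect_error(rb_pop(rb, 1), "underrun")

  ov <- ring_buffer(3, "overwrite")
  rb_push(ov, 1:5)                        # oldest values discarded
  expect_equal(rb_pop(ov, 3), c(3, 4, 5))
  expect_equal(ov$dropped, 2L)
})

test_that("a steady run emits the conserved beat and sample counts", {
  sc <- vitals_scenario(
    data.frame(t_s = 0, hr_bpm = 60, sbp_mmhg = 120, dbp_mmhg = 80),
    duration = 10
  )
  run <- run_pipeline(sc, tpl_default)
  expect_equal(run$n_beats, 10)       # 60 bpm x 10 s / 60
  expect_equal(run$n_samples, 2500)   # 250 Hz x 10 s
  expect_equal(diff(run$waveform$t_s), rep(1 / 250, 2499), tolerance = 1e-12)

  # per-beat extrema equal the commanded pressures exactly, pre-quantization
  by_beat <- split(run$waveform$p_mmhg, run$waveform$beat_index)
  expect_true(all(vapply(by_beat, max, numeric(1)) == 120))
  expect_true(all(vapply(by_beat, min, numeric(1)) == 80))
})

test_that("beat conservation holds across heart rates", {
  for (hr in c(47, 90, 180, 350)) {
    sc <- vitals_scenario(
      data.frame(t_s = 0, hr_bpm = hr, sbp_mmhg = 110, dbp_mmhg = 70),
      duration = 12
    )
    run <- run_pipeline(sc, tpl_default)
    expect_lte(abs(run$n_beats - round(hr * 12 / 60)), 1)
  }
})

test_that("a zero-duration scenario yields an empty run", {
  sc <- vitals_scenario(
    data.frame(t_s = 0, hr_bpm = 60, sbp_mmhg = 120, dbp_mmhg = 80),
    duration = 0
  )
  run <- run_pipeline(sc, tpl_default)
  expect_equal(run$n_beats, 0)
  expect_equal(run$n_samples, 0)
})

test_that("beat-atomic updates never let a beat straddle two vitals", {
  sc <- vitals_scenario(
    data.frame(t_s = c(0, 5), hr_bpm = c(60, 120),
               sbp_mmhg = c(120, 100), dbp_mmhg = c(80, 60)),
    duration = 10
  )
  run <- run_pipeline(sc, tpl_default)
  # provenance: each beat's vitals equal the scenario sampled at its poll
  cmd <- sample_vitals(sc, run$beats$poll_t_s)
  expect_equal(run$beats$hr_bpm, cmd$hr_bpm)
  expect_equal(run$beats$sbp_mmhg, cmd$sbp_mmhg)
  expect_equal(run$beats$dbp_mmhg, cmd$dbp_mmhg)
  # and the emitted samples of each complete beat span exactly that range
  for (b in seq_len(run$n_beats - 1)) {
    p <- run$waveform$p_mmhg[run$waveform$beat_index == b]
    expect_equal(max(p), run$beats$sbp_mmhg[b])
    expect_equal(min(p), run$beats$dbp_mmhg[b])
  }
})

test_that("waveform is continuous across beat junctions at constant vitals", {
  # the endpoint invariant bounds the junction jump by 5% of pulse pressure
  # (with changing vitals the jump additionally reflects the commanded step)
  cases <- data.frame(hr = c(47, 72, 130, 310), sbp = c(120, 90, 200, 65),
                      dbp = c(80, 55, 110, 40))
  for (i in seq_len(nrow(cases))) {
    sc <- vitals_scenario(
      data.frame(t_s = 0, hr_bpm = cases$hr[i], sbp_mmhg = cases$sbp[i],
                 dbp_mmhg = cases$dbp[i]),
      duration = 10
    )
    run <- run_pipeline(sc, tpl_default)
    wf <- run$waveform
    jumps <- abs(diff(wf$p_mmhg))
    junction <- diff(wf$beat_index) != 0
    expect_lte(max(jumps[junction]),
               0.05 * (cases$sbp[i] - cases$dbp[i]) + 1e-9)
  }
})

test_that("zero heart rate flatlines at the diastolic pressure", {
  sc <- vitals_scenario(
    data.frame(t_s = c(0, 3), hr_bpm = c(0, 60),
               sbp_mmhg = c(120, 120), dbp_mmhg = c(80, 80)),
    duration = 6
  )
  run <- run_pipeline(sc, tpl_default)
  expect_true(any(grepl("flatline", run$warnings)))
  flat <- run$waveform[run$waveform$t_s < 3, ]
  expect_true(all(flat$p_mmhg == 80))
  expect_true(all(is.na(flat$beat_index)))
  beating <- run$waveform[run$waveform$t_s >= 3, ]
  expect_gt(max(beating$p_mmhg), 100)
})

test_that("concurrent execution reproduces the deterministic stream", {
  sc <- make_synthetic_scenario("hypotension-step", duration = 12,
                                noise_sd = 3, seed = 11)
  det <- run_pipeline(sc, tpl_default, mode = "deterministic")
  conc <- run_pipeline(sc, tpl_default, mode = "concurrent")
  expect_identical(det$waveform, conc$waveform)
  expect_equal(det$poll_log, conc$poll_log, tolerance = 1e-15)
  # a rerun of the same deterministic pipeline is bit-identical
  expect_identical(det$waveform,
                   run_pipeline(sc, tpl_default)$waveform)
})

test_that("an undersized ring buffer is rejected, not deadlocked", {
  sc <- make_synthetic_scenario("steady", duration = 2)
  cfg <- engine_config(buffer_capacity = 100)  # < one 319-sample cycle
  expect_error(run_pipeline(sc, tpl_default, config = cfg,
                            mode = "concurrent"),
               "buffer_capacity")
})

test_that("a failing sink stops the pipeline with a partial report", {
  sc <- make_synthetic_scenario("steady", duration = 10)
  n_chunks <- 0
  sink <- function(chunk) {
    n_chunks <<- n_chunks + 1
    if (n_chunks >= 3) stop("disk full")
  }
  run <- run_pipeline(sc, tpl_default, sink = sink)
  expect_false(run$complete)
  expect_equal(run$n_beats, 3)
  expect_true(any(grepl("sink failure", run$warnings)))
})

test_that("immediate update policy retargets amplitude mid-beat", {
  # step change placed mid-beat: 47 bpm beats last ~1.28 s, change at t = 1 s
  sc <- vitals_scenario(
    data.frame(t_s = c(0, 1), hr_bpm = c(47, 47),
               sbp_mmhg = c(120, 200), dbp_mmhg = c(80, 120)),
    duration = 4
  )
  imm <- run_pipeline(sc, tpl_default,
                      config = engine_config(update_policy = "immediate"))
  beat1 <- imm$waveform[imm$waveform$beat_index == 1, ]
  # samples of the first beat after t = 1 s already use the new pressures
  expect_gt(max(beat1$p_mmhg[beat1$t_s >= 1]), 120)
  # beat-atomic mode keeps the whole first beat on the old vitals
  atom <- run_pipeline(sc, tpl_default)
  expect_lte(max(atom$waveform$p_mmhg[atom$waveform$beat_index == 1]), 120)
})
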