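test_that("scenario CSV parsing preserves segments and reports defects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,hr_bpm,sbp_mmhg,dbp_mmhg",
               "0,60,120,80",
               "30,90,90,60"), f)
  sc <- load_scenario(f, duration = 60)
  expect_s3_class(sc, "vitals_scenario")
  expect_equal(nrow(sc$segments), 2)
  expect_equal(sc$duration, 60)
  expect_equal(sc$segments$hr_bpm, c(60, 90))
  # default duration is last start + 1
  expect_equal(load_scenario(f)$duration, 31)

  writeLines(c("t_s,hr_bpm,sbp_mmhg,dbp_mmhg",
               "0,60,120,80",
               "0,90,90,60"), f)
  expect_error(load_scenario(f), class = "pulsewave_unordered_scenario")

  writeLines("t_s,hr_bpm,sbp_mmhg,dbp_mmhg", f)
  expect_error(load_scenario(f), class = "pulsewave_empty_scenario")

  writeLines(c("t_s,hr_bpm,sbp_mmhg", "0,60,120"), f)
  expect_error(load_scenario(f), "dbp_mmhg")

  # out-of-limit HR parses; clamping is deferred to validation
  writeLines(c("t_s,hr_bpm,sbp_mmhg,dbp_mmhg", "0,400,120,80"), f)
  sc400 <- load_scenario(f)
  expect_equal(sc400$segments$hr_bpm, 400)
  expect_warning(v <- sample_vitals(sc400, 0),
                 class = "pulsewave_clamp_warning")
  expect_equal(v$hr_bpm, 350)
})

test_that("scenario round-trips through write_scenario", {
  sc <- make_synthetic_scenario("hemorrhage-ramp", duration = 60,
                                noise_sd = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scenario(sc, f)
  back <- load_scenario(f, duration = sc$duration)
  expect_equal(back$segments, sc$segments, tolerance = 1e-12)
})

test_that("hold sampling is a right-continuous step function", {
  sc <- two_segment_scenario("hold")
  v10 <- sample_vitals(sc, 10)
  expect_equal(unlist(v10[c("hr_bpm", "sbp_mmhg", "dbp_mmhg")]),
               c(hr_bpm = 60, sbp_mmhg = 120, dbp_mmhg = 80))
  # a segment takes effect at exactly its start time
  v30 <- sample_vitals(sc, 30)
  expect_equal(unlist(v30[c("hr_bpm", "sbp_mmhg", "dbp_mmhg")]),
               c(hr_bpm = 90, sbp_mmhg = 90, dbp_mmhg = 60))
  # idempotent under re-sampling at the same t
  expect_identical(sample_vitals(sc, 17.5), sample_vitals(sc, 17.5))
  expect_error(sample_vitals(sc, 61), "out of range")
  expect_error(sample_vitals(sc, -1), "out of range")
})

test_that("ramp sampling interpolates each vital linearly", {
  sc <- two_segment_scenario("ramp")
  v <- sample_vitals(sc, 15)  # midpoint of the 0-30 s bracket
  expect_equal(v$hr_bpm, 75)
  expect_equal(v$sbp_mmhg, 105)
  expect_equal(v$dbp_mmhg, 70)
  # held flat beyond the last segment start
  v45 <- sample_vitals(sc, 45)
  expect_equal(v45$sbp_mmhg, 90)
})

test_that("vitals validation clamps HR to 0-350 and rejects SBP <= DBP", {
  expect_warning(
    v <- validate_vitals(data.frame(hr_bpm = 400, sbp_mmhg = 120,
                                    dbp_mmhg = 80)),
    class = "pulsewave_clamp_warning"
  )
  expect_equal(v$hr_bpm, 350)
  expect_equal(v$sbp_mmhg, 120)

  id <- data.frame(hr_bpm = 60, sbp_mmhg = 120, dbp_mmhg = 80)
  expect_identical(validate_vitals(id), tibble::as_tibble(id))

  expect_error(validate_vitals(data.frame(hr_bpm = 60, sbp_mmhg = 80,
                                          dbp_mmhg = 90)),
               class = "pulsewave_pressure_error")
  # ...but a stopped heart may carry any pressure pair
  expect_silent(validate_vitals(data.frame(hr_bpm = 0, sbp_mmhg = 0,
                                           dbp_mmhg = 0)))
})

test_that("validation is a projection: applying it twice changes nothing", {
  set.seed(42)
  raw <- data.frame(hr_bpm = runif(50, -50, 500),
                    sbp_mmhg = runif(50, 100, 700))
  # keep the pair ordered even after the 500 mmHg clamp
  raw$dbp_mmhg <- pmin(raw$sbp_mmhg, 500) - runif(50, 1, 60)
  once <- suppressWarnings(validate_vitals(raw))
  twice <- suppressWarnings(validate_vitals(once))
  expect_identical(once, twice)
  expect_true(all(once$hr_bpm >= 0 & once$hr_bpm <= 350))
  expect_true(all(once$sbp_mmhg <= 500 & once$dbp_mmhg >= 0))
})

test_that("synthetic scenario presets honour their documented shapes", {
  st <- make_synthetic_scenario("steady", duration = 60, noise_sd = 0,
                                seed = 1)
  expect_equal(nrow(st$segments), 1)
  expect_equal(unlist(st$segments),
               c(t_s = 0, hr_bpm = 70, sbp_mmhg = 120, dbp_mmhg = 80))

  expect_identical(make_synthetic_scenario("steady", 30, 4, seed = 7),
                   make_synthetic_scenario("steady", 30, 4, seed = 7))

  hem <- make_synthetic_scenario("hemorrhage-ramp", duration = 120,
                                 noise_sd = 0, seed = 1)
  expect_true(all(diff(hem$segments$sbp_mmhg) <= 0))
  expect_lt(tail(hem$segments$sbp_mmhg, 1), hem$segments$sbp_mmhg[1])

  step <- make_synthetic_scenario("hypotension-step", duration = 60,
                                  noise_sd = 0, seed = 1)
  expect_equal(sort(unique(step$segments$sbp_mmhg)), c(80, 120))

  expect_error(make_synthetic_scenario("cardiac-arrest", 60),
               "steady")
})

test_that("every sample from random scenarios satisfies the vitals contract", {
  for (seed in 1:25) {
    sc <- draw_random_scenario(seed)
    t <- sort(runif(20, 0, sc$duration))
    v <- sample_vitals(sc, t)
    expect_true(all(v$hr_bpm >= 0 & v$hr_bpm <= 350))
    expect_true(all(v$sbp_mmhg >= 0 & v$sbp_mmhg <= 500))
    expect_true(all(v$dbp_mmhg >= 0 & v$dbp_mmhg <= 500))
    expect_true(all(v$hr_bpm == 0 | v$sbp_mmhg > v$dbp_mmhg))
  }
})
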