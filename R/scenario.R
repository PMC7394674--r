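#' Construct a vitals scenario
#'
#' A scenario scripts the once-per-second vital-sign feed a patient simulator
#' would supply: an ordered set of segments, each giving heart rate (bpm),
#' systolic and diastolic pressure (mmHg) from a start time onward. It stands
#' in for a live query link to a physical simulator, so runs are reproducible
#' and need no hardware.
#'
#' @param segments Data frame with columns `t_s`, `hr_bpm`, `sbp_mmhg`,
#'   `dbp_mmhg`; one row per segment, start times strictly increasing, first
#'   row at `t_s = 0`. A segment takes effect at exactly its start time
#'   (half-open intervals).
#' @param duration Total scenario length in seconds; must be at least the last
#'   segment start. Defaults to the last start time + 1.
#' @param interpolation `"hold"` (step function, default) or `"ramp"`
#'   (component-wise linear interpolation between segment starts).
#' @return An object of class `vitals_scenario`.
#' @examples
#' sc <- vitals_scenario(
#'   data.frame(t_s = c(0, 30), hr_bpm = c(60, 90),
#'              sbp_mmhg = c(120, 90), dbp_mmhg = c(80, 60)),
#'   duration = 60
#' )
#' sample_vitals(sc, c(10, 30, 45))
#' @export
vitals_scenario <- function(segments, duration = NULL,
                            interpolation = c("hold", "ramp")) {
  interpolation <- match.arg(interpolation)
  segments <- tibble::as_tibble(segments)
  required <- c("t_s", "hr_bpm", "sbp_mmhg", "dbp_mmhg")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    abort(paste0("scenario is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pulsewave_parse_error")
  }
  segments <- segments[required]
  if (nrow(segments) == 0) {
    abort("empty scenario: no segments", class = "pulsewave_empty_scenario")
  }
  bad <- which(!stats::complete.cases(segments) |
                 !purrr::map_lgl(seq_len(nrow(segments)),
                                 function(i) all(is.finite(unlist(segments[i, ])))))
  if (length(bad) > 0) {
    abort(paste0("malformed scenario row(s): ",
                 paste(bad, collapse = ", ")),
          class = "pulsewave_parse_error")
  }
  if (any(diff(segments$t_s) <= 0)) {
    abort("unordered scenario: segment times must be strictly increasing",
          class = "pulsewave_unordered_scenario")
  }
  if (segments$t_s[1] != 0) {
    abort("first scenario segment must start at t = 0",
          class = "pulsewave_parse_error")
  }
  if (is.null(duration)) duration <- tail(segments$t_s, 1) + 1
  if (!is.finite(duration) || duration < tail(segments$t_s, 1)) {
    abort("duration must be finite and >= the last segment start time")
  }
  structure(
    list(segments = segments, duration = as.numeric(duration),
         interpolation = interpolation),
    class = "vitals_scenario"
  )
}

#' @export
print.vitals_scenario <- function(x, ...) {
  cat(sprintf("<vitals_scenario> %d segment(s), %.6g s, %s interpolation\n",
              nrow(x$segments), x$duration, x$interpolation))
  print(x$segments, n = 5)
  invisible(x)
}

#' Read a vitals scenario from a CSV file
#'
#' The file format is a plain CSV with header
#' `t_s,hr_bpm,sbp_mmhg,dbp_mmhg`, UTF-8, `.` decimal separator, one row per
#' segment. Values are taken as written; range enforcement (the 0-350 bpm
#' heart-rate limit, the 0-500 mmHg representable pressure range) happens at
#' [validate_vitals()] when samples are drawn.
#'
#' @param file Path to the scenario CSV.
#' @inheritParams vitals_scenario
#' @return A `vitals_scenario`.
#' @export
load_scenario <- function(file, duration = NULL,
                          interpolation = c("hold", "ramp")) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed scenario row(s) at line(s): ",
                 paste(unique(probs$row), collapse = ", ")),
          class = "pulsewave_parse_error")
  }
  if (nrow(raw) == 0) {
    abort("empty scenario: no segments", class = "pulsewave_empty_scenario")
  }
  vitals_scenario(raw, duration = duration, interpolation = interpolation)
}

#' Write a vitals scenario to a CSV file
#'
#' @param scenario A `vitals_scenario`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scenario <- function(scenario, file) {
  stopifnot(inherits(scenario, "vitals_scenario"))
  readr::write_csv(scenario$segments, file, progress = FALSE)
  invisible(file)
}

#' Sample the scripted vitals at given times
#'
#' In hold mode the last segment whose start time is at or before `t` applies
#' (a segment takes effect at exactly its start). In ramp mode each vital is
#' linearly interpolated between the bracketing segment starts, and held flat
#' after the last segment. Every returned row has passed [validate_vitals()].
#'
#' @param scenario A `vitals_scenario`.
#' @param t Numeric vector of times in `[0, duration]`, seconds.
#' @return Tibble with columns `t_s`, `hr_bpm`, `sbp_mmhg`, `dbp_mmhg`.
#' @export
sample_vitals <- function(scenario, t) {
  stopifnot(inherits(scenario, "vitals_scenario"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > scenario$duration)) {
    abort(sprintf("sample time out of range [0, %.6g]", scenario$duration))
  }
  seg <- scenario$segments
  if (scenario$interpolation == "hold" || nrow(seg) == 1) {
    i <- findInterval(t, seg$t_s)
    out <- tibble::tibble(
      t_s = t,
      hr_bpm = seg$hr_bpm[i],
      sbp_mmhg = seg$sbp_mmhg[i],
      dbp_mmhg = seg$dbp_mmhg[i]
    )
  } else {
    interp <- function(y) approx(seg$t_s, y, xout = pmin(t, max(seg$t_s)),
                                 method = "linear", rule = 2)$y
    out <- tibble::tibble(
      t_s = t,
      hr_bpm = interp(seg$hr_bpm),
      sbp_mmhg = interp(seg$sbp_mmhg),
      dbp_mmhg = interp(seg$dbp_mmhg)
    )
  }
  validate_vitals(out)
}

#' Enforce the vitals value-range contract
#'
#' Heart rate is clamped into the transmitted-variable limits, 0-350 bpm, with
#' a warning when clamping occurs. Pressures are clamped into 0-500 mmHg, the
#' representable range of the analog output mapping. A systolic pressure at or
#' below the diastolic while the heart is beating is rejected rather than
#' repaired: no affine amplitude scaling can honour it.
#'
#' @param vitals Data frame with columns `hr_bpm`, `sbp_mmhg`, `dbp_mmhg`
#'   (a `t_s` column, if present, is passed through).
#' @return The clamped tibble.
#' @examples
#' validate_vitals(data.frame(hr_bpm = 400, sbp_mmhg = 120, dbp_mmhg = 80))
#' @export
validate_vitals <- function(vitals) {
  v <- tibble::as_tibble(vitals)
  stopifnot(all(c("hr_bpm", "sbp_mmhg", "dbp_mmhg") %in% names(v)))
  n_hr <- sum(v$hr_bpm < 0 | v$hr_bpm > 350)
  n_p <- sum(v$sbp_mmhg < 0 | v$sbp_mmhg > 500 |
               v$dbp_mmhg < 0 | v$dbp_mmhg > 500)
  v$hr_bpm <- clamp(v$hr_bpm, 0, 350)
  v$sbp_mmhg <- clamp(v$sbp_mmhg, 0, 500)
  v$dbp_mmhg <- clamp(v$dbp_mmhg, 0, 500)
  if (n_hr > 0) {
    warn(sprintf("%d heart-rate value(s) clamped into [0, 350] bpm", n_hr),
         class = "pulsewave_clamp_warning")
  }
  if (n_p > 0) {
    warn(sprintf("%d pressure value(s) clamped into [0, 500] mmHg", n_p),
         class = "pulsewave_clamp_warning")
  }
  bad <- v$hr_bpm > 0 & v$sbp_mmhg <= v$dbp_mmhg
  if (any(bad)) {
    abort(sprintf("non-physiological pressure pair: SBP <= DBP in %d row(s)",
                  sum(bad)),
          class = "pulsewave_pressure_error")
  }
  v
}

# Baseline vitals profiles for the synthetic presets, as functions of time.
scenario_presets <- list(
  steady = function(t, duration) {
    tibble::tibble(hr_bpm = 70, sbp_mmhg = 120, dbp_mmhg = 80)
  },
  `hemorrhage-ramp` = function(t, duration) {
    f <- t / duration
    tibble::tibble(
      hr_bpm = 70 + f * (120 - 70),
      sbp_mmhg = 120 + f * (70 - 120),
      dbp_mmhg = 80 + f * (50 - 80)
    )
  },
  `hypotension-step` = function(t, duration) {
    late <- t >= duration / 2
    tibble::tibble(
      hr_bpm = ifelse(late, 110, 70),
      sbp_mmhg = ifelse(late, 80, 120),
      dbp_mmhg = ifelse(late, 50, 80)
    )
  }
)

#' Generate a synthetic vitals scenario
#'
#' Presets emulate the scenario classes a simulation instructor would script:
#' `steady` (70 bpm, 120/80 mmHg), `hemorrhage-ramp` (progressive fall from
#' 120/80 to 70/50 mmHg with compensatory tachycardia 70 to 120 bpm), and
#' `hypotension-step` (abrupt drop to 80/50 mmHg at half time). Optional
#' additive Gaussian jitter per segment emulates beat-to-beat measurement
#' noise; jittered values are clamped back into the physiological contract so
#' every segment passes [validate_vitals()].
#'
#' @param kind One of `"steady"`, `"hemorrhage-ramp"`, `"hypotension-step"`.
#' @param duration Scenario length, seconds (> 0).
#' @param noise_sd Standard deviation of the jitter, either one number for all
#'   three vitals or a length-3 vector `(hr, sbp, dbp)`. `0` disables jitter.
#' @param seed Integer seed; the same call with the same seed returns an
#'   identical scenario.
#' @param segment_step Spacing of generated segments in seconds when the
#'   preset or jitter needs more than one segment.
#' @return A `vitals_scenario` in hold mode.
#' @examples
#' make_synthetic_scenario("hemorrhage-ramp", duration = 120, seed = 1)
#' @export
make_synthetic_scenario <- function(kind, duration, noise_sd = 0, seed = 1,
                                    segment_step = NULL) {
  if (!kind %in% names(scenario_presets)) {
    abort(sprintf("unknown scenario kind '%s'; available presets: %s",
                  kind, paste(names(scenario_presets), collapse = ", ")))
  }
  if (!is.finite(duration) || duration <= 0) abort("duration must be > 0")
  noise_sd <- rep_len(noise_sd, 3)
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")
  if (is.null(segment_step)) {
    segment_step <- if (any(noise_sd > 0)) 1 else 5
  }
  noiseless_constant <- kind == "steady" && all(noise_sd == 0)
  t_seg <- if (noiseless_constant) 0 else {
    s <- seq(0, duration, by = segment_step)
    if (kind == "hypotension-step") sort(unique(c(s, duration / 2))) else s
  }
  t_seg <- t_seg[t_seg <= duration]
  base <- scenario_presets[[kind]](t_seg, duration)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    expr
  }
  seg <- withr_seed({
    n <- length(t_seg)
    tibble::tibble(
      t_s = t_seg,
      hr_bpm = base$hr_bpm + rnorm(n, 0, noise_sd[1]),
      sbp_mmhg = base$sbp_mmhg + rnorm(n, 0, noise_sd[2]),
      dbp_mmhg = base$dbp_mmhg + rnorm(n, 0, noise_sd[3])
    )
  })
  # Post-hoc clamp so every sample honours the vitals contract: HR in
  # [0, 350], pressures in [0, 500], and SBP strictly above DBP.
  seg$hr_bpm <- clamp(seg$hr_bpm, 0, 350)
  seg$sbp_mmhg <- clamp(seg$sbp_mmhg, 1, 500)
  seg$dbp_mmhg <- clamp(seg$dbp_mmhg, 0, seg$sbp_mmhg - 1)
  vitals_scenario(seg, duration = duration, interpolation = "hold")
}
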