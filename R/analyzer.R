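#' Detect beat boundaries in an arterial pressure series
#'
#' Segments the waveform at diastolic troughs: local minima separated by at
#' least the refractory period 60/350 s (one beat at the 350 bpm heart-rate
#' ceiling). Two refinements make trough picking robust to normal arterial
#' morphology: (1) an amplitude gate rejects shallow minima such as the
#' dicrotic notch — a candidate must lie within 25% of the local range above
#' the local minimum, both taken over a window of +/- max(1 s, 3 refractory
#' periods); (2) when two candidates fall inside one refractory period the
#' deeper one wins. Series endpoints count as troughs when the signal rises
#' away from them, so complete first and last beats are kept. A flatline
#' (zero peak-to-peak range) has no beats.
#'
#' @param p Numeric pressure series, mmHg.
#' @param fs Sampling rate, Hz (> 0).
#' @return Integer vector of boundary indices (1-based), possibly empty.
#' @examples
#' run <- run_pipeline(make_synthetic_scenario("steady", duration = 10),
#'                     default_template())
#' length(detect_beats(run$waveform$p_mmhg, 250))  # 11 troughs -> 10 beats
#' @export
detect_beats <- function(p, fs) {
  if (!is.finite(fs) || fs <= 0) abort("fs must be > 0")
  n <- length(p)
  if (n < 3) return(integer(0))
  rng <- max(p) - min(p)
  if (rng < 1e-9) return(integer(0))          # flatline

  interior <- which(p[2:(n - 1)] <= p[1:(n - 2)] & p[2:(n - 1)] < p[3:n]) + 1L
  cand <- interior
  if (p[1] < p[2]) cand <- c(1L, cand)
  if (p[n] < p[n - 1]) cand <- c(cand, n)
  if (length(cand) == 0) return(integer(0))

  # amplitude gate against a local window
  half_w <- as.integer(max(fs, 3 * ceiling(fs * 60 / 350)))
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - half_w); hi <- min(n, i + half_w)
    w <- p[lo:hi]
    wr <- max(w) - min(w)
    wr > 1e-9 && p[i] <= min(w) + 0.25 * wr
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) return(integer(0))

  # refractory pass, deeper trough wins
  refractory <- fs * 60 / 350
  out <- cand[1]
  for (i in cand[-1]) {
    last <- out[length(out)]
    if (i - last >= refractory) {
      out <- c(out, i)
    } else if (p[i] < p[last]) {
      out[length(out)] <- i
    }
  }
  out
}

#' Extract per-beat pressures from detected boundaries
#'
#' Each beat spans consecutive boundary indices (both ends included, so the
#' trough shared by two beats contributes its diastolic value to both).
#' Reported per beat: onset time, period, systolic pressure (beat maximum),
#' diastolic pressure (beat minimum), pulse pressure `pp = sbp - dbp`, and
#' mean arterial pressure by the standard clinical approximation
#' `map = dbp + pp/3`.
#'
#' @param p Numeric pressure series, mmHg.
#' @param boundaries Boundary indices from [detect_beats()].
#' @param fs Sampling rate, Hz.
#' @return Tibble with columns `t_onset_s`, `period_s`, `sbp_mmhg`,
#'   `dbp_mmhg`, `pp_mmhg`, `map_mmhg`; zero rows when fewer than two
#'   boundaries exist (no complete beat).
#' @export
extract_features <- function(p, boundaries, fs) {
  if (!is.finite(fs) || fs <= 0) abort("fs must be > 0")
  empty <- tibble::tibble(t_onset_s = numeric(), period_s = numeric(),
                          sbp_mmhg = numeric(), dbp_mmhg = numeric(),
                          pp_mmhg = numeric(), map_mmhg = numeric())
  if (length(boundaries) < 2) return(empty)
  b <- as.integer(boundaries)
  purrr::map_dfr(seq_len(length(b) - 1L), function(j) {
    seg <- p[b[j]:b[j + 1L]]
    sbp <- max(seg); dbp <- min(seg)
    tibble::tibble(
      t_onset_s = (b[j] - 1L) / fs,
      period_s = (b[j + 1L] - b[j]) / fs,
      sbp_mmhg = sbp, dbp_mmhg = dbp,
      pp_mmhg = sbp - dbp,
      map_mmhg = dbp + (sbp - dbp) / 3
    )
  })
}

#' Pulse pressure variation over a beat window
#'
#' The standard clinical definition:
#' `ppv = 100 * (pp_max - pp_min) / ((pp_max + pp_min) / 2)` percent, over
#' the beats supplied. A constant-amplitude signal has PPV 0; without
#' synthesized respiratory modulation that is the expected value for any
#' steady run.
#'
#' @param features Per-beat tibble from [extract_features()] (needs a
#'   `pp_mmhg` column with at least 2 rows).
#' @return PPV in percent.
#' @examples
#' compute_ppv(tibble::tibble(pp_mmhg = c(40, 44, 40, 44)))  # ~9.52
#' @export
compute_ppv <- function(features) {
  pp <- features$pp_mmhg
  if (length(pp) < 2) {
    abort("insufficient beats: PPV needs at least 2 beats",
          class = "pulsewave_analysis_error")
  }
  hi <- max(pp); lo <- min(pp)
  if (hi + lo == 0) return(0)
  100 * (hi - lo) / ((hi + lo) / 2)
}

#' Analyze a pressure waveform like a pulse-contour monitor front end
#'
#' Runs beat detection and feature extraction, then summarizes heart rate
#' (from the mean beat period) and pulse pressure variation over the trailing
#' analysis window. This is a generic, openly defined beat-statistics
#' analyzer for round-trip verification; it is not a reimplementation of any
#' proprietary pulse-contour algorithm, and it derives no flow-side
#' quantities (CO, SV, SVR, SVV).
#'
#' @param waveform Data frame with columns `t_s` and `p_mmhg`, uniformly
#'   sampled.
#' @param fs Sampling rate, Hz; by default inferred from the median time
#'   step.
#' @param window Averaging window in seconds for HR and PPV (default 10 s, a
#'   typical monitor window), counted back from the last beat.
#' @return A `pulse_analysis` object: `beats` (per-beat features), `hr_bpm`,
#'   `ppv_pct`, `window_s`, `fs`. [tidy()] returns the beat table,
#'   [glance()] the one-row summary.
#' @export
analyze_waveform <- function(waveform, fs = NULL, window = 10) {
  wf <- tibble::as_tibble(waveform)
  stopifnot(all(c("t_s", "p_mmhg") %in% names(wf)))
  if (is.null(fs)) {
    dt <- stats::median(diff(wf$t_s))
    if (!is.finite(dt) || dt <= 0) abort("cannot infer fs from t_s")
    fs <- 1 / dt
  }
  if (window <= 0) abort("window must be > 0")
  boundaries <- detect_beats(wf$p_mmhg, fs)
  beats <- extract_features(wf$p_mmhg, boundaries, fs)
  if (nrow(beats) >= 1) {
    t_end <- max(beats$t_onset_s + beats$period_s)
    in_win <- beats$t_onset_s >= t_end - window
    wb <- beats[in_win, ]
    hr <- 60 / mean(wb$period_s)
    ppv <- if (nrow(wb) >= 2) compute_ppv(wb) else NA_real_
  } else {
    hr <- 0
    ppv <- NA_real_
  }
  structure(
    list(beats = beats, hr_bpm = hr, ppv_pct = ppv, window_s = window,
         fs = fs),
    class = "pulse_analysis"
  )
}

#' @export
print.pulse_analysis <- function(x, ...) {
  cat(sprintf("<pulse_analysis> %d beat(s); HR %.1f bpm, PPV %s (window %g s)\n",
              nrow(x$beats), x$hr_bpm,
              if (is.na(x$ppv_pct)) "NA" else sprintf("%.2f%%", x$ppv_pct),
              x$window_s))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pulse_analysis <- function(x, ...) x$beats

#' @exportS3Method generics::glance
glance.pulse_analysis <- function(x, ...) {
  tibble::tibble(n_beats = nrow(x$beats), hr_bpm = x$hr_bpm,
                 ppv_pct = x$ppv_pct, window_s = x$window_s, fs = x$fs)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pulse_analysis <- function(object, ...) {
  ggplot2::ggplot(object$beats,
                  ggplot2::aes(x = .data$t_onset_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sbp_mmhg, linetype = "SBP")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$map_mmhg, linetype = "MAP")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dbp_mmhg, linetype = "DBP")) +
    ggplot2::labs(x = "Beat onset (s)", y = "Pressure (mmHg)",
                  linetype = NULL, title = "Recovered per-beat pressures")
}

#' Round-trip verification of commanded vs recovered vitals
#'
#' Automates the check that a monitor fed the synthesized waveform would
#' read back the scripted vitals: for every steady (hold) segment of the
#' scenario, compare the commanded SBP, DBP and HR with the values the
#' contour analyzer recovers from the waveform, excluding each segment's
#' first analyzed beat (the transition beat after a parameter change) and
#' beats that straddle a segment change.
#'
#' @param scenario The `vitals_scenario` that drove the run (hold mode).
#' @param analysis A `pulse_analysis` of the run's waveform (or the
#'   waveform data frame itself, which will be analyzed).
#' @return A `roundtrip_report`: `per_segment` tibble (commanded and
#'   recovered values with absolute errors) and `summary` tibble of the
#'   maximum absolute error per vital. [tidy()] returns `per_segment`,
#'   [glance()] the summary in one row.
#' @export
roundtrip_report <- function(scenario, analysis) {
  stopifnot(inherits(scenario, "vitals_scenario"))
  if (!inherits(analysis, "pulse_analysis")) {
    analysis <- analyze_waveform(analysis)
  }
  if (scenario$interpolation != "hold") {
    abort("round-trip verification is defined for hold-mode scenarios")
  }
  beats <- analysis$beats
  seg <- scenario$segments
  seg_start <- seg$t_s
  seg_end <- c(seg$t_s[-1], scenario$duration)

  per_seg <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    cmd <- validate_vitals(seg[i, ])
    inside <- beats$t_onset_s >= seg_start[i] - 1e-9 &
      beats$t_onset_s + beats$period_s <= seg_end[i] + 1e-9
    b <- beats[inside, ]
    if (i > 1 && nrow(b) > 0) b <- b[-1, ]   # drop the transition beat
    if (nrow(b) < 5) return(NULL)
    hr_est <- 60 / mean(b$period_s)
    tibble::tibble(
      segment = i, t_start_s = seg_start[i], n_beats = nrow(b),
      hr_cmd = cmd$hr_bpm, hr_est = hr_est,
      hr_abs_err = abs(hr_est - cmd$hr_bpm),
      sbp_cmd = cmd$sbp_mmhg, sbp_est = max(b$sbp_mmhg),
      sbp_abs_err = max(abs(b$sbp_mmhg - cmd$sbp_mmhg)),
      dbp_cmd = cmd$dbp_mmhg, dbp_est = min(b$dbp_mmhg),
      dbp_abs_err = max(abs(b$dbp_mmhg - cmd$dbp_mmhg))
    )
  })
  if (nrow(per_seg) == 0) {
    abort("scenario too short: no steady segment with at least 5 analyzed beats",
          class = "pulsewave_analysis_error")
  }
  summary <- tibble::tibble(
    metric = c("sbp_mmhg", "dbp_mmhg", "hr_bpm"),
    max_abs_error = c(max(per_seg$sbp_abs_err),
                      max(per_seg$dbp_abs_err),
                      max(per_seg$hr_abs_err)),
    n_segments = nrow(per_seg)
  )
  structure(list(per_segment = per_seg, summary = summary),
            class = "roundtrip_report")
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat(sprintf("<roundtrip_report> %d steady segment(s)\n",
              nrow(x$per_segment)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roundtrip_report <- function(x, ...) x$per_segment

#' @exportS3Method generics::glance
glance.roundtrip_report <- function(x, ...) {
  tibble::tibble(
    sbp_max_abs_err = x$summary$max_abs_error[x$summary$metric == "sbp_mmhg"],
    dbp_max_abs_err = x$summary$max_abs_error[x$summary$metric == "dbp_mmhg"],
    hr_max_abs_err = x$summary$max_abs_error[x$summary$metric == "hr_bpm"],
    n_segments = nrow(x$per_segment)
  )
}
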