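#' Waveform engine configuration
#'
#' @param fs_out Output sampling rate in Hz. Default 250 Hz, the sampling
#'   rate of the reference template, so no template detail is lost.
#' @param poll_period Vitals polling period in seconds; the scripted feed is
#'   queried once per period (default 1 s, the patient-simulator cadence).
#' @param buffer_capacity Ring-buffer capacity in samples for the concurrent
#'   mode; default `NULL` means 4 template cycles.
#' @param update_policy `"beat"` (default): a vitals change takes effect at
#'   the next beat boundary, never mid-beat, so no beat mixes two parameter
#'   sets. `"immediate"`: amplitude rescaling follows the newest vitals
#'   sample-by-sample mid-beat (beat length is still fixed at onset, since a
#'   beat's duration cannot change after it has started).
#' @param buffer_policy Ring-buffer overflow policy, `"block"` or
#'   `"overwrite"` (see [ring_buffer()]).
#' @return An `engine_config` list.
#' @export
engine_config <- function(fs_out = 250, poll_period = 1,
                          buffer_capacity = NULL,
                          update_policy = c("beat", "immediate"),
                          buffer_policy = c("block", "overwrite")) {
  update_policy <- match.arg(update_policy)
  buffer_policy <- match.arg(buffer_policy)
  if (!is.finite(fs_out) || fs_out <= 0) abort("fs_out must be > 0")
  if (!is.finite(poll_period) || poll_period <= 0) abort("poll_period must be > 0")
  structure(list(fs_out = fs_out, poll_period = poll_period,
                 buffer_capacity = buffer_capacity,
                 update_policy = update_policy,
                 buffer_policy = buffer_policy),
            class = "engine_config")
}

#' Resample a pulse template to a commanded heart rate
#'
#' Adjusts the normalized beat to the heart rate by interpolating the
#' template onto a uniform phase grid of `round(fs_out * 60 / hr)` points
#' (round half away from zero) spanning one beat. Phase is treated as
#' periodic: the grid point nearest the end of the beat interpolates between
#' the template's last and first samples. The result is re-pinned to span
#' [0, 1] exactly, so subsequent amplitude scaling hits SBP and DBP exactly.
#'
#' @param template A `pulse_template`.
#' @param hr Commanded heart rate, bpm, in (0, 350]. A zero heart rate is a
#'   pipeline-level condition (flatline), not a beat.
#' @param fs_out Output sampling rate, Hz.
#' @return Numeric vector of normalized amplitudes, `min == 0`, `max == 1`.
#' @examples
#' length(resample_beat(default_template(), hr = 60, fs_out = 250))  # 250
#' @export
resample_beat <- function(template, hr, fs_out) {
  stopifnot(inherits(template, "pulse_template"))
  if (!is.finite(hr) || hr <= 0 || hr > 350) {
    abort("hr must be in (0, 350] for beat synthesis")
  }
  if (!is.finite(fs_out) || fs_out <= 0) abort("fs_out must be > 0")
  s <- template$samples
  len <- length(s)
  n_out <- round_half_away(fs_out * 60 / hr)
  if (n_out < 2) abort("fewer than 2 output samples per beat; raise fs_out")
  ph_t <- (seq_len(len) - 1) / len
  ph_o <- (seq_len(n_out) - 1) / n_out
  if (n_out == len) return(s)  # identity grid
  y <- approx(x = c(ph_t, 1), y = c(s, s[1]), xout = ph_o,
              method = "linear")$y
  (y - min(y)) / (max(y) - min(y))
}

#' Scale a normalized beat to commanded pressures
#'
#' Affine amplitude map `p_i = dbp + n_i * (sbp - dbp)`: the beat's maximum
#' lands exactly on the systolic pressure and its minimum exactly on the
#' diastolic pressure.
#'
#' @param beat Normalized amplitude vector spanning [0, 1].
#' @param sbp,dbp Systolic / diastolic pressure, mmHg, with `sbp > dbp >= 0`.
#' @return Pressure vector, mmHg.
#' @examples
#' scale_beat(c(0, 1, 0.25), sbp = 120, dbp = 80)  # 80 120 90
#' @export
scale_beat <- function(beat, sbp, dbp) {
  if (!is.finite(sbp) || !is.finite(dbp) || dbp < 0 || sbp <= dbp) {
    abort("need sbp > dbp >= 0", class = "pulsewave_pressure_error")
  }
  dbp + beat * (sbp - dbp)
}

#' Synthesize one arterial pressure beat
#'
#' Composition of [resample_beat()] and [scale_beat()]: one beat at the
#' commanded heart rate whose extrema equal the commanded SBP and DBP.
#'
#' @inheritParams resample_beat
#' @inheritParams scale_beat
#' @return Pressure vector, mmHg, of `round(fs_out * 60 / hr)` samples.
#' @examples
#' b <- synthesize_beat(default_template(), hr = 60, sbp = 120, dbp = 80)
#' c(length(b), max(b), min(b))  # 250 120 80
#' @export
synthesize_beat <- function(template, hr, sbp, dbp, fs_out = 250) {
  scale_beat(resample_beat(template, hr, fs_out), sbp, dbp)
}

# --- pipeline -------------------------------------------------------------

# Deterministic role set: vitals polls are a precomputed table, template
# cycles come straight from the template.
det_roles <- function(scenario, template, config, collect_warning) {
  poll <- config$poll_period
  dur <- scenario$duration
  n_polls <- if (dur <= 0) 0L else as.integer(floor((dur - 1e-9) / poll)) + 1L
  poll_times <- (seq_len(n_polls) - 1) * poll
  polls <- if (n_polls > 0) {
    withCallingHandlers(
      sample_vitals(scenario, poll_times),
      pulsewave_clamp_warning = function(w) {
        collect_warning(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  } else {
    tibble::tibble(t_s = numeric(), hr_bpm = numeric(),
                   sbp_mmhg = numeric(), dbp_mmhg = numeric())
  }
  list(
    advance_to = function(t) invisible(NULL),
    poll_fetch = function(k) polls[k + 1L, ],
    get_cycle = function() template$samples,
    poll_log = function() polls
  )
}

# Concurrent role set: a vitals poller advancing event-by-event on the
# virtual clock, and a refiller keeping a bounded ring buffer topped up with
# template samples that the consumer drains one cycle per beat. Cooperative
# scheduling: the consumer yields to the poller for every poll event at or
# before its beat clock, and to the refiller whenever the buffer holds less
# than one cycle.
conc_roles <- function(scenario, template, config, collect_warning) {
  poll <- config$poll_period
  dur <- scenario$duration
  len <- length(template$samples)
  capacity <- config$buffer_capacity %||% (4L * len)
  if (config$buffer_policy == "block" && capacity < len) {
    abort("buffer_capacity smaller than one template cycle would deadlock the consumer")
  }
  rb <- ring_buffer(capacity, policy = config$buffer_policy)
  state <- new.env(parent = emptyenv())
  state$next_poll <- 0L          # poll index
  state$log <- list()
  state$cycle_pos <- 0L          # template phase of the refiller
  poller_step <- function() {
    t_p <- state$next_poll * poll
    row <- withCallingHandlers(
      sample_vitals(scenario, t_p),
      pulsewave_clamp_warning = function(w) {
        collect_warning(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    state$log[[state$next_poll + 1L]] <- row
    state$next_poll <- state$next_poll + 1L
  }
  refiller_step <- function() {
    free <- rb$capacity - rb$count
    if (free <= 0L) return(invisible(NULL))
    idx <- ((state$cycle_pos + seq_len(free) - 1L) %% len) + 1L
    pushed <- rb_push(rb, template$samples[idx])
    state$cycle_pos <- (state$cycle_pos + pushed) %% len
    invisible(NULL)
  }
  k_max <- if (dur <= 0) -1L else as.integer(floor((dur - 1e-9) / poll))
  list(
    advance_to = function(t) {
      while (state$next_poll <= k_max && state$next_poll * poll <= t + 1e-9) {
        poller_step()
      }
      invisible(NULL)
    },
    poll_fetch = function(k) state$log[[k + 1L]],
    get_cycle = function() {
      while (rb_size(rb) < len) refiller_step()
      rb_pop(rb, len)
    },
    poll_log = function() dplyr::bind_rows(state$log)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the streaming waveform pipeline
#'
#' Turns a vitals scenario plus a pulse template into a continuous pressure
#' waveform via three cooperating roles on a shared virtual clock: a
#' coordinator that initializes state and the ring buffer, a vitals poller
#' that samples the scenario once per poll period and publishes the latest
#' validated reading, and a waveform consumer that synthesizes beats at the
#' current vitals and emits pressure samples at `fs_out`.
#'
#' `mode = "deterministic"` executes the consumer directly against the
#' scenario (single role, virtual clock); `mode = "concurrent"` routes the
#' template stream through the bounded ring buffer and drives the poller as
#' a separate event process, interleaved cooperatively. Both modes must
#' produce the identical sample stream for identical inputs; the concurrent
#' mode exists to exercise the producer/consumer plumbing. (R executes on a
#' single thread, so concurrency here is cooperative interleaving on the
#' virtual clock, not preemptive threading; the data-flow contract — bounded
#' FIFO, single producer, single consumer, publish-then-consume ordering —
#' is the same one a threaded implementation must honour.)
#'
#' Under the default beat-atomic update policy every beat is synthesized
#' from exactly one vitals sample, the newest one published at the beat's
#' onset. While the commanded heart rate is zero the consumer emits a
#' flatline at the current diastolic pressure (logged as a warning) and
#' re-checks the vitals at the next poll.
#'
#' @param scenario A `vitals_scenario`.
#' @param template A `pulse_template`.
#' @param config An [engine_config()].
#' @param mode `"deterministic"` or `"concurrent"`.
#' @param sink Optional function called with each emitted chunk (a tibble of
#'   pressure samples). An error raised by the sink stops the pipeline and
#'   returns the partial run with a warning recorded.
#' @return A `pulse_run` object: `waveform` (tibble `t_s`, `p_mmhg`,
#'   `beat_index`), `beats` (per-beat provenance: onset, sample count, and
#'   the vitals used), `poll_log`, counts, and accumulated warnings.
#'   [tidy()] returns the per-beat table, [glance()] a one-row summary.
#' @examples
#' run <- run_pipeline(
#'   make_synthetic_scenario("steady", duration = 10),
#'   default_template()
#' )
#' glance(run)
#' @export
run_pipeline <- function(scenario, template, config = engine_config(),
                         mode = c("deterministic", "concurrent"),
                         sink = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "vitals_scenario"),
            inherits(template, "pulse_template"))
  fs <- config$fs_out
  poll <- config$poll_period
  dur <- scenario$duration
  warnings <- character()
  collect_warning <- function(msg) warnings <<- c(warnings, msg)

  roles <- switch(mode,
    deterministic = det_roles(scenario, template, config, collect_warning),
    concurrent = conc_roles(scenario, template, config, collect_warning)
  )

  chunks <- list()
  beat_rows <- list()
  m <- 0L            # total samples scheduled (clock = m / fs)
  beat_i <- 0L
  hr_zero_flagged <- FALSE
  sink_failed <- FALSE

  emit <- function(chunk) {
    chunks[[length(chunks) + 1L]] <<- chunk
    if (!is.null(sink)) {
      ok <- tryCatch({ sink(chunk); TRUE }, error = function(e) {
        collect_warning(paste0("sink failure: ", conditionMessage(e)))
        FALSE
      })
      if (!ok) sink_failed <<- TRUE
    }
  }

  while (!sink_failed) {
    t_b <- m / fs
    if (t_b >= dur - 1e-9) break
    roles$advance_to(t_b)
    k <- as.integer(floor(t_b / poll + 1e-9))
    v <- roles$poll_fetch(k)
    if (v$hr_bpm == 0) {
      if (!hr_zero_flagged) {
        collect_warning("hr = 0: emitting flatline at diastolic pressure")
        hr_zero_flagged <- TRUE
      }
      t_end <- min((k + 1L) * poll, dur)
      n_flat <- as.integer(ceiling(t_end * fs - 1e-9)) - m
      if (n_flat <= 0L) break
      emit(tibble::tibble(t_s = (m + seq_len(n_flat) - 1L) / fs,
                          p_mmhg = v$dbp_mmhg,
                          beat_index = NA_integer_))
      m <- m + n_flat
      next
    }
    cycle <- roles$get_cycle()
    nvec <- resample_beat(
      pulse_template(cycle, fs = template$fs, hr_ref = template$hr_ref),
      hr = v$hr_bpm, fs_out = fs
    )
    n <- length(nvec)
    t_all <- (m + seq_len(n) - 1L) / fs
    keep <- t_all < dur - 1e-9
    if (config$update_policy == "beat") {
      p <- scale_beat(nvec, v$sbp_mmhg, v$dbp_mmhg)
    } else {
      roles$advance_to(t_all[n])
      ks <- pmin(as.integer(floor(t_all / poll + 1e-9)),
                 as.integer(floor((dur - 1e-9) / poll)))
      vs <- dplyr::bind_rows(lapply(unique(ks), roles$poll_fetch))
      vi <- match(ks, unique(ks))
      p <- vs$dbp_mmhg[vi] + nvec * (vs$sbp_mmhg[vi] - vs$dbp_mmhg[vi])
    }
    beat_i <- beat_i + 1L
    beat_rows[[beat_i]] <- tibble::tibble(
      beat_index = beat_i, t_onset_s = t_b, n_samples = sum(keep),
      hr_bpm = v$hr_bpm, sbp_mmhg = v$sbp_mmhg, dbp_mmhg = v$dbp_mmhg,
      poll_t_s = k * poll
    )
    emit(tibble::tibble(t_s = t_all[keep], p_mmhg = p[keep],
                        beat_index = beat_i))
    m <- m + n
  }

  waveform <- if (length(chunks) > 0) dplyr::bind_rows(chunks) else {
    tibble::tibble(t_s = numeric(), p_mmhg = numeric(),
                   beat_index = integer())
  }
  beats <- if (beat_i > 0) dplyr::bind_rows(beat_rows) else {
    tibble::tibble(beat_index = integer(), t_onset_s = numeric(),
                   n_samples = integer(), hr_bpm = numeric(),
                   sbp_mmhg = numeric(), dbp_mmhg = numeric(),
                   poll_t_s = numeric())
  }
  structure(
    list(waveform = waveform, beats = beats,
         poll_log = roles$poll_log(),
         n_beats = beat_i, n_samples = nrow(waveform),
         warnings = warnings, config = config, mode = mode,
         complete = !sink_failed),
    class = "pulse_run"
  )
}

#' @export
print.pulse_run <- function(x, ...) {
  cat(sprintf("<pulse_run> %d beat(s), %d sample(s) @ %g Hz (%s mode)%s\n",
              x$n_beats, x$n_samples, x$config$fs_out, x$mode,
              if (x$complete) "" else " [partial: sink failure]"))
  if (length(x$warnings) > 0) {
    cat("warnings:\n"); for (w in unique(x$warnings)) cat(" -", w, "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pulse_run <- function(x, ...) x$beats

#' @exportS3Method generics::glance
glance.pulse_run <- function(x, ...) {
  tibble::tibble(
    n_beats = x$n_beats, n_samples = x$n_samples,
    fs_out = x$config$fs_out, mode = x$mode,
    duration_s = if (x$n_samples > 0) tail(x$waveform$t_s, 1) + 1 / x$config$fs_out else 0,
    n_warnings = length(x$warnings), complete = x$complete
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pulse_run <- function(object, ...) {
  ggplot2::ggplot(object$waveform,
                  ggplot2::aes(x = .data$t_s, y = .data$p_mmhg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Pressure (mmHg)",
                  title = sprintf("Synthesized arterial waveform (%d beats)",
                                  object$n_beats))
}
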