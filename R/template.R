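#' Construct a pulse template
#'
#' A pulse template is the normalized single-beat reference waveform: a
#' dimensionless amplitude series spanning exactly [0, 1], together with the
#' sampling rate and heart rate of the source recording. One beat of arterial
#' pressure at any commanded heart rate and SBP/DBP is produced by resampling
#' this series in phase and rescaling its amplitude.
#'
#' Invariants enforced: `min(samples) == 0` and `max(samples) == 1` exactly;
#' at least 8 samples; `fs > 0`; `0 < hr_ref <= 350`; both endpoints at most
#' 0.05 so consecutive beats join without a pressure jump.
#'
#' @param samples Numeric amplitude series in [0, 1].
#' @param fs Sampling rate of the series, Hz.
#' @param hr_ref Heart rate of the source recording, bpm.
#' @return An object of class `pulse_template`.
#' @export
pulse_template <- function(samples, fs, hr_ref) {
  samples <- as.numeric(samples)
  if (length(samples) < 8) {
    abort("template too short: need at least 8 samples",
          class = "pulsewave_template_error")
  }
  if (!all(is.finite(samples))) {
    abort("template samples must be finite", class = "pulsewave_template_error")
  }
  if (!is.finite(fs) || fs <= 0) {
    abort("template fs must be > 0", class = "pulsewave_template_error")
  }
  if (!is.finite(hr_ref) || hr_ref <= 0 || hr_ref > 350) {
    abort("template hr_ref must be in (0, 350]", class = "pulsewave_template_error")
  }
  if (abs(min(samples)) > 1e-12 || abs(max(samples) - 1) > 1e-12) {
    abort("template samples must span [0, 1] exactly (min 0, max 1)",
          class = "pulsewave_template_error")
  }
  if (samples[1] > 0.05 || samples[length(samples)] > 0.05) {
    abort("template endpoints must be <= 0.05 so beats concatenate smoothly",
          class = "pulsewave_template_error")
  }
  structure(list(samples = samples, fs = as.numeric(fs),
                 hr_ref = as.numeric(hr_ref)),
            class = "pulse_template")
}

#' @export
print.pulse_template <- function(x, ...) {
  cat(sprintf("<pulse_template> %d samples @ %g Hz, reference HR %g bpm\n",
              length(x$samples), x$fs, x$hr_ref))
  invisible(x)
}

#' Min-max normalize a recorded beat into a pulse template
#'
#' Rescales a single-beat pressure recording so its minimum maps to 0 and its
#' maximum to 1: `s_i = (raw_i - min) / (max - min)`. The normalization is
#' idempotent and invariant to positive affine changes of the input, so the
#' template depends only on the beat's shape, not the pressures at which it
#' was recorded.
#'
#' @param raw Numeric pressure series for one beat, mmHg (>= 8 samples).
#' @param fs Sampling rate of the recording, Hz.
#' @param hr_ref Heart rate of the recording, bpm.
#' @return A `pulse_template`.
#' @examples
#' tpl <- normalize_template(c(80, 81, 120, 96, 90, 86, 83, 81), 250, 60)
#' range(tpl$samples)
#' @export
normalize_template <- function(raw, fs, hr_ref) {
  raw <- as.numeric(raw)
  if (length(raw) < 8) {
    abort("template too short: need at least 8 samples",
          class = "pulsewave_template_error")
  }
  rng <- range(raw)
  if (!all(is.finite(rng)) || rng[2] <= rng[1]) {
    abort("zero amplitude: max(raw) must exceed min(raw)",
          class = "pulsewave_template_error")
  }
  pulse_template((raw - rng[1]) / (rng[2] - rng[1]), fs = fs, hr_ref = hr_ref)
}

#' Generate a synthetic arterial pulse template
#'
#' Builds a parametric single-beat waveform with the canonical arterial
#' morphology: a fast systolic upstroke (raised-cosine) peaking at
#' `systolic_fraction` of the beat, an exponential diastolic decay, and a
#' Gaussian dicrotic wave on the downstroke marking aortic valve closure.
#' The series is min-max renormalized so it satisfies every `pulse_template`
#' invariant. It ships as the package default in place of a real-patient
#' recording, with the default metadata of a 250 Hz, 47 bpm acquisition.
#'
#' @param fs Sampling rate, Hz.
#' @param hr_ref Nominal heart rate of the synthetic beat, bpm; the template
#'   holds `round(fs * 60 / hr_ref)` samples (round half away from zero).
#' @param systolic_fraction Fraction of the beat occupied by the upstroke,
#'   in (0, 1).
#' @param dicrotic_amplitude Relative amplitude of the dicrotic wave, in
#'   [0, 1); 0 gives a strictly unimodal beat.
#' @param jitter_sd Standard deviation of optional additive shape noise
#'   (dimensionless, applied before renormalization); 0 keeps the template
#'   fully deterministic.
#' @param seed Seed used when `jitter_sd > 0`.
#' @return A `pulse_template`.
#' @examples
#' tpl <- make_synthetic_template()
#' length(tpl$samples)  # 319 at 250 Hz, 47 bpm
#' @export
make_synthetic_template <- function(fs = 250, hr_ref = 47,
                                    systolic_fraction = 0.3,
                                    dicrotic_amplitude = 0.15,
                                    jitter_sd = 0, seed = 1) {
  if (!is.finite(fs) || fs <= 0) abort("fs must be > 0")
  if (!is.finite(hr_ref) || hr_ref <= 0 || hr_ref > 350) {
    abort("hr_ref must be in (0, 350]")
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    abort("systolic_fraction must be in (0, 1)")
  }
  if (dicrotic_amplitude < 0 || dicrotic_amplitude >= 1) {
    abort("dicrotic_amplitude must be in [0, 1)")
  }
  if (jitter_sd < 0) abort("jitter_sd must be non-negative")
  n <- round_half_away(fs * 60 / hr_ref)
  if (n < 8) abort("fs / hr_ref combination yields fewer than 8 samples")
  x <- (seq_len(n) - 1) / n  # beat phase in [0, 1)
  s <- systolic_fraction
  up <- x < s
  y <- numeric(n)
  y[up] <- 0.5 * (1 - cos(pi * x[up] / s))
  # Diastolic decay with time constant (1 - s)/3.2: the end-of-beat value is
  # exp(-3.2) ~ 0.041, safely inside the 0.05 endpoint budget even after
  # renormalization.
  tau <- (1 - s) / 3.2
  y[!up] <- exp(-(x[!up] - s) / tau)
  if (dicrotic_amplitude > 0) {
    x_d <- s + 0.35 * (1 - s)      # dicrotic wave centre on the downstroke
    # narrow enough that the wave forms a genuine secondary maximum (its
    # rising slope must exceed the local decay slope), as on a real beat
    w <- (1 - s) / 16
    y <- y + dicrotic_amplitude * exp(-0.5 * ((x - x_d) / w)^2)
  }
  if (jitter_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    y <- y + rnorm(n, 0, jitter_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  y <- (y - min(y)) / (max(y) - min(y))
  pulse_template(y, fs = fs, hr_ref = hr_ref)
}

#' The packaged default pulse template
#'
#' A synthetic normal arterial beat carrying the metadata of the reference
#' recording the simulator emulates: 250 Hz sampling and a 47 bpm source
#' heart rate (319 samples).
#'
#' @return A `pulse_template`.
#' @export
default_template <- function() {
  make_synthetic_template(fs = 250, hr_ref = 47,
                          systolic_fraction = 0.3, dicrotic_amplitude = 0.15)
}

#' Read / write a pulse template file
#'
#' The template file is plain text: comment-style metadata lines
#' `# fs_hz=<value>` and `# hr_ref_bpm=<value>`, then one normalized
#' amplitude per line. `save_template()` then `load_template()` round-trips
#' the samples and metadata exactly (values are written with full `%.17g`
#' precision).
#'
#' @param file Path to the template file.
#' @return `load_template()` returns a `pulse_template`; `save_template()`
#'   returns `file` invisibly.
#' @export
load_template <- function(file) {
  lines <- readLines(file, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0) {
      abort(sprintf("template file missing metadata header '# %s='", key),
            class = "pulsewave_parse_error")
    }
    as.numeric(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1]))
  }
  fs <- get_meta("fs_hz")
  hr_ref <- get_meta("hr_ref_bpm")
  samples <- suppressWarnings(as.numeric(body))
  if (any(is.na(samples))) {
    abort("template file contains non-numeric sample lines",
          class = "pulsewave_parse_error")
  }
  pulse_template(samples, fs = fs, hr_ref = hr_ref)
}

#' @rdname load_template
#' @param template A `pulse_template` to write.
#' @export
save_template <- function(template, file) {
  stopifnot(inherits(template, "pulse_template"))
  writeLines(
    c(sprintf("# fs_hz=%.17g", template$fs),
      sprintf("# hr_ref_bpm=%.17g", template$hr_ref),
      sprintf("%.17g", template$samples)),
    file
  )
  invisible(file)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pulse_template <- function(object, ...) {
  df <- tibble::tibble(
    t_s = (seq_along(object$samples) - 1) / object$fs,
    amplitude = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Normalized amplitude",
                  title = sprintf("Pulse template (%g Hz, ref %g bpm)",
                                  object$fs, object$hr_ref))
}
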