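#' Pressure-to-voltage mapping configuration
#'
#' The monitor's analog input convention: pressure is directly proportional
#' to voltage, 0 mmHg at 0 V up to `p_max` mmHg at `v_max` V (500 mmHg and
#' 5 V by default), quantized by a `bits`-deep DAC (12 by default, codes
#' 0-4095).
#'
#' @param p_max Full-scale pressure, mmHg.
#' @param v_max Full-scale voltage, V.
#' @param bits DAC resolution in bits.
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(p_max = 500, v_max = 5, bits = 12) {
  if (!is.finite(p_max) || p_max <= 0) abort("p_max must be > 0")
  if (!is.finite(v_max) || v_max <= 0) abort("v_max must be > 0")
  if (!is.finite(bits) || bits < 1) abort("bits must be >= 1")
  structure(list(p_max = p_max, v_max = v_max, bits = as.integer(bits)),
            class = "mapping_config")
}

#' Map pressure to analog voltage
#'
#' Linear, strictly increasing map `v = p * v_max / p_max` after clamping
#' the pressure into `[0, p_max]`. Out-of-range inputs are clamped with a
#' warning rather than rejected: the output stage must never crash a running
#' stream.
#'
#' @param p Pressure, mmHg (vectorized).
#' @param cfg A [mapping_config()].
#' @return Voltage, V, in `[0, v_max]`.
#' @examples
#' mmhg_to_volts(c(0, 120, 500))  # 0.0 1.2 5.0
#' @export
mmhg_to_volts <- function(p, cfg = mapping_config()) {
  n_out <- sum(!is.finite(p) | p < 0 | p > cfg$p_max)
  if (n_out > 0) {
    warn(sprintf("%d pressure value(s) clamped into [0, %g] mmHg before mapping",
                 n_out, cfg$p_max),
         class = "pulsewave_clamp_warning")
  }
  clamp(p, 0, cfg$p_max) * cfg$v_max / cfg$p_max
}

#' @rdname mmhg_to_volts
#' @param v Voltage, V.
#' @return `volts_to_mmhg()` returns the pressure a voltage encodes.
#' @export
volts_to_mmhg <- function(v, cfg = mapping_config()) {
  v * cfg$p_max / cfg$v_max
}

#' Quantize a voltage to a DAC code
#'
#' `code = round(v * (2^bits - 1) / v_max)`, rounding half away from zero
#' and clamping to `[0, 2^bits - 1]`. Full scale maps to the top code
#' (4095 for 12 bits); note real DAC chips sometimes divide by `2^bits`
#' instead — this package fixes and tests the `2^bits - 1` convention.
#'
#' @param v Voltage, V (vectorized; clamped into `[0, v_max]`).
#' @param cfg A [mapping_config()].
#' @return Integer DAC codes.
#' @examples
#' quantize_to_code(c(0, 2.5, 5))  # 0 2048 4095
#' @export
quantize_to_code <- function(v, cfg = mapping_config()) {
  full <- 2^cfg$bits - 1
  code <- round_half_away(clamp(v, 0, cfg$v_max) * full / cfg$v_max)
  as.integer(clamp(code, 0, full))
}

#' @rdname quantize_to_code
#' @param code Integer DAC codes.
#' @return `code_to_volts()` returns the voltage a code reconstructs to.
#' @export
code_to_volts <- function(code, cfg = mapping_config()) {
  code * cfg$v_max / (2^cfg$bits - 1)
}

#' @rdname quantize_to_code
#' @return `decode_pressure()` returns the pressure in mmHg a code
#'   reconstructs to; round-trip error from mapping plus quantization is at
#'   most half an LSB in pressure units (about 0.061 mmHg at defaults).
#' @export
decode_pressure <- function(code, cfg = mapping_config()) {
  volts_to_mmhg(code_to_volts(code, cfg), cfg)
}

#' Attach voltages and DAC codes to a pressure waveform
#'
#' @param waveform Data frame with columns `t_s` and `p_mmhg` (e.g.
#'   `run$waveform` from [run_pipeline()]).
#' @param cfg A [mapping_config()].
#' @return The input tibble with `volts` and `dac_code` columns added.
#' @export
as_voltage <- function(waveform, cfg = mapping_config()) {
  wf <- tibble::as_tibble(waveform)
  stopifnot(all(c("t_s", "p_mmhg") %in% names(wf)))
  wf$volts <- mmhg_to_volts(wf$p_mmhg, cfg)
  wf$dac_code <- quantize_to_code(wf$volts, cfg)
  wf
}

#' Write / read a waveform file
#'
#' CSV with header `t_s,p_mmhg,volts,dac_code`, one row per sample. Floats
#' are written with 6 significant digits, which the reader recovers exactly,
#' so write-then-read round-trips at that precision; DAC codes round-trip
#' exactly.
#'
#' @param waveform Data frame with columns `t_s`, `p_mmhg`, `volts`,
#'   `dac_code`, time-ordered (see [as_voltage()]).
#' @param file Output path.
#' @return `write_waveform()` returns the number of data rows written;
#'   `read_waveform()` returns the waveform tibble.
#' @export
write_waveform <- function(waveform, file) {
  wf <- tibble::as_tibble(waveform)
  cols <- c("t_s", "p_mmhg", "volts", "dac_code")
  stopifnot(all(cols %in% names(wf)))
  wf <- wf[cols]
  if (nrow(wf) > 0 && is.unsorted(wf$t_s)) {
    abort("waveform samples must be time-ordered")
  }
  fmt6 <- function(x) trimws(formatC(signif(x, 6), format = "g", digits = 6))
  out <- data.frame(
    t_s = fmt6(wf$t_s),
    p_mmhg = fmt6(wf$p_mmhg),
    volts = fmt6(wf$volts),
    dac_code = wf$dac_code
  )
  readr::write_csv(out, file, progress = FALSE)
  nrow(wf)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(file) {
  readr::read_csv(
    file,
    col_types = readr::cols(
      t_s = readr::col_double(), p_mmhg = readr::col_double(),
      volts = readr::col_double(), dac_code = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Recording mock of the DAC driver
#'
#' Stands in for the hardware digital-to-analog converter: it accepts codes
#' and appends them to an in-memory log, preserving order. Use [dac_log()]
#' to retrieve everything written.
#'
#' @return A `dac_driver` object.
#' @export
mock_dac_driver <- function() {
  env <- new.env(parent = emptyenv())
  env$codes <- integer(0)
  env$write <- function(code) env$codes <- c(env$codes, as.integer(code))
  class(env) <- "dac_driver"
  env
}

#' @rdname mock_dac_driver
#' @param driver A `dac_driver`.
#' @return `dac_log()` returns the integer codes written so far, in order.
#' @export
dac_log <- function(driver) {
  stopifnot(inherits(driver, "dac_driver"))
  driver$codes
}

#' Forward voltage samples to a DAC driver
#'
#' The output sink of the pipeline: validates the codes and hands them to a
#' pluggable driver. The packaged driver is the recording mock; driving a
#' physical converter requires supplying a driver object, and omitting one
#' raises an explicit error rather than failing silently.
#'
#' @param waveform Data frame with a `dac_code` column (see [as_voltage()]).
#' @param driver A `dac_driver`; the packaged option is [mock_dac_driver()].
#' @return The number of codes forwarded, invisibly.
#' @export
dac_sink <- function(waveform, driver = NULL) {
  if (is.null(driver)) {
    abort("hardware unavailable: no DAC driver installed; pass mock_dac_driver() to record codes",
          class = "pulsewave_hardware_error")
  }
  stopifnot(inherits(driver, "dac_driver"))
  wf <- tibble::as_tibble(waveform)
  stopifnot("dac_code" %in% names(wf))
  codes <- wf$dac_code
  if (length(codes) > 0 && (min(codes) < 0 || max(codes) > 4095)) {
    abort("DAC codes out of [0, 4095]")
  }
  driver$write(codes)
  invisible(length(codes))
}
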