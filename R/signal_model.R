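#' Synthetic BCG specification
#'
#' Parameters of the sum-of-sinusoids ballistocardiogram model: six cardiac
#' harmonics between 1.5 and 9 Hz plus a low-frequency respiratory sinusoid.
#' The defaults are the published simulation conditions: cardiac frequencies
#' 1.5, 3, 4.5, 6, 7.5 and 9 Hz with amplitudes 0.1, 0.2, 0.1, 0.4, 0.3 and
#' 0.6 a.u., a 0.2 Hz respiratory component of amplitude 2 a.u., sampled at
#' 100 Hz for 30 s.
#'
#' @param cardiac_freqs Cardiac component frequencies (Hz).
#' @param cardiac_amps Cardiac component amplitudes (a.u.); same length as
#'   `cardiac_freqs`.
#' @param resp_freq Respiratory frequency (Hz).
#' @param resp_amp Respiratory amplitude (a.u.).
#' @param duration Signal duration (s).
#' @param rate Sampling rate (Hz). All frequencies must be below `rate / 2`.
#' @param seed Default seed for noise realizations built from this spec.
#' @return An object of class `bcg_spec`.
#' @export
#' @examples
#' spec <- bcg_spec(duration = 10)
#' comps <- bcg_components(spec)
#' head(comps)
bcg_spec <- function(cardiac_freqs = c(1.5, 3, 4.5, 6, 7.5, 9),
                     cardiac_amps = c(0.1, 0.2, 0.1, 0.4, 0.3, 0.6),
                     resp_freq = 0.2,
                     resp_amp = 2,
                     duration = 30,
                     rate = 100,
                     seed = 1L) {
  stopifnot(length(cardiac_freqs) == length(cardiac_amps))
  if (rate <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (any(cardiac_amps < 0) || resp_amp < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  freqs <- c(cardiac_freqs, resp_freq)
  if (any(freqs >= rate / 2)) {
    bad <- freqs[freqs >= rate / 2]
    stop(
      "component frequency ", paste(bad, collapse = ", "),
      " Hz is at or above the Nyquist frequency ", rate / 2, " Hz",
      call. = FALSE
    )
  }
  structure(
    list(
      cardiac_freqs = as.double(cardiac_freqs),
      cardiac_amps = as.double(cardiac_amps),
      resp_freq = as.double(resp_freq),
      resp_amp = as.double(resp_amp),
      duration = as.double(duration),
      rate = as.double(rate),
      seed = as.integer(seed)
    ),
    class = "bcg_spec"
  )
}

#' @export
print.bcg_spec <- function(x, ...) {
  cat("<bcg_spec>\n")
  cat(
    "  cardiac:", paste0(x$cardiac_freqs, " Hz (A=", x$cardiac_amps, ")",
      collapse = ", "
    ), "\n"
  )
  cat("  respiratory:", x$resp_freq, "Hz (A=", x$resp_amp, ")\n")
  cat("  duration:", x$duration, "s at", x$rate, "Hz, seed", x$seed, "\n")
  invisible(x)
}

#' Generate the noise-free synthetic BCG components
#'
#' Evaluates the deterministic part of the model: the cardiac component is
#' `sum_k A_k sin(2 pi f_k t)` and the respiratory component
#' `A_r sin(2 pi f_r t)`, both on the sample grid `t = n / rate`, n = 0 .. N-1.
#'
#' @param spec A [bcg_spec()].
#' @return A tibble with columns `time`, `cardiac`, `respiratory`, and their
#'   sum `clean`; sampling rate attached as attribute `rate`.
#' @export
bcg_components <- function(spec) {
  stopifnot(inherits(spec, "bcg_spec"))
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  cardiac <- rep(0, n)
  for (k in seq_along(spec$cardiac_freqs)) {
    cardiac <- cardiac + spec$cardiac_amps[k] * sin(2 * pi * spec$cardiac_freqs[k] * t)
  }
  respiratory <- spec$resp_amp * sin(2 * pi * spec$resp_freq * t)
  out <- tibble::tibble(
    time = t,
    cardiac = cardiac,
    respiratory = respiratory,
    clean = cardiac + respiratory
  )
  attr(out, "rate") <- spec$rate
  out
}

#' Calibrated Gaussian white noise
#'
#' Draws i.i.d. zero-mean Gaussian noise whose standard deviation realizes a
#' nominal signal-to-noise ratio against a reference signal:
#' `sigma = RMS(reference) * 10^(-snr_db / 20)`.
#'
#' @param reference Reference signal (numeric vector, or data frame with a
#'   `value` column) defining the signal power. Must have positive power.
#' @param snr_db Nominal SNR in dB (0 dB makes the noise RMS equal the
#'   reference RMS).
#' @param seed Integer seed; the draw is reproducible and does not disturb the
#'   caller's RNG state.
#' @return Numeric vector of noise samples, same length as `reference`.
#' @export
gaussian_noise <- function(reference, snr_db, seed) {
  ref <- signal_values(reference)
  p <- mean(ref^2)
  if (!is.finite(p) || p <= 0) {
    stop("reference signal has zero power; SNR is undefined", call. = FALSE)
  }
  sigma <- sqrt(p) * 10^(-snr_db / 20)
  withr::with_seed(as.integer(seed), stats::rnorm(length(ref), 0, sigma))
}

#' Simulate a noisy synthetic BCG
#'
#' Generates the clean components of `spec` and adds Gaussian white noise
#' calibrated to `snr_db` against the full clean signal
#' (cardiac + respiratory). The output decomposes exactly:
#' `noisy == cardiac + respiratory + noise` sample-wise.
#'
#' @param spec A [bcg_spec()].
#' @param snr_db Nominal SNR (dB) of the added noise; the study conditions
#'   cover 0 to 15 dB.
#' @param seed Noise seed; defaults to the seed stored in `spec`.
#' @param noise_ref Reference for noise calibration: `"clean"` (default; the
#'   full cardiac + respiratory signal) or `"cardiac"`.
#' @return A tibble with columns `time`, `cardiac`, `respiratory`, `clean`,
#'   `noise`, `noisy`; attributes `rate` and `nominal_snr_db`.
#' @export
#' @examples
#' sim <- bcg_simulate(bcg_spec(duration = 5), snr_db = 10, seed = 42)
#' measure_snr(sim$noisy, sim$clean)
bcg_simulate <- function(spec, snr_db, seed = spec$seed,
                         noise_ref = c("clean", "cardiac")) {
  noise_ref <- match.arg(noise_ref)
  comps <- bcg_components(spec)
  ref <- if (noise_ref == "clean") comps$clean else comps$cardiac
  noise <- gaussian_noise(ref, snr_db, seed)
  out <- dplyr::mutate(comps, noise = noise, noisy = .data$clean + noise)
  attr(out, "rate") <- spec$rate
  attr(out, "nominal_snr_db") <- snr_db
  out
}

#' Signal-to-noise ratio of an estimate against a reference
#'
#' `10 * log10(P(reference) / P(estimate - reference))` in dB, where `P` is
#' mean squared amplitude. When the residual power is exactly zero the value
#' is capped (default 300 dB) instead of returning infinity.
#'
#' @param estimate,reference Equal-length numeric vectors (or data frames with
#'   a `value` column). The reference must have positive power.
#' @param cap_db Value returned when the residual power is 0.
#' @return SNR in dB (scalar).
#' @export
measure_snr <- function(estimate, reference, cap_db = 300) {
  est <- signal_values(estimate)
  ref <- signal_values(reference)
  if (length(est) != length(ref)) {
    stop("estimate and reference must have equal length", call. = FALSE)
  }
  p_ref <- mean(ref^2)
  if (!is.finite(p_ref) || p_ref <= 0) {
    stop("reference signal has zero power", call. = FALSE)
  }
  p_res <- mean((est - ref)^2)
  if (p_res == 0) {
    return(cap_db)
  }
  min(10 * log10(p_ref / p_res), cap_db)
}

#' Beat-train test signal with known peak times
#'
#' Places one template pulse at each (optionally jittered) beat time and
#' returns the ground-truth peak times alongside the waveform. This is a test
#' harness for peak detectors, not a physiological simulator: the pulses are
#' identical, there is no respiratory modulation and no pathology.
#'
#' @param rate_bpm Beat rate (beats per minute, > 0).
#' @param duration Signal duration (s).
#' @param fs Sampling rate (Hz, >= 50).
#' @param jitter_sd Standard deviation of Gaussian timing jitter (s).
#' @param template Pulse shape: `"gaussian-bump"` or `"biphasic"` (first
#'   derivative of a Gaussian, ECG-like).
#' @param amplitude Pulse amplitude (a.u.).
#' @param width Pulse width parameter (s), the Gaussian sigma.
#' @param seed Jitter seed.
#' @return A list with `signal` (tibble `time`, `value`; attribute `rate`)
#'   and `peak_times` (seconds).
#' @export
#' @examples
#' bt <- beat_train(60, duration = 10, fs = 100, jitter_sd = 0, seed = 1)
#' length(bt$peak_times)
beat_train <- function(rate_bpm, duration, fs = 100, jitter_sd = 0,
                       template = c("gaussian-bump", "biphasic"),
                       amplitude = 1, width = 0.03, seed = 1L) {
  template <- match.arg(template)
  if (rate_bpm <= 0) stop("rate_bpm must be positive", call. = FALSE)
  if (fs < 50) stop("fs must be at least 50 Hz", call. = FALSE)
  period <- 60 / rate_bpm
  base_times <- seq(period / 2, duration - period / 4, by = period)
  jitter <- if (jitter_sd > 0) {
    withr::with_seed(as.integer(seed), stats::rnorm(length(base_times), 0, jitter_sd))
  } else {
    rep(0, length(base_times))
  }
  times <- base_times + jitter
  if (length(times) > 1 && min(diff(times)) < 4 * width) {
    stop("jitter too large: adjacent beats overlap", call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  value <- rep(0, n)
  for (tc in times) {
    u <- (t - tc) / width
    # both templates have their positive maximum exactly at the beat time,
    # so the returned peak times are the waveform ground truth
    pulse <- switch(template,
      "gaussian-bump" = exp(-u^2 / 2),
      "biphasic" = -(u - 1) * exp(-(u - 1)^2 / 2) * exp(0.5)
    )
    value <- value + amplitude * pulse
  }
  sig <- tibble::tibble(time = t, value = value)
  attr(sig, "rate") <- fs
  list(signal = sig, peak_times = times)
}

#' Write / read a synthetic BCG bundle
#'
#' Exports a simulated bundle as a 4-column CSV (`time_s`, `cardiac`,
#' `respiratory`, `noise`) plus a JSON sidecar holding the generating
#' parameters; `read_bcg_bundle()` round-trips the values at full double
#' precision and reassembles the `noisy` column.
#'
#' @param sim A tibble from [bcg_simulate()].
#' @param spec The [bcg_spec()] that generated it.
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @return `write_bcg_bundle()` returns `path` invisibly; `read_bcg_bundle()`
#'   returns a list with `signal` (tibble as from [bcg_simulate()]) and `spec`.
#' @export
write_bcg_bundle <- function(sim, spec, path) {
  stopifnot(inherits(spec, "bcg_spec"))
  out <- tibble::tibble(
    time_s = sim$time, cardiac = sim$cardiac,
    respiratory = sim$respiratory, noise = sim$noise
  )
  readr::write_csv(out, path)
  sidecar <- unclass(spec)
  sidecar$nominal_snr_db <- attr(sim, "nominal_snr_db")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bcg_bundle
#' @export
read_bcg_bundle <- function(path) {
  # base read.csv parses doubles with strtod, which is exact to the last ulp
  df <- tibble::as_tibble(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- bcg_spec(
    cardiac_freqs = meta$cardiac_freqs, cardiac_amps = meta$cardiac_amps,
    resp_freq = meta$resp_freq, resp_amp = meta$resp_amp,
    duration = meta$duration, rate = meta$rate, seed = meta$seed
  )
  sig <- tibble::tibble(
    time = df$time_s,
    cardiac = df$cardiac,
    respiratory = df$respiratory,
    clean = df$cardiac + df$respiratory,
    noise = df$noise,
    noisy = df$cardiac + df$respiratory + df$noise
  )
  attr(sig, "rate") <- spec$rate
  attr(sig, "nominal_snr_db") <- meta$nominal_snr_db
  list(signal = sig, spec = spec)
}

#' Front-end hardware emulation filter
#'
#' Optional emulation of the acquisition front end: a 1-30 Hz Butterworth
#' band-pass followed by a fixed gain of 4. Off by default in all simulation
#' paths because the simulation study keeps the respiratory term explicit.
#'
#' @param x Signal (numeric vector or data frame with `value` column).
#' @param rate Sampling rate (Hz).
#' @param band Pass band (Hz).
#' @param gain Amplification factor.
#' @return Numeric vector, filtered and amplified.
#' @export
emulate_frontend <- function(x, rate = 100, band = c(1, 30), gain = 4) {
  v <- signal_values(x)
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  gain * as.numeric(signal::filtfilt(bf, v))
}
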