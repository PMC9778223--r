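#' Specification of the EMG conditioning filter chain
#'
#' Describes the digital equivalent of a hardware surface-EMG conditioning
#' front end: a high-pass filter removing motion artifacts and electrode
#' drift, a low-pass filter removing wide-band high-frequency noise, and a
#' narrow notch removing power-line (AC baseline) interference.
#'
#' @param emg_sampling_rate_hz Sampling rate of the EMG channels in Hz.
#' @param highpass_cutoff_hz High-pass corner frequency in Hz. Default 10 Hz,
#'   the conventional corner for suppressing motion artifact in surface EMG.
#' @param lowpass_cutoff_hz Low-pass corner frequency in Hz. Default 500 Hz,
#'   the upper edge of the useful surface-EMG band.
#' @param notch_freq_hz Power-line frequency in Hz (50 Hz mains).
#' @param notch_quality Quality factor of the notch; higher is narrower.
#' @param filter_order Butterworth order for the high- and low-pass sections.
#' @param notch_harmonics If TRUE, additional notches are placed at the 2nd
#'   and 3rd harmonics of `notch_freq_hz`.
#'
#' @return An object of class `filter_chain_spec`.
#' @export
filter_chain_spec <- function(emg_sampling_rate_hz = 2000,
                              highpass_cutoff_hz = 10,
                              lowpass_cutoff_hz = 500,
                              notch_freq_hz = 50,
                              notch_quality = 30,
                              filter_order = 4,
                              notch_harmonics = FALSE) {
  if (!is.numeric(emg_sampling_rate_hz) || length(emg_sampling_rate_hz) != 1 ||
      !is.finite(emg_sampling_rate_hz) || emg_sampling_rate_hz <= 0) {
    stop("configuration error: emg_sampling_rate_hz must be a positive number",
         call. = FALSE)
  }
  nyquist <- emg_sampling_rate_hz / 2
  if (lowpass_cutoff_hz >= nyquist) {
    stop(sprintf(
      "configuration error: lowpass_cutoff_hz (%g Hz) must be below the Nyquist frequency (%g Hz)",
      lowpass_cutoff_hz, nyquist), call. = FALSE)
  }
  if (highpass_cutoff_hz <= 0 || highpass_cutoff_hz >= lowpass_cutoff_hz) {
    stop(sprintf(
      "configuration error: highpass_cutoff_hz (%g Hz) must lie in (0, lowpass_cutoff_hz = %g Hz)",
      highpass_cutoff_hz, lowpass_cutoff_hz), call. = FALSE)
  }
  if (notch_freq_hz <= 0 || notch_freq_hz >= nyquist) {
    stop(sprintf(
      "configuration error: notch_freq_hz (%g Hz) must lie in (0, Nyquist = %g Hz)",
      notch_freq_hz, nyquist), call. = FALSE)
  }
  if (notch_quality <= 0) {
    stop("configuration error: notch_quality must be positive", call. = FALSE)
  }
  if (filter_order < 1 || filter_order != round(filter_order)) {
    stop("configuration error: filter_order must be a positive integer",
         call. = FALSE)
  }
  structure(
    list(emg_sampling_rate_hz = emg_sampling_rate_hz,
         highpass_cutoff_hz = highpass_cutoff_hz,
         lowpass_cutoff_hz = lowpass_cutoff_hz,
         notch_freq_hz = notch_freq_hz,
         notch_quality = notch_quality,
         filter_order = as.integer(filter_order),
         notch_harmonics = isTRUE(notch_harmonics)),
    class = "filter_chain_spec")
}

# Second-order IIR notch (constrained-pole-zero biquad). Zeros on the unit
# circle at +-w0; pole radius set by the quality factor.
design_notch <- function(freq_hz, fs_hz, quality) {
  w0 <- 2 * pi * freq_hz / fs_hz
  alpha <- sin(w0) / (2 * quality)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Design the digital EMG conditioning filter chain
#'
#' Designs causal IIR filters realizing a `filter_chain_spec`: Butterworth
#' high-pass and low-pass sections plus a biquad notch (and optional
#' harmonic notches). All sections are verified stable at design time.
#'
#' @param spec A [filter_chain_spec()].
#' @return An object of class `filter_chain` holding the coefficient sets.
#' @export
design_filter_chain <- function(spec) {
  if (!inherits(spec, "filter_chain_spec")) {
    spec <- do.call(filter_chain_spec, as.list(spec))
  }
  fs <- spec$emg_sampling_rate_hz
  hp <- signal::butter(spec$filter_order, spec$highpass_cutoff_hz / (fs / 2),
                       type = "high")
  lp <- signal::butter(spec$filter_order, spec$lowpass_cutoff_hz / (fs / 2),
                       type = "low")
  notch_freqs <- spec$notch_freq_hz
  if (spec$notch_harmonics) {
    harmonics <- spec$notch_freq_hz * c(2, 3)
    notch_freqs <- c(notch_freqs, harmonics[harmonics < fs / 2])
  }
  notches <- lapply(notch_freqs, design_notch, fs_hz = fs,
                    quality = spec$notch_quality)
  chain <- structure(
    list(spec = spec,
         sections = c(list(hp = list(b = hp$b, a = hp$a),
                           lp = list(b = lp$b, a = lp$a)),
                      stats::setNames(notches,
                                      paste0("notch_", notch_freqs, "hz")))),
    class = "filter_chain")
  for (s in chain$sections) {
    r <- Mod(polyroot(rev(s$a)))
    if (any(r >= 1)) {
      stop("internal error: designed filter section is unstable", call. = FALSE)
    }
  }
  chain
}

#' Frequency response of a designed filter chain
#'
#' Evaluates the complex frequency response of the full chain (product of
#' the section responses) at the requested frequencies.
#'
#' @param chain A `filter_chain` from [design_filter_chain()].
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return Complex vector of the same length as `freq_hz`.
#' @export
filter_chain_response <- function(chain, freq_hz) {
  stopifnot(inherits(chain, "filter_chain"))
  fs <- chain$spec$emg_sampling_rate_hz
  z <- exp(-1i * 2 * pi * freq_hz / fs)
  h <- rep(1 + 0i, length(freq_hz))
  for (s in chain$sections) {
    num <- outer(z, seq_along(s$b) - 1, `^`) %*% s$b
    den <- outer(z, seq_along(s$a) - 1, `^`) %*% s$a
    h <- h * as.vector(num) / as.vector(den)
  }
  h
}

#' Gain of the filter chain in decibels
#'
#' @inheritParams filter_chain_response
#' @return Numeric vector, 20*log10(|H(f)|).
#' @export
filter_chain_gain_db <- function(chain, freq_hz) {
  20 * log10(Mod(filter_chain_response(chain, freq_hz)))
}

apply_sections <- function(chain, x, zero_phase) {
  for (s in chain$sections) {
    x <- if (zero_phase) {
      signal::filtfilt(s$b, s$a, x)
    } else {
      as.numeric(signal::filter(s$b, s$a, x))
    }
  }
  x
}

#' Apply the conditioning chain to an EMG recording
#'
#' Filters both channels of an [emg_recording()] through the chain's
#' sections in order (high-pass, low-pass, notches). Causal single-pass
#' filtering is the default, matching a real-time front end; zero-phase
#' forward-backward filtering is available for offline batch analysis.
#'
#' @param chain A `filter_chain` from [design_filter_chain()].
#' @param recording An [emg_recording()] sampled at the chain's design rate.
#' @param zero_phase If TRUE, applies each section forward and backward
#'   (no phase distortion, non-causal); the result is flagged in metadata.
#' @return A filtered [emg_recording()] with `filtered = TRUE`.
#' @export
apply_filter_chain <- function(chain, recording, zero_phase = FALSE) {
  stopifnot(inherits(chain, "filter_chain"))
  if (!inherits(recording, "emg_recording")) {
    stop("recording must be an emg_recording", call. = FALSE)
  }
  if (length(recording$vl) == 0) {
    stop("cannot filter an empty recording", call. = FALSE)
  }
  fs_chain <- chain$spec$emg_sampling_rate_hz
  if (abs(recording$sampling_rate_hz - fs_chain) > 1e-9) {
    stop(sprintf(
      "sampling-rate mismatch: recording at %g Hz but chain designed for %g Hz",
      recording$sampling_rate_hz, fs_chain), call. = FALSE)
  }
  out <- recording
  out$vl <- apply_sections(chain, recording$vl, zero_phase)
  out$vm <- apply_sections(chain, recording$vm, zero_phase)
  out$filtered <- TRUE
  out$zero_phase <- isTRUE(zero_phase)
  out
}
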