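#' Two-channel surface EMG recording
#'
#' Container for the vastus lateralis (VL) and vastus medialis (VM) EMG
#' channels of one recording, in volts, uniformly sampled.
#'
#' @param vl,vm Numeric vectors of equal length: the VL and VM channel
#'   samples in volts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param filtered Whether the samples have already passed the conditioning
#'   chain.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(vl, vm, sampling_rate_hz, t0 = 0, filtered = FALSE) {
  vl <- as.numeric(vl)
  vm <- as.numeric(vm)
  if (length(vl) != length(vm)) {
    stop("VL and VM channels must have equal length", call. = FALSE)
  }
  if (length(vl) < 1) {
    stop("an EMG recording needs at least one sample", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  structure(list(vl = vl, vm = vm,
                 sampling_rate_hz = sampling_rate_hz,
                 t0 = t0, filtered = isTRUE(filtered)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x 2 channels (VL, VM) @ %g Hz, %s\n",
              length(x$vl), x$sampling_rate_hz,
              if (x$filtered) "filtered" else "raw"))
  invisible(x)
}

#' Duration of an EMG recording in seconds
#' @param recording An [emg_recording()].
#' @return Duration in seconds (n / fs).
#' @export
emg_duration_s <- function(recording) {
  length(recording$vl) / recording$sampling_rate_hz
}

#' Mean absolute value of an EMG window
#'
#' MAV = (1/N) * sum |x(n)|, the average rectified amplitude — the standard
#' time-domain surface-EMG activation feature.
#'
#' @param window Numeric vector of EMG samples (volts).
#' @return MAV in volts (non-negative scalar).
#' @export
mav <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  mean(abs(window))
}

#' Root mean square of an EMG window
#'
#' RMS = sqrt((1/N) * sum x(n)^2). By the power-mean inequality RMS >= MAV
#' for every window.
#'
#' @param window Numeric vector of EMG samples (volts).
#' @return RMS in volts (non-negative scalar).
#' @export
rms <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  sqrt(mean(window^2))
}

#' Windowed MAV/RMS features of a two-channel EMG recording
#'
#' Tiles the recording with analysis windows starting at `t0` and computes
#' MAV and RMS per channel in each window. A trailing partial window shorter
#' than half the window length is dropped; a longer partial window is kept
#' with its actual sample count.
#'
#' @param recording An [emg_recording()].
#' @param window_s Window length in seconds (default 0.25 s).
#' @param hop_s Hop between window starts in seconds (default = `window_s`,
#'   i.e. non-overlapping).
#' @return A data.frame with one row per window: `window_start_s`,
#'   `window_end_s`, `n_samples`, `mav_vl`, `mav_vm`, `rms_vl`, `rms_vm`.
#' @export
windowed_features <- function(recording, window_s = 0.25, hop_s = window_s) {
  if (!inherits(recording, "emg_recording")) {
    stop("recording must be an emg_recording", call. = FALSE)
  }
  if (window_s <= 0 || hop_s <= 0) {
    stop("window_s and hop_s must be positive", call. = FALSE)
  }
  fs <- recording$sampling_rate_hz
  n <- length(recording$vl)
  win_n <- round(window_s * fs)
  hop_n <- round(hop_s * fs)
  if (win_n < 1 || hop_n < 1) {
    stop("window_s and hop_s must cover at least one sample", call. = FALSE)
  }
  if (n < win_n) {
    stop(sprintf(
      "recording too short: %g s available, at least %g s (one window) required",
      n / fs, win_n / fs), call. = FALSE)
  }
  starts <- seq(1L, n, by = hop_n)
  rows <- lapply(starts, function(i) {
    j <- min(i + win_n - 1L, n)
    len <- j - i + 1L
    if (len < win_n && len < win_n / 2) return(NULL)
    data.frame(
      window_start_s = recording$t0 + (i - 1L) / fs,
      window_end_s = recording$t0 + j / fs,
      n_samples = len,
      mav_vl = mav(recording$vl[i:j]),
      mav_vm = mav(recording$vm[i:j]),
      rms_vl = rms(recording$vl[i:j]),
      rms_vm = rms(recording$vm[i:j]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
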