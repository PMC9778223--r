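#' Configuration of the coupled angle + EMG simulator
#'
#' Describes one simulated knee-extension session: a trapezoidal angle
#' trajectory (rest, rise, sustained hold near the peak, fall) repeated
#' `reps` times, and two surface-EMG channels whose amplitude envelope
#' follows the normalized knee angle. The VL gain must be at least the VM
#' gain: in seated knee extension against an ankle load the vastus
#' lateralis consistently produces the larger surface amplitude.
#'
#' @param seed Integer seed; the same seed and config reproduce the outputs
#'   byte for byte.
#' @param reps Number of extension repetitions (protocol default 5).
#' @param rise_s,hold_s,fall_s Durations of the rise, hold and fall phases
#'   in seconds (defaults 2, 4, 2; the hold matches the prescribed 3-6 s
#'   sustained contraction).
#' @param rest_s Rest between repetitions (and before the first) in
#'   seconds. The clinical protocol rests 1 min; tests may compress this
#'   down to 2 s without changing the signal structure.
#' @param peak_deg Peak extension angle in degrees (default 88; the full
#'   0-90 degree excursion is rarely reached exactly).
#' @param peak_jitter_deg Per-repetition standard deviation of the peak
#'   angle, degrees (0 = perfectly repeatable peaks).
#' @param angle_noise_deg Standard deviation of additive Gaussian angle
#'   sensor noise, degrees.
#' @param emg_gain_vl_v,emg_gain_vm_v Peak EMG envelope per channel, volts.
#'   Defaults 0.19 and 0.13 match the amplitude scale of healthy subjects
#'   performing loaded knee extension.
#' @param envelope_exponent Exponent linking the envelope to the normalized
#'   angle (1 = proportional).
#' @param fatigue_decay_per_s Exponential decay rate of the envelope during
#'   the hold phase, per second (muscle fatigue).
#' @param baseline_noise_v Standard deviation of additive wide-band baseline
#'   noise, volts.
#' @param powerline_amp_v Amplitude of additive 50 Hz power-line
#'   contamination, volts.
#' @param emg_sampling_rate_hz EMG sampling rate (default 2000 Hz).
#' @param angle_sampling_period_s Angle sensor sampling period (default
#'   0.1 s, i.e. a reading every 100 ms).
#' @param activation_lead_s How far the EMG envelope precedes the movement,
#'   seconds (default 0).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              reps = 5L,
                              rise_s = 2, hold_s = 4, fall_s = 2,
                              rest_s = 60,
                              peak_deg = 88,
                              peak_jitter_deg = 0,
                              angle_noise_deg = 0.5,
                              emg_gain_vl_v = 0.19,
                              emg_gain_vm_v = 0.13,
                              envelope_exponent = 1,
                              fatigue_decay_per_s = 0.02,
                              baseline_noise_v = 0.005,
                              powerline_amp_v = 0.01,
                              emg_sampling_rate_hz = 2000,
                              angle_sampling_period_s = 0.1,
                              activation_lead_s = 0) {
  stopifnot(reps >= 0, rise_s > 0, hold_s >= 0, fall_s > 0, rest_s >= 2,
            angle_noise_deg >= 0, peak_jitter_deg >= 0,
            envelope_exponent >= 1, fatigue_decay_per_s >= 0,
            baseline_noise_v >= 0, powerline_amp_v >= 0,
            emg_sampling_rate_hz > 0, angle_sampling_period_s > 0)
  if (!(peak_deg > 10 && peak_deg <= 95)) {
    stop("peak_deg must lie in (10, 95]", call. = FALSE)
  }
  if (!(emg_gain_vl_v >= emg_gain_vm_v && emg_gain_vm_v >= 0)) {
    stop("gains must satisfy emg_gain_vl_v >= emg_gain_vm_v >= 0 ",
         "(VL exceeds VM in loaded knee extension)", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulator presets for typical subject profiles
#'
#' Convenience presets whose gains and variability echo the qualitative
#' contrast between healthy subjects, patients with bone-and-joint
#' problems, and patients with neurodegenerative or brain problems (weaker
#' EMG, less stable peaks). They parameterize the same generative model and
#' make no claim of physiological fidelity.
#'
#' @param profile One of "healthy", "bone_joint", "neuro".
#' @param seed Integer seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A [simulation_config()].
#' @export
subject_preset <- function(profile = c("healthy", "bone_joint", "neuro"),
                           seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    healthy = list(peak_deg = 88, peak_jitter_deg = 0.5, angle_noise_deg = 0.5,
                   emg_gain_vl_v = 0.19, emg_gain_vm_v = 0.13),
    bone_joint = list(peak_deg = 86, peak_jitter_deg = 1.5, angle_noise_deg = 0.8,
                      emg_gain_vl_v = 0.10, emg_gain_vm_v = 0.09),
    neuro = list(peak_deg = 79, peak_jitter_deg = 4, angle_noise_deg = 1.5,
                 emg_gain_vl_v = 0.045, emg_gain_vm_v = 0.035,
                 fatigue_decay_per_s = 0.05))
  do.call(simulation_config, utils::modifyList(base, c(list(seed = seed), list(...))))
}

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's RNG afterwards so simulation never perturbs user randomness.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-repetition phase boundaries (noiseless ground truth).
rep_schedule <- function(config, peaks) {
  cycle <- config$rise_s + config$hold_s + config$fall_s + config$rest_s
  t_start <- config$rest_s + (seq_len(config$reps) - 1) * cycle
  data.frame(index = seq_len(config$reps),
             t_start_s = t_start,
             t_hold_start_s = t_start + config$rise_s,
             t_hold_end_s = t_start + config$rise_s + config$hold_s,
             t_end_s = t_start + config$rise_s + config$hold_s + config$fall_s,
             peak_deg = peaks,
             rom_deg = peaks)
}

# Noiseless trapezoidal angle at arbitrary times.
theta_true_at <- function(t, config, schedule) {
  theta <- numeric(length(t))
  for (k in seq_len(nrow(schedule))) {
    s <- schedule[k, ]
    rising <- t >= s$t_start_s & t < s$t_hold_start_s
    holding <- t >= s$t_hold_start_s & t < s$t_hold_end_s
    falling <- t >= s$t_hold_end_s & t < s$t_end_s
    theta[rising] <- s$peak_deg * (t[rising] - s$t_start_s) / config$rise_s
    theta[holding] <- s$peak_deg
    theta[falling] <- s$peak_deg *
      (1 - (t[falling] - s$t_hold_end_s) / config$fall_s)
  }
  theta
}

#' Simulate the knee-angle trace of one session
#'
#' Generates a trapezoidal angle trajectory repeated `reps` times with
#' additive Gaussian sensor noise, sampled at the angle-sensor rate, plus
#' the exact ground-truth phase boundaries of every repetition.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `trace` (an [angle_trace()]) and
#'   `ground_truth` (a data.frame of per-repetition boundaries, peak and
#'   ROM; zero rows when `reps = 0`).
#' @export
simulate_angle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(config$seed, {
    peaks <- config$peak_deg -
      abs(stats::rnorm(config$reps, 0, config$peak_jitter_deg))
    peaks <- pmin(95, pmax(15, peaks))
    schedule <- rep_schedule(config, peaks)
    total_s <- config$rest_s +
      config$reps * (config$rise_s + config$hold_s + config$fall_s + config$rest_s)
    t <- seq(0, total_s, by = config$angle_sampling_period_s)
    theta <- theta_true_at(t, config, schedule) +
      stats::rnorm(length(t), 0, config$angle_noise_deg)
    list(trace = angle_trace(t, theta), ground_truth = schedule)
  })
}

#' Simulate the two-channel EMG recording of one session
#'
#' Each channel is amplitude-modulated band-limited (20-450 Hz) Gaussian
#' noise: envelope(t) = gain x (theta(t)/peak)^envelope_exponent, decaying
#' exponentially during the hold phase to mimic fatigue, plus wide-band
#' baseline noise and a 50 Hz power-line sinusoid. Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param ground_truth The ground-truth schedule from [simulate_angle()]
#'   (recomputed from `config` if omitted).
#' @return A raw (unfiltered) [emg_recording()].
#' @export
simulate_emg <- function(config, ground_truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(ground_truth)) {
    ground_truth <- simulate_angle(config)$ground_truth
  }
  fs <- config$emg_sampling_rate_hz
  total_s <- config$rest_s +
    config$reps * (config$rise_s + config$hold_s + config$fall_s + config$rest_s)
  t <- seq(0, total_s - 1 / fs, by = 1 / fs)
  theta <- theta_true_at(t + config$activation_lead_s, config, ground_truth)

  # activation envelope, with exponential decay while holding
  norm <- (pmax(theta, 0) / config$peak_deg)^config$envelope_exponent
  fatigue <- rep(1, length(t))
  if (config$fatigue_decay_per_s > 0 && nrow(ground_truth) > 0) {
    for (k in seq_len(nrow(ground_truth))) {
      s <- ground_truth[k, ]
      inhold <- t >= s$t_hold_start_s & t < s$t_hold_end_s
      fatigue[inhold] <- exp(-config$fatigue_decay_per_s *
                               (t[inhold] - s$t_hold_start_s))
      after <- t >= s$t_hold_end_s & t < s$t_end_s
      fatigue[after] <- exp(-config$fatigue_decay_per_s * config$hold_s)
    }
  }

  bp <- signal::butter(4, c(20, min(450, 0.45 * fs)) / (fs / 2), type = "pass")
  channel <- function(gain, carrier_white, base_white) {
    carrier <- as.numeric(signal::filter(bp$b, bp$a, carrier_white))
    carrier <- carrier / stats::sd(carrier)      # unit-variance carrier
    gain * norm * fatigue * carrier +
      config$baseline_noise_v * base_white +
      config$powerline_amp_v * sin(2 * pi * 50 * t)
  }
  with_sim_seed(config$seed + 499979L, {
    n <- length(t)
    vl <- channel(config$emg_gain_vl_v, stats::rnorm(n), stats::rnorm(n))
    vm <- channel(config$emg_gain_vm_v, stats::rnorm(n), stats::rnorm(n))
    emg_recording(vl, vm, fs, t0 = 0, filtered = FALSE)
  })
}

#' Simulate a complete session recording
#'
#' Runs [simulate_angle()] and [simulate_emg()] with a shared ground truth.
#'
#' @param config A [simulation_config()].
#' @return A list with `angle` (an [angle_trace()]), `emg` (an
#'   [emg_recording()]) and `ground_truth` (per-repetition schedule).
#' @export
simulate_recording <- function(config) {
  ang <- simulate_angle(config)
  emg <- simulate_emg(config, ang$ground_truth)
  list(angle = ang$trace, emg = emg, ground_truth = ang$ground_truth)
}
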