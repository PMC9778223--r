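# Shared builders for simulated fixtures. Rest periods are compressed to
# 2 s so a full five-repetition session spans ~52 s instead of ~6 min.

quick_sim <- function(seed = 1, ...) {
  simulation_config(seed = seed, rest_s = 2, ...)
}

# Noiseless single-trapezoid trace: rest, linear rise, flat hold, linear
# fall, rest; sampled at the angle-sensor rate.
trapezoid_trace <- function(peak = 85, rest = 2, rise = 2, hold = 4,
                            fall = 2, dt = 0.1) {
  t <- seq(0, 2 * rest + rise + hold + fall, by = dt)
  theta <- ifelse(t < rest, 0,
           ifelse(t < rest + rise, peak * (t - rest) / rise,
           ifelse(t < rest + rise + hold, peak,
           ifelse(t < rest + rise + hold + fall,
                  peak * (1 - (t - rest - rise - hold) / fall), 0))))
  angle_trace(t, theta)
}

permissive_config <- function(...) {
  session_config(mav_threshold_v = 0.01, rms_threshold_v = 0.01,
                 rom_threshold_deg = 60, ...)
}
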