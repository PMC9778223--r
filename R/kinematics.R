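#' Knee-extension angle trace
#'
#' Time series of the knee-extension angle theta in degrees, sampled by the
#' angle sensor (nominally every 100 ms). 0 degrees is the sitting rest
#' posture, 90 degrees a fully stretched-out knee.
#'
#' @param time_s Strictly increasing numeric vector of sample times (s).
#' @param theta_deg Knee-extension angles in degrees, same length.
#' @return An object of class `angle_trace`.
#' @export
angle_trace <- function(time_s, theta_deg) {
  time_s <- as.numeric(time_s)
  theta_deg <- as.numeric(theta_deg)
  if (length(time_s) != length(theta_deg)) {
    stop("time_s and theta_deg must have equal length", call. = FALSE)
  }
  if (length(time_s) >= 2 && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(theta_deg < -15 | theta_deg > 105)) {
    warning("angle samples outside the [-15, 105] degree operating range; ",
            "check sensor mounting and calibration", call. = FALSE)
  }
  structure(list(time_s = time_s, theta_deg = theta_deg),
            class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> %d samples over %.1f s, theta in [%.1f, %.1f] deg\n",
              length(x$time_s), diff(range(x$time_s)),
              min(x$theta_deg), max(x$theta_deg)))
  invisible(x)
}

#' Knee angle from quasi-static accelerometer tilt
#'
#' Converts 3-axis accelerometer samples (units of g) to the knee-extension
#' angle by tilt sensing: the angle between the measured gravity vector and
#' a reference gravity direction captured in the sitting rest pose (default
#' +z). Valid only while the shank is quasi-static, so each sample's
#' magnitude must be near 1 g.
#'
#' @param time_s Sample times in seconds.
#' @param accel_g Numeric matrix with 3 columns (ax, ay, az) in g, one row
#'   per sample.
#' @param reference_g Gravity direction in the calibration (sitting) pose;
#'   default `c(0, 0, 1)`.
#' @return An [angle_trace()] with angles clipped to [-15, 105] degrees.
#' @export
accel_to_angle <- function(time_s, accel_g, reference_g = c(0, 0, 1)) {
  accel_g <- as.matrix(accel_g)
  if (ncol(accel_g) != 3) stop("accel_g must have 3 columns", call. = FALSE)
  mag <- sqrt(rowSums(accel_g^2))
  if (any(mag < 0.5 | mag > 1.5)) {
    stop("data-quality error: acceleration magnitude outside [0.5, 1.5] g ",
         "(free fall or shaking breaks the quasi-static tilt assumption)",
         call. = FALSE)
  }
  ref <- reference_g / sqrt(sum(reference_g^2))
  cosang <- pmin(1, pmax(-1, (accel_g %*% ref) / mag))
  theta <- as.vector(acos(cosang)) * 180 / pi
  theta <- pmin(105, pmax(-15, theta))
  angle_trace(time_s, theta)
}

#' Extremes of the knee angle over an interval
#'
#' @param trace An [angle_trace()].
#' @param interval Length-2 numeric `c(t_a, t_b)` in seconds; the closed
#'   interval over which to search.
#' @return Named numeric vector `c(theta_max_deg, theta_min_deg)`.
#' @export
extract_extrema <- function(trace, interval = range(trace$time_s)) {
  stopifnot(inherits(trace, "angle_trace"))
  sel <- trace$time_s >= interval[1] & trace$time_s <= interval[2]
  if (sum(sel) < 1) {
    stop("interval contains no samples", call. = FALSE)
  }
  th <- trace$theta_deg[sel]
  c(theta_max_deg = max(th), theta_min_deg = min(th))
}

#' Range of motion from the angle extremes
#'
#' ROM = |theta_max - theta_min|, in degrees. Symmetric in its arguments
#' and non-negative.
#'
#' @param theta_max_deg,theta_min_deg Angle extremes in degrees.
#' @return ROM in degrees.
#' @export
compute_rom <- function(theta_max_deg, theta_min_deg) {
  abs(theta_max_deg - theta_min_deg)
}

#' Detection parameters for the repetition segmenter
#'
#' The detector runs a Schmitt trigger (hysteresis) on a lightly smoothed
#' angle trace: a repetition becomes active when theta rises more than
#' `start_delta_deg` above the resting angle and deactivates when it falls
#' back below `end_delta_deg` above rest. The active core is then extended
#' outward to the nearest local angle minimum so that the repetition
#' interval covers the full rest-to-rest cycle.
#'
#' @param min_rom_deg Repetitions with ROM below this are discarded
#'   (default 10 degrees, the clinical floor for a countable extension).
#' @param start_delta_deg Rise threshold above rest to open a repetition.
#' @param end_delta_deg Fall threshold above rest to close it
#'   (`< start_delta_deg` gives the hysteresis).
#' @param rest_window_s Initial span used to estimate the resting angle
#'   (median of the first `rest_window_s` seconds).
#' @param smooth_s Width of the centred moving-average smoother applied
#'   before thresholding and extrema extraction, seconds.
#' @param sustained_fraction A sample counts as sustained contraction when
#'   theta >= this fraction of the repetition's peak angle.
#' @param boundary_margin_s How far beyond the active core to search for
#'   the bounding local minima.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_rom_deg = 10,
                             start_delta_deg = 10,
                             end_delta_deg = 5,
                             rest_window_s = 2,
                             smooth_s = 0.9,
                             sustained_fraction = 0.9,
                             boundary_margin_s = 3) {
  stopifnot(min_rom_deg >= 0, start_delta_deg > end_delta_deg,
            end_delta_deg > 0, rest_window_s > 0, smooth_s >= 0,
            sustained_fraction > 0, sustained_fraction <= 1,
            boundary_margin_s > 0)
  structure(list(min_rom_deg = min_rom_deg,
                 start_delta_deg = start_delta_deg,
                 end_delta_deg = end_delta_deg,
                 rest_window_s = rest_window_s,
                 smooth_s = smooth_s,
                 sustained_fraction = sustained_fraction,
                 boundary_margin_s = boundary_margin_s),
            class = "detection_params")
}

# Centred moving average with edge shrinking; window forced odd.
smooth_theta <- function(theta, k) {
  if (k <= 1) return(theta)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  n <- length(theta)
  cs <- cumsum(c(0, theta))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect knee-extension repetitions in an angle trace
#'
#' Segments the trace into non-overlapping extension cycles (rest, rise,
#' sustained hold near the peak, fall back to rest) and measures each
#' repetition's angle extremes, ROM, and phase durations.
#'
#' @param trace An [angle_trace()] spanning at least ~2 s.
#' @param params A [detection_params()] list.
#' @return A data.frame with one row per repetition: `index`, `t_start_s`,
#'   `t_peak_s`, `t_end_s`, `theta_max_deg`, `theta_min_deg`, `rom_deg`,
#'   `rise_s`, `sustained_s`, `fall_s`. Zero rows if nothing is detected.
#' @export
detect_repetitions <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "angle_trace"))
  t <- trace$time_s
  n <- length(t)
  empty <- data.frame(index = integer(0), t_start_s = numeric(0),
                      t_peak_s = numeric(0), t_end_s = numeric(0),
                      theta_max_deg = numeric(0), theta_min_deg = numeric(0),
                      rom_deg = numeric(0), rise_s = numeric(0),
                      sustained_s = numeric(0), fall_s = numeric(0))
  if (n < 4 || (t[n] - t[1]) < 2) {
    stop("trace too short to contain a repetition (< 2 s)", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  th <- smooth_theta(trace$theta_deg, round(params$smooth_s / dt))
  rest_sel <- t <= t[1] + params$rest_window_s
  theta_rest <- stats::median(th[rest_sel])
  hi <- theta_rest + params$start_delta_deg
  lo <- theta_rest + params$end_delta_deg

  # Schmitt trigger over samples -> active cores [up, down)
  active <- FALSE
  ups <- integer(0); downs <- integer(0)
  for (i in seq_len(n)) {
    if (!active && th[i] > hi) {
      active <- TRUE; ups <- c(ups, i)
    } else if (active && th[i] < lo) {
      active <- FALSE; downs <- c(downs, i)
    }
  }
  if (active) ups <- ups[-length(ups)]   # incomplete trailing cycle: discard
  if (length(ups) == 0) return(empty)

  margin_n <- max(1L, round(params$boundary_margin_s / dt))
  reps <- vector("list", length(ups))
  for (k in seq_along(ups)) {
    up <- ups[k]; down <- downs[k]
    # bound the outward search by the midpoint of the gap to the neighbour
    prev_lim <- if (k == 1) 1L else floor((downs[k - 1] + up) / 2)
    next_lim <- if (k == length(ups)) n else ceiling((down + ups[k + 1]) / 2)
    a0 <- max(prev_lim, up - margin_n)
    b0 <- min(next_lim, down + margin_n)
    i_start <- a0 + which.min(th[a0:up]) - 1L
    i_end <- down + which.min(th[down:b0]) - 1L
    seg <- i_start:i_end
    theta_max <- max(th[seg])
    theta_min <- min(th[seg])
    i_peak <- seg[which.max(th[seg])]   # first sample attaining the max
    reps[[k]] <- list(i_start = i_start, i_peak = i_peak, i_end = i_end,
                      theta_max = theta_max, theta_min = theta_min)
  }
  rows <- lapply(reps, function(r) {
    rom <- compute_rom(r$theta_max, r$theta_min)
    if (rom < params$min_rom_deg) return(NULL)
    ph <- phase_durations(t, th, r$i_start, r$i_end, r$theta_max,
                          params$sustained_fraction, dt)
    data.frame(t_start_s = t[r$i_start], t_peak_s = t[r$i_peak],
               t_end_s = t[r$i_end],
               theta_max_deg = r$theta_max, theta_min_deg = r$theta_min,
               rom_deg = rom, rise_s = ph["rise_s"],
               sustained_s = ph["sustained_s"], fall_s = ph["fall_s"])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Phase durations within [i_start, i_end]: rise up to the first crossing of
# the sustained threshold, fall after the last, sustained = total time at
# or above it.
phase_durations <- function(t, th, i_start, i_end, theta_max, fraction, dt) {
  thr <- fraction * theta_max
  seg <- i_start:i_end
  above <- which(th[seg] >= thr)
  if (length(above) == 0) {
    return(c(rise_s = t[i_end] - t[i_start], sustained_s = 0, fall_s = 0))
  }
  first <- seg[min(above)]
  last <- seg[max(above)]
  c(rise_s = t[first] - t[i_start],
    sustained_s = length(above) * dt,
    fall_s = t[i_end] - t[last])
}

#' Phase durations of one detected repetition
#'
#' Recomputes the rise / sustained-contraction / fall split of a repetition
#' from the trace it was detected on: rise is the time from the repetition
#' start to the first crossing of the sustained threshold
#' (`sustained_fraction` x peak angle), sustained is the total time spent at
#' or above that threshold, and fall is the time from the last crossing to
#' the repetition end.
#'
#' @param rep_row One row of the data.frame returned by
#'   [detect_repetitions()].
#' @param trace The [angle_trace()] the repetition was detected on.
#' @param params The [detection_params()] used for detection.
#' @return Named numeric vector `c(rise_s, sustained_s, fall_s)`.
#' @export
segment_phases <- function(rep_row, trace, params = detection_params()) {
  stopifnot(inherits(trace, "angle_trace"))
  t <- trace$time_s
  dt <- stats::median(diff(t))
  th <- smooth_theta(trace$theta_deg, round(params$smooth_s / dt))
  i_start <- which.min(abs(t - rep_row$t_start_s))
  i_end <- which.min(abs(t - rep_row$t_end_s))
  phase_durations(t, th, i_start, i_end, rep_row$theta_max_deg,
                  params$sustained_fraction, dt)
}
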