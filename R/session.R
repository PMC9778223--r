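#' Rehabilitation session configuration
#'
#' Encodes one rehabilitation test: the exercise prescription (repetitions
#' per set, hold-duration target, rest, ankle load), the pass/fail target
#' thresholds set by the clinician, and the signal-processing parameters
#' used to evaluate the recording.
#'
#' @param subject_id Opaque subject identifier.
#' @param knee_side "left" or "right".
#' @param reps_per_set Repetitions per set (protocol default 5).
#' @param n_sets Number of sets (default 1).
#' @param hold_target_s Length-2 target interval for the sustained
#'   contraction, seconds (default c(3, 6)). Recorded and reported; does
#'   not gate pass/fail.
#' @param rest_between_reps_s Prescribed rest between repetitions, seconds.
#' @param sandbag_kg Ankle load in kg (typically 0.5, 1.0 or 1.5).
#' @param mav_threshold_v,rms_threshold_v EMG amplitude targets in volts;
#'   either a single value applied to both channels or a named vector
#'   `c(vl = ..., vm = ...)`.
#' @param rom_threshold_deg ROM target in degrees.
#' @param filter_chain A [filter_chain_spec()].
#' @param window_s,hop_s Feature window length and hop, seconds.
#' @param detection A [detection_params()] list.
#' @param strict_comparison If TRUE a value must strictly exceed its
#'   threshold to pass; default FALSE (meeting the target passes).
#' @param channel_rule "both" (default: VL and VM must each meet the EMG
#'   threshold for the family to pass) or "either".
#' @param feature_scope "active" (default: repetition-level EMG features
#'   average the analysis windows inside each repetition interval) or
#'   "trial" (average over the whole recording).
#' @return An object of class `session_config`.
#' @export
session_config <- function(subject_id = "anonymous",
                           knee_side = c("right", "left"),
                           reps_per_set = 5L,
                           n_sets = 1L,
                           hold_target_s = c(3, 6),
                           rest_between_reps_s = 60,
                           sandbag_kg = 1.0,
                           mav_threshold_v = 0.05,
                           rms_threshold_v = 0.07,
                           rom_threshold_deg = 60,
                           filter_chain = filter_chain_spec(),
                           window_s = 0.25,
                           hop_s = window_s,
                           detection = detection_params(),
                           strict_comparison = FALSE,
                           channel_rule = c("both", "either"),
                           feature_scope = c("active", "trial")) {
  knee_side <- match.arg(knee_side)
  channel_rule <- match.arg(channel_rule)
  feature_scope <- match.arg(feature_scope)
  stopifnot(reps_per_set >= 1, n_sets >= 1,
            length(hold_target_s) == 2, hold_target_s[1] < hold_target_s[2],
            rest_between_reps_s >= 0, sandbag_kg > 0,
            window_s > 0, hop_s > 0)
  mav_threshold_v <- expand_threshold(mav_threshold_v, "mav_threshold_v")
  rms_threshold_v <- expand_threshold(rms_threshold_v, "rms_threshold_v")
  if (rom_threshold_deg < 0) {
    stop("configuration error: rom_threshold_deg must be non-negative",
         call. = FALSE)
  }
  if (!inherits(filter_chain, "filter_chain_spec")) {
    filter_chain <- do.call(filter_chain_spec, as.list(filter_chain))
  }
  if (!inherits(detection, "detection_params")) {
    detection <- do.call(detection_params, as.list(detection))
  }
  structure(list(
    subject_id = subject_id, knee_side = knee_side,
    reps_per_set = as.integer(reps_per_set), n_sets = as.integer(n_sets),
    hold_target_s = hold_target_s,
    rest_between_reps_s = rest_between_reps_s, sandbag_kg = sandbag_kg,
    mav_threshold_v = mav_threshold_v, rms_threshold_v = rms_threshold_v,
    rom_threshold_deg = rom_threshold_deg,
    filter_chain = filter_chain, window_s = window_s, hop_s = hop_s,
    detection = detection, strict_comparison = strict_comparison,
    channel_rule = channel_rule, feature_scope = feature_scope),
    class = "session_config")
}

expand_threshold <- function(x, what) {
  if (any(x < 0)) {
    stop(sprintf("configuration error: %s must be non-negative", what),
         call. = FALSE)
  }
  if (length(x) == 1) x <- c(vl = unname(x), vm = unname(x))
  if (!all(c("vl", "vm") %in% names(x))) {
    stop(sprintf("%s must be a single value or named c(vl=, vm=)", what),
         call. = FALSE)
  }
  x[c("vl", "vm")]
}

#' Evaluate session averages against the target thresholds
#'
#' Implements the binary bio-feedback outputs: each target family (MAV,
#' RMS, ROM) yields 1 for passing and 0 for not passing. By default a value
#' meeting its threshold exactly passes, and the EMG families require both
#' the VL and VM channels to meet their thresholds.
#'
#' @param averages Named numeric with `avg_mav_vl`, `avg_mav_vm`,
#'   `avg_rms_vl`, `avg_rms_vm`, `avg_rom_deg` (as produced by
#'   [run_session()]).
#' @param config A [session_config()] carrying the thresholds and
#'   comparison rules.
#' @return Named integer vector `c(mav_pass, rms_pass, rom_pass)`, each 0
#'   or 1.
#' @export
evaluate_targets <- function(averages, config) {
  cmp <- if (isTRUE(config$strict_comparison)) `>` else `>=`
  combine <- if (config$channel_rule == "both") all else any
  mav_ok <- combine(cmp(averages[["avg_mav_vl"]], config$mav_threshold_v[["vl"]]),
                    cmp(averages[["avg_mav_vm"]], config$mav_threshold_v[["vm"]]))
  rms_ok <- combine(cmp(averages[["avg_rms_vl"]], config$rms_threshold_v[["vl"]]),
                    cmp(averages[["avg_rms_vm"]], config$rms_threshold_v[["vm"]]))
  rom_ok <- cmp(averages[["avg_rom_deg"]], config$rom_threshold_deg)
  c(mav_pass = as.integer(mav_ok), rms_pass = as.integer(rms_ok),
    rom_pass = as.integer(rom_ok))
}

#' Run a rehabilitation session evaluation
#'
#' Executes the full monitoring workflow over a synchronized EMG recording
#' and angle trace: conditions the EMG through the configured filter chain,
#' extracts windowed MAV/RMS features, detects extension repetitions in the
#' angle trace, attaches repetition-level features (windows whose midpoint
#' lies inside the repetition interval), averages across repetitions, and
#' compares the averages against the clinician-set targets.
#'
#' @param emg A raw [emg_recording()].
#' @param angle An [angle_trace()] overlapping the EMG in time.
#' @param config A [session_config()].
#' @param stop_time_s Optional early-stop instant in seconds: both inputs
#'   are truncated there and only repetitions completed before it count
#'   (the safety-stop button of a supervised session).
#' @return An object of class `session_result`: `per_rep` (data.frame of
#'   repetitions with their EMG features), `averages`, `pass_flags`,
#'   `completed`, and the echoed `config`.
#' @export
run_session <- function(emg, angle, config, stop_time_s = NULL) {
  stopifnot(inherits(emg, "emg_recording"), inherits(angle, "angle_trace"),
            inherits(config, "session_config"))
  if (!is.null(stop_time_s)) {
    keep_e <- which(emg$t0 + (seq_along(emg$vl) - 1) / emg$sampling_rate_hz
                    <= stop_time_s)
    keep_a <- which(angle$time_s <= stop_time_s)
    if (length(keep_e) == 0 || length(keep_a) < 4) {
      return(empty_session_result(config))
    }
    emg <- emg_recording(emg$vl[keep_e], emg$vm[keep_e],
                         emg$sampling_rate_hz, emg$t0, emg$filtered)
    angle <- angle_trace(angle$time_s[keep_a], angle$theta_deg[keep_a])
  }
  emg_t1 <- emg$t0 + length(emg$vl) / emg$sampling_rate_hz
  if (emg$t0 >= max(angle$time_s) || emg_t1 <= min(angle$time_s)) {
    stop("EMG recording and angle trace do not overlap in time", call. = FALSE)
  }

  chain <- design_filter_chain(config$filter_chain)
  filtered <- apply_filter_chain(chain, emg)
  feats <- windowed_features(filtered, config$window_s, config$hop_s)
  reps <- tryCatch(detect_repetitions(angle, config$detection),
                   error = function(e) NULL)
  if (is.null(reps) || nrow(reps) == 0) {
    return(empty_session_result(config))
  }

  mid <- (feats$window_start_s + feats$window_end_s) / 2
  emg_cols <- c("mav_vl", "mav_vm", "rms_vl", "rms_vm")
  rep_feats <- t(vapply(seq_len(nrow(reps)), function(k) {
    sel <- if (config$feature_scope == "trial") rep(TRUE, nrow(feats))
           else mid >= reps$t_start_s[k] & mid <= reps$t_end_s[k]
    if (!any(sel)) return(rep(NA_real_, 4))
    colMeans(feats[sel, emg_cols, drop = FALSE])
  }, numeric(4)))
  colnames(rep_feats) <- emg_cols
  per_rep <- cbind(reps, as.data.frame(rep_feats))

  averages <- c(
    avg_rom_deg = mean(per_rep$rom_deg),
    avg_mav_vl = mean(per_rep$mav_vl, na.rm = TRUE),
    avg_mav_vm = mean(per_rep$mav_vm, na.rm = TRUE),
    avg_rms_vl = mean(per_rep$rms_vl, na.rm = TRUE),
    avg_rms_vm = mean(per_rep$rms_vm, na.rm = TRUE),
    avg_sustained_s = mean(per_rep$sustained_s))
  structure(list(
    per_rep = per_rep,
    averages = averages,
    pass_flags = evaluate_targets(averages, config),
    completed = nrow(per_rep) == config$reps_per_set * config$n_sets,
    hold_within_target = mean(
      per_rep$sustained_s >= config$hold_target_s[1] &
        per_rep$sustained_s <= config$hold_target_s[2]),
    config = config),
    class = "session_result")
}

empty_session_result <- function(config) {
  structure(list(
    per_rep = data.frame(),
    averages = c(avg_rom_deg = 0, avg_mav_vl = 0, avg_mav_vm = 0,
                 avg_rms_vl = 0, avg_rms_vm = 0, avg_sustained_s = 0),
    pass_flags = c(mav_pass = 0L, rms_pass = 0L, rom_pass = 0L),
    completed = FALSE,
    hold_within_target = NA_real_,
    config = config),
    class = "session_result")
}

#' Stop a session early and keep completed repetitions
#'
#' Equivalent to pressing the safety stop button: evaluates the session on
#' the data recorded up to `stop_time_s`. Only repetitions whose full
#' rest-to-rest cycle finished before the stop instant are counted, and
#' `completed` is FALSE unless the prescribed count was already reached.
#'
#' @inheritParams run_session
#' @param stop_time_s Stop instant in seconds.
#' @return A [run_session()] result (possibly with zero repetitions).
#' @export
early_stop <- function(emg, angle, config, stop_time_s) {
  run_session(emg, angle, config, stop_time_s = stop_time_s)
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> subject %s: %d repetition(s), completed = %s\n",
              x$config$subject_id, nrow(x$per_rep), x$completed))
  if (nrow(x$per_rep) > 0) {
    cat(sprintf("  avg ROM %.1f deg | MAV VL/VM %.4f/%.4f V | RMS VL/VM %.4f/%.4f V\n",
                x$averages[["avg_rom_deg"]],
                x$averages[["avg_mav_vl"]], x$averages[["avg_mav_vm"]],
                x$averages[["avg_rms_vl"]], x$averages[["avg_rms_vm"]]))
  }
  cat(sprintf("  pass flags: MAV=%d RMS=%d ROM=%d\n",
              x$pass_flags[["mav_pass"]], x$pass_flags[["rms_pass"]],
              x$pass_flags[["rom_pass"]]))
  invisible(x)
}
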