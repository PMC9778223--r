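#' @name kneemon-io
#' @title CSV and JSON readers and writers
#' @description
#' All files are UTF-8, comma-separated, with a mandatory header row.
#' Malformed inputs raise named parse errors rather than returning partial
#' data. Numeric round trips preserve 6 decimal places.
NULL

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("parse error in ", path, ": file is empty", call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  }
  for (col in required) {
    if (col %in% c("subject_id", "group_label", "week_label")) next
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0) {
      stop("parse error in ", path, ": non-numeric value in column '", col,
           "' at data row ", bad[1], call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a two-channel EMG recording from CSV
#'
#' Expects columns `time_s`, `emg_vl_v`, `emg_vm_v`. The sampling rate is
#' inferred from the median time step, which must be uniform to 1%.
#'
#' @param path CSV file path.
#' @return An [emg_recording()].
#' @export
load_emg_csv <- function(path) {
  df <- read_csv_checked(path, c("time_s", "emg_vl_v", "emg_vm_v"))
  if (nrow(df) < 2) {
    stop("parse error in ", path, ": need at least 2 samples", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("parse error in ", path, ": time_s must increase uniformly",
         call. = FALSE)
  }
  emg_recording(df$emg_vl_v, df$emg_vm_v,
                sampling_rate_hz = 1 / stats::median(dt),
                t0 = df$time_s[1])
}

#' Write an EMG recording to CSV
#' @param recording An [emg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(recording, path) {
  t <- recording$t0 + (seq_along(recording$vl) - 1) / recording$sampling_rate_hz
  df <- data.frame(time_s = round(t, 6),
                   emg_vl_v = round(recording$vl, 6),
                   emg_vm_v = round(recording$vm, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a knee-angle trace from CSV
#'
#' Auto-detects the input form by header: either a pre-fused angle
#' (`time_s`, `theta_deg`) or raw 3-axis accelerometer samples (`time_s`,
#' `ax_g`, `ay_g`, `az_g`), which are converted via [accel_to_angle()].
#'
#' @param path CSV file path.
#' @return An [angle_trace()].
#' @export
load_angle_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("parse error in ", path, ": file is empty", call. = FALSE)
  }
  header <- names(utils::read.csv(path, nrows = 1))
  if (all(c("time_s", "theta_deg") %in% header)) {
    df <- read_csv_checked(path, c("time_s", "theta_deg"))
    angle_trace(df$time_s, df$theta_deg)
  } else if (all(c("time_s", "ax_g", "ay_g", "az_g") %in% header)) {
    df <- read_csv_checked(path, c("time_s", "ax_g", "ay_g", "az_g"))
    accel_to_angle(df$time_s, as.matrix(df[, c("ax_g", "ay_g", "az_g")]))
  } else {
    stop("parse error in ", path,
         ": expected columns time_s,theta_deg or time_s,ax_g,ay_g,az_g",
         call. = FALSE)
  }
}

#' Write an angle trace to CSV
#' @param trace An [angle_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(trace, path) {
  df <- data.frame(time_s = round(trace$time_s, 6),
                   theta_deg = round(trace$theta_deg, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_json_keys <- c(
  "subject_id", "knee_side", "reps_per_set", "n_sets", "hold_target_s",
  "rest_between_reps_s", "sandbag_kg", "mav_threshold_v", "rms_threshold_v",
  "rom_threshold_deg", "filter_chain", "window_s", "hop_s", "detection",
  "strict_comparison", "channel_rule", "feature_scope")

#' Read a session configuration from JSON
#'
#' Keys map one-to-one onto [session_config()] arguments; a `filter_chain`
#' object maps onto [filter_chain_spec()] and a `detection` object onto
#' [detection_params()]. Unknown keys are rejected by name so that
#' misspelled settings never silently fall back to defaults.
#'
#' @param path JSON file path.
#' @return A [session_config()].
#' @export
load_config_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  unknown <- setdiff(names(raw), config_json_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$filter_chain)) {
    raw$filter_chain <- do.call(filter_chain_spec, as.list(raw$filter_chain))
  }
  if (!is.null(raw$detection)) {
    raw$detection <- do.call(detection_params, as.list(raw$detection))
  }
  for (k in c("mav_threshold_v", "rms_threshold_v")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(session_config, raw)
}

#' Write a session configuration to JSON
#' @param config A [session_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  x <- unclass(config)
  x$filter_chain <- unclass(x$filter_chain)
  x$detection <- unclass(x$detection)
  # named vectors must stay keyed in JSON
  x$mav_threshold_v <- as.list(x$mav_threshold_v)
  x$rms_threshold_v <- as.list(x$rms_threshold_v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an evaluated session to disk
#'
#' Writes `session_result.csv` (per-repetition rows followed by a summary
#' row holding the session averages) and `session_result.json` (the full
#' structure). Output is deterministic: identical results produce
#' byte-identical files.
#'
#' @param result A [run_session()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_session_result <- function(result, dir) {
  stopifnot(inherits(result, "session_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "session_result.csv")
  json_path <- file.path(dir, "session_result.json")
  num_cols <- c("t_start_s", "t_peak_s", "t_end_s", "theta_max_deg",
                "theta_min_deg", "rom_deg", "rise_s", "sustained_s", "fall_s",
                "mav_vl", "mav_vm", "rms_vl", "rms_vm")
  if (nrow(result$per_rep) > 0) {
    per_rep <- result$per_rep
    per_rep[num_cols] <- lapply(per_rep[num_cols], round, 6)
    summary_row <- data.frame(index = NA_integer_,
      t_start_s = NA, t_peak_s = NA, t_end_s = NA,
      theta_max_deg = NA, theta_min_deg = NA,
      rom_deg = round(result$averages[["avg_rom_deg"]], 6),
      rise_s = NA,
      sustained_s = round(result$averages[["avg_sustained_s"]], 6),
      fall_s = NA,
      mav_vl = round(result$averages[["avg_mav_vl"]], 6),
      mav_vm = round(result$averages[["avg_mav_vm"]], 6),
      rms_vl = round(result$averages[["avg_rms_vl"]], 6),
      rms_vm = round(result$averages[["avg_rms_vm"]], 6))
    out <- rbind(cbind(row_type = "repetition", per_rep),
                 cbind(row_type = "average", summary_row))
  } else {
    out <- data.frame(row_type = character(0))
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE, na = "")
  payload <- list(
    subject_id = result$config$subject_id,
    completed = result$completed,
    n_repetitions = nrow(result$per_rep),
    averages = as.list(round(result$averages, 6)),
    pass_flags = as.list(result$pass_flags),
    hold_within_target = result$hold_within_target,
    per_rep = result$per_rep)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Write subject summaries to CSV
#' @param summaries A data.frame of [summarize_subject()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  df <- as.data.frame(summaries)
  df[summary_value_cols] <- lapply(df[summary_value_cols], round, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject summaries from CSV
#' @param path CSV path as written by [write_summary_csv()].
#' @return A data.frame of subject summary rows.
#' @export
read_summary_csv <- function(path) {
  read_csv_checked(path, c("subject_id", "group_label", "week_label",
                           summary_value_cols))
}
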