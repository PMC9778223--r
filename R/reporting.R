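#' Summarize a subject's sessions
#'
#' Collapses one or more evaluated sessions into a single per-subject
#' summary row: the arithmetic mean of each session's average ROM, MAV and
#' RMS values. This is the row shape used in per-subject result tables
#' (one average ROM plus VL/VM MAV and RMS columns).
#'
#' @param results A [run_session()] result or a list of them; at least one
#'   must contain repetitions.
#' @param subject_id Subject identifier.
#' @param group_label One of "healthy", "bone_joint", "neuro".
#' @param week_label One of "first", "middle", "last", "single".
#' @return A one-row data.frame of class `subject_summary` with columns
#'   `subject_id`, `group_label`, `week_label`, `avg_rom_deg`, `mav_vl_v`,
#'   `mav_vm_v`, `rms_vl_v`, `rms_vm_v`.
#' @export
summarize_subject <- function(results, subject_id,
                              group_label = c("healthy", "bone_joint", "neuro"),
                              week_label = c("single", "first", "middle", "last")) {
  group_label <- match.arg(group_label)
  week_label <- match.arg(week_label)
  if (inherits(results, "session_result")) results <- list(results)
  results <- Filter(function(r) nrow(r$per_rep) > 0, results)
  if (length(results) == 0) {
    stop("summarize_subject needs at least one session with repetitions",
         call. = FALSE)
  }
  avgs <- t(vapply(results, function(r) r$averages[
    c("avg_rom_deg", "avg_mav_vl", "avg_mav_vm", "avg_rms_vl", "avg_rms_vm")],
    numeric(5)))
  m <- colMeans(avgs)
  out <- data.frame(subject_id = subject_id, group_label = group_label,
                    week_label = week_label,
                    avg_rom_deg = m[["avg_rom_deg"]],
                    mav_vl_v = m[["avg_mav_vl"]], mav_vm_v = m[["avg_mav_vm"]],
                    rms_vl_v = m[["avg_rms_vl"]], rms_vm_v = m[["avg_rms_vm"]])
  class(out) <- c("subject_summary", class(out))
  out
}

summary_value_cols <- c("avg_rom_deg", "mav_vl_v", "mav_vm_v",
                        "rms_vl_v", "rms_vm_v")

#' Aggregate subject summaries into a group summary
#'
#' Fieldwise arithmetic means over the subjects of one group and week, with
#' the member count. All rows must share the same `group_label` and
#' `week_label`.
#'
#' @param summaries A data.frame of subject summaries (rows from
#'   [summarize_subject()] or [read_summary_csv()]).
#' @param pooled_label Optional label that pools subjects across group
#'   labels (e.g. all patients regardless of diagnosis group); when given,
#'   only `week_label` must be homogeneous.
#' @return A one-row data.frame of class `group_summary` with columns
#'   `group_label`, `week_label`, `n_subjects`, `mean_rom_deg`,
#'   `mean_mav_vl_v`, `mean_mav_vm_v`, `mean_rms_vl_v`, `mean_rms_vm_v`.
#' @export
aggregate_group <- function(summaries, pooled_label = NULL) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0) {
    stop("aggregate_group needs at least one subject summary", call. = FALSE)
  }
  missing <- setdiff(c("group_label", "week_label", summary_value_cols),
                     names(summaries))
  if (length(missing) > 0) {
    stop("summaries are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(summaries$week_label)) != 1) {
    stop("mixed week_label: aggregate one week at a time", call. = FALSE)
  }
  if (is.null(pooled_label) && length(unique(summaries$group_label)) != 1) {
    stop("mixed group_label: aggregate one group at a time, ",
         "or set pooled_label to pool across groups", call. = FALSE)
  }
  out <- data.frame(group_label = if (is.null(pooled_label))
                      summaries$group_label[1] else pooled_label,
                    week_label = summaries$week_label[1],
                    n_subjects = nrow(summaries),
                    mean_rom_deg = mean(summaries$avg_rom_deg),
                    mean_mav_vl_v = mean(summaries$mav_vl_v),
                    mean_mav_vm_v = mean(summaries$mav_vm_v),
                    mean_rms_vl_v = mean(summaries$rms_vl_v),
                    mean_rms_vm_v = mean(summaries$rms_vm_v))
  class(out) <- c("group_summary", class(out))
  out
}

#' Week-over-week progress between two summaries
#'
#' Computes per-field deltas (last minus first) between two summaries of
#' the same entity — either two [summarize_subject()] rows of one subject
#' or two [aggregate_group()] rows of one group — and classifies each delta
#' as improved, unchanged or declined. Deltas within a dead band (default
#' 0.001 V for EMG amplitudes, 0.1 degree for ROM) count as unchanged: at
#' the reported measurement precision such differences are not meaningful.
#'
#' @param first,last Two summaries of the same kind and entity, from
#'   different weeks.
#' @param band_v Dead band for MAV/RMS deltas, volts.
#' @param band_deg Dead band for ROM deltas, degrees.
#' @return A data.frame with one row per field: `field`, `first`, `last`,
#'   `delta`, `direction`.
#' @export
progress_report <- function(first, last, band_v = 0.001, band_deg = 0.1) {
  is_group <- inherits(first, "group_summary")
  if (is_group != inherits(last, "group_summary")) {
    stop("cannot compare a subject summary with a group summary", call. = FALSE)
  }
  key <- if (is_group) "group_label" else "subject_id"
  if (first[[key]] != last[[key]]) {
    stop(sprintf("mismatched entities: %s '%s' vs '%s'", key,
                 first[[key]], last[[key]]), call. = FALSE)
  }
  if (first$week_label == last$week_label &&
      !identical(first$week_label, "single")) {
    warning("comparing two summaries from the same week", call. = FALSE)
  }
  cols <- if (is_group) {
    c("mean_rom_deg", "mean_mav_vl_v", "mean_mav_vm_v",
      "mean_rms_vl_v", "mean_rms_vm_v")
  } else {
    summary_value_cols
  }
  band <- ifelse(grepl("rom", cols), band_deg, band_v)
  delta <- as.numeric(last[1, cols]) - as.numeric(first[1, cols])
  direction <- ifelse(abs(delta) <= band + 1e-9, "unchanged",
                      ifelse(delta > 0, "improved", "declined"))
  data.frame(field = cols,
             first = as.numeric(first[1, cols]),
             last = as.numeric(last[1, cols]),
             delta = delta, direction = direction)
}

#' Published per-subject reference summaries
#'
#' Loads the bundled per-subject average ROM / MAV / RMS table: six healthy
#' subjects (single test day) and six patients measured in the first and
#' last week of a one-month rehabilitation period, split into a
#' bone-and-joint group and a neurodegenerative/brain group. These are
#' device measurements on real subjects, shipped for aggregation and
#' progress-report examples and tests.
#'
#' @return A data.frame in [summarize_subject()] row format.
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "reference_subject_summaries.csv",
                      package = "kneemon", mustWork = TRUE)
  read_summary_csv(path)
}

#' @describeIn progress_report Plain-text rendering of a progress report.
#' @param report A data.frame from [progress_report()].
#' @param label Heading for the rendered block.
#' @export
render_report <- function(report, label = "Progress") {
  lines <- c(sprintf("%s (last - first):", label),
             sprintf("  %-14s %9.4f -> %9.4f  delta %+8.4f  [%s]",
                     report$field, report$first, report$last,
                     report$delta, report$direction))
  paste(lines, collapse = "\n")
}
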