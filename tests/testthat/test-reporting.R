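# Equality at the precision a table cell is printed with (round half to even).
expect_printed <- function(computed, printed) {
  dp <- nchar(sub("^[^.]*\\.?", "", as.character(printed)))
  expect_equal(round(computed, dp), printed)
}

test_that("group aggregation reproduces the published group-table cells", {
  ref <- reference_summaries()
  a_first <- aggregate_group(ref[ref$group_label == "bone_joint" &
                                   ref$week_label == "first", ])
  expect_printed(a_first$mean_rom_deg, 85.5)
  expect_printed(a_first$mean_mav_vl_v, 0.072333)
  expect_printed(a_first$mean_mav_vm_v, 0.069333)
  expect_printed(a_first$mean_rms_vl_v, 0.103333)
  expect_printed(a_first$mean_rms_vm_v, 0.098667)
  expect_equal(a_first$n_subjects, 3)

  b_first <- aggregate_group(ref[ref$group_label == "neuro" &
                                   ref$week_label == "first", ])
  expect_printed(b_first$mean_rom_deg, 78.7)
  expect_printed(b_first$mean_mav_vl_v, 0.037)
  expect_printed(b_first$mean_mav_vm_v, 0.028333)

  a_last <- aggregate_group(ref[ref$group_label == "bone_joint" &
                                  ref$week_label == "last", ])
  expect_printed(a_last$mean_rom_deg, 87.16667)
  expect_printed(a_last$mean_mav_vl_v, 0.091333)
  expect_printed(a_last$mean_rms_vl_v, 0.133)
  expect_printed(a_last$mean_rms_vm_v, 0.123667)

  b_last <- aggregate_group(ref[ref$group_label == "neuro" &
                                  ref$week_label == "last", ])
  expect_printed(b_last$mean_rom_deg, 81.46667)
  expect_printed(b_last$mean_mav_vm_v, 0.037667)

  healthy <- aggregate_group(ref[ref$group_label == "healthy", ])
  expect_printed(healthy$mean_rom_deg, 87.73333)
  expect_printed(healthy$mean_mav_vl_v, 0.136167)
  expect_printed(healthy$mean_mav_vm_v, 0.09)
  expect_printed(healthy$mean_rms_vl_v, 0.198)
  expect_printed(healthy$mean_rms_vm_v, 0.127333)

  pat <- ref[ref$group_label != "healthy", ]
  all_first <- aggregate_group(pat[pat$week_label == "first", ],
                               pooled_label = "patients")
  expect_printed(all_first$mean_rom_deg, 82.1)
  expect_printed(all_first$mean_mav_vl_v, 0.054667)
  expect_printed(all_first$mean_rms_vm_v, 0.0705)
  all_last <- aggregate_group(pat[pat$week_label == "last", ],
                              pooled_label = "patients")
  expect_printed(all_last$mean_rom_deg, 84.31667)
  expect_printed(all_last$mean_mav_vl_v, 0.078167)
})

test_that("aggregation is permutation invariant and label checked", {
  ref <- reference_summaries()
  grp <- ref[ref$group_label == "neuro" & ref$week_label == "first", ]
  set.seed(2)
  shuffled <- grp[sample(nrow(grp)), ]
  expect_equal(aggregate_group(grp), aggregate_group(shuffled),
               ignore_attr = TRUE)
  expect_error(aggregate_group(ref), "mixed")
  single <- aggregate_group(grp[1, ])
  expect_equal(single$mean_rom_deg, grp$avg_rom_deg[1])
  expect_error(aggregate_group(grp[0, ]), "at least one")
})

test_that("progress reports reproduce the published week-over-week deltas", {
  ref <- reference_summaries()
  a_first <- aggregate_group(ref[ref$group_label == "bone_joint" &
                                   ref$week_label == "first", ])
  a_last <- aggregate_group(ref[ref$group_label == "bone_joint" &
                                  ref$week_label == "last", ])
  pr <- progress_report(a_first, a_last)
  rom <- pr[pr$field == "mean_rom_deg", ]
  expect_equal(rom$delta, 87.16667 - 85.5, tolerance = 1e-5)
  expect_equal(rom$direction, "improved")

  # patient 2's VM amplitudes barely move: inside the dead band
  p2 <- ref[ref$subject_id == "P2", ]
  pr2 <- progress_report(p2[p2$week_label == "first", ],
                         p2[p2$week_label == "last", ])
  vm_mav <- pr2[pr2$field == "mav_vm_v", ]
  expect_equal(vm_mav$delta, -0.001)
  expect_equal(vm_mav$direction, "unchanged")
  expect_equal(pr2[pr2$field == "mav_vl_v", "direction"], "improved")

  # antisymmetry and the degenerate identical comparison
  rev <- progress_report(a_last, a_first)
  expect_equal(rev$delta, -pr$delta)
  same <- suppressWarnings(progress_report(a_first, a_first))
  expect_true(all(same$delta == 0) && all(same$direction == "unchanged"))

  expect_error(progress_report(a_first,
                               aggregate_group(ref[ref$group_label == "neuro" &
                                                     ref$week_label == "last", ])),
               "mismatched")
  expect_error(progress_report(a_first, p2[1, ]), "cannot compare")
})

test_that("subject summaries average their sessions", {
  rec <- simulate_recording(quick_sim(seed = 31))
  res <- run_session(rec$emg, rec$angle, permissive_config())
  one <- summarize_subject(res, "S1", "healthy", "single")
  expect_equal(one$avg_rom_deg, res$averages[["avg_rom_deg"]])
  expect_equal(one$mav_vl_v, res$averages[["avg_mav_vl"]])

  rec2 <- simulate_recording(quick_sim(seed = 32))
  res2 <- run_session(rec2$emg, rec2$angle, permissive_config())
  two <- summarize_subject(list(res, res2), "S1", "healthy", "single")
  expect_equal(two$avg_rom_deg,
               (res$averages[["avg_rom_deg"]] + res2$averages[["avg_rom_deg"]]) / 2)

  expect_error(summarize_subject(list(), "S1"), "at least one")
})

test_that("CSV and JSON round trips preserve values", {
  tmp <- tempfile(fileext = ".csv")
  ref <- reference_summaries()
  write_summary_csv(ref, tmp)
  back <- read_summary_csv(tmp)
  expect_equal(back$avg_rom_deg, ref$avg_rom_deg)
  expect_equal(back$mav_vl_v, ref$mav_vl_v, tolerance = 1e-6)

  rec <- simulate_recording(quick_sim(seed = 41, reps = 1))
  ep <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
  write_emg_csv(rec$emg, ep)
  write_angle_csv(rec$angle, ap)
  emg2 <- load_emg_csv(ep)
  ang2 <- load_angle_csv(ap)
  expect_equal(emg2$sampling_rate_hz, rec$emg$sampling_rate_hz, tolerance = 1e-6)
  expect_lt(max(abs(emg2$vl - rec$emg$vl)), 1e-6)
  expect_lt(max(abs(ang2$theta_deg - rec$angle$theta_deg)), 1e-6)

  cfgp <- tempfile(fileext = ".json")
  write_config_json(session_config(subject_id = "S9", rom_threshold_deg = 75), cfgp)
  cfg2 <- load_config_json(cfgp)
  expect_equal(cfg2$subject_id, "S9")
  expect_equal(cfg2$rom_threshold_deg, 75)
  expect_s3_class(cfg2$filter_chain, "filter_chain_spec")
})

test_that("raw accelerometer angle CSVs are auto-detected", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("time_s,ax_g,ay_g,az_g",
               "0,0,0,1",
               "0.1,0.70710678,0,0.70710678",
               "0.2,1,0,0"), tmp)
  tr <- load_angle_csv(tmp)
  expect_equal(tr$theta_deg, c(0, 45, 90), tolerance = 1e-6)
})

test_that("malformed inputs raise named parse errors", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("time_s,emg_vl_v", "0,0.1"), tmp)
  expect_error(load_emg_csv(tmp), "missing column\\(s\\) emg_vm_v")

  file.create(empty <- tempfile(fileext = ".csv"))
  expect_error(load_emg_csv(empty), "empty")
  expect_error(load_angle_csv(empty), "empty")

  writeLines(c("time_s,theta_deg", "0,ten"), bad <- tempfile(fileext = ".csv"))
  expect_error(load_angle_csv(bad), "non-numeric value in column 'theta_deg'")

  writeLines('{"subject_id": "x", "bogus_key": 1}',
             badcfg <- tempfile(fileext = ".json"))
  expect_error(load_config_json(badcfg), "unknown configuration key.*bogus_key")
})

test_that("session results render to stable CSV/JSON artifacts", {
  rec <- simulate_recording(quick_sim(seed = 51))
  res <- run_session(rec$emg, rec$angle, permissive_config(subject_id = "S3"))
  paths <- write_session_result(res, file.path(tempdir(), "sess"))
  csv <- utils::read.csv(paths[["csv"]])
  expect_equal(sum(csv$row_type == "repetition"), 5)
  expect_equal(sum(csv$row_type == "average"), 1)
  avg_row <- csv[csv$row_type == "average", ]
  expect_equal(avg_row$rom_deg, round(res$averages[["avg_rom_deg"]], 6))
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_true(js$completed)
  expect_equal(js$n_repetitions, 5)

  txt <- render_report(progress_report(
    summarize_subject(res, "S3", "healthy", "first"),
    summarize_subject(res, "S3", "healthy", "last")))
  expect_match(txt, "avg_rom_deg")
  expect_match(txt, "unchanged")
})
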