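sim_fixture <- function(seed = 1) simulate_recording(quick_sim(seed = seed))

test_that("attainable thresholds pass and unattainable ones fail", {
  rec <- sim_fixture()
  res <- run_session(rec$emg, rec$angle, permissive_config())
  expect_true(res$completed)
  expect_equal(nrow(res$per_rep), 5)
  expect_equal(unname(res$pass_flags), c(1L, 1L, 1L))

  hard <- session_config(mav_threshold_v = 0.01, rms_threshold_v = 0.01,
                         rom_threshold_deg = 120)
  res2 <- run_session(rec$emg, rec$angle, hard)
  expect_equal(res2$pass_flags[["rom_pass"]], 0L)
  expect_equal(res2$pass_flags[["mav_pass"]], 1L)

  impossible <- session_config(mav_threshold_v = 10, rms_threshold_v = 10,
                               rom_threshold_deg = 120)
  expect_equal(unname(run_session(rec$emg, rec$angle, impossible)$pass_flags),
               c(0L, 0L, 0L))
})

test_that("session averages recompute exactly from per-repetition rows", {
  rec <- sim_fixture(2)
  res <- run_session(rec$emg, rec$angle, permissive_config())
  expect_equal(res$averages[["avg_rom_deg"]], mean(res$per_rep$rom_deg))
  expect_equal(res$averages[["avg_mav_vl"]], mean(res$per_rep$mav_vl))
  expect_equal(res$averages[["avg_mav_vm"]], mean(res$per_rep$mav_vm))
  expect_equal(res$averages[["avg_rms_vl"]], mean(res$per_rep$rms_vl))
  expect_equal(res$averages[["avg_rms_vm"]], mean(res$per_rep$rms_vm))
})

test_that("tie, conjunction and strictness rules behave as documented", {
  avgs <- c(avg_rom_deg = 60, avg_mav_vl = 0.05, avg_mav_vm = 0.05,
            avg_rms_vl = 0.07, avg_rms_vm = 0.07)
  cfg <- session_config()   # thresholds exactly at these values
  expect_equal(unname(evaluate_targets(avgs, cfg)), c(1L, 1L, 1L))

  strict <- session_config(strict_comparison = TRUE)
  expect_equal(unname(evaluate_targets(avgs, strict)), c(0L, 0L, 0L))

  zeros <- c(avg_rom_deg = 0, avg_mav_vl = 0, avg_mav_vm = 0,
             avg_rms_vl = 0, avg_rms_vm = 0)
  expect_equal(unname(evaluate_targets(zeros, cfg)), c(0L, 0L, 0L))

  # VL above, VM below: family fails under "both", passes under "either"
  mixed <- c(avg_rom_deg = 90, avg_mav_vl = 0.2, avg_mav_vm = 0.01,
             avg_rms_vl = 0.2, avg_rms_vm = 0.01)
  expect_equal(evaluate_targets(mixed, cfg)[["mav_pass"]], 0L)
  either <- session_config(channel_rule = "either")
  expect_equal(evaluate_targets(mixed, either)[["mav_pass"]], 1L)

  expect_error(session_config(mav_threshold_v = -1), "non-negative")
})

test_that("pass flags are monotone non-increasing in the thresholds", {
  rec <- sim_fixture(3)
  flags <- vapply(c(10, 60, 85, 88.3, 120), function(thr) {
    cfg <- session_config(mav_threshold_v = 0.001, rms_threshold_v = 0.001,
                          rom_threshold_deg = thr)
    run_session(rec$emg, rec$angle, cfg)$pass_flags[["rom_pass"]]
  }, integer(1))
  expect_true(all(diff(flags) <= 0))
})

test_that("truncated input yields an incomplete session", {
  rec <- sim_fixture(4)
  cut <- rec$ground_truth$t_end_s[3] + 1.5   # during the rest after rep 3
  res <- run_session(rec$emg, rec$angle, permissive_config(),
                     stop_time_s = cut)
  expect_false(res$completed)
  expect_equal(nrow(res$per_rep), 3)
})

test_that("early stop keeps only fully completed repetitions", {
  rec <- sim_fixture(5)
  cfg <- permissive_config()

  before <- early_stop(rec$emg, rec$angle, cfg, stop_time_s = 1)
  expect_false(before$completed)
  expect_equal(nrow(before$per_rep), 0)
  expect_equal(unname(before$pass_flags), c(0L, 0L, 0L))

  mid3 <- (rec$ground_truth$t_hold_start_s[3] +
             rec$ground_truth$t_hold_end_s[3]) / 2
  partial <- early_stop(rec$emg, rec$angle, cfg, stop_time_s = mid3)
  expect_false(partial$completed)
  expect_equal(nrow(partial$per_rep), 2)

  after <- early_stop(rec$emg, rec$angle, cfg,
                      stop_time_s = max(rec$angle$time_s) + 1)
  full <- run_session(rec$emg, rec$angle, cfg)
  expect_equal(after$per_rep, full$per_rep)
  expect_equal(after$completed, full$completed)
})

test_that("identical inputs produce byte-identical result files", {
  rec <- sim_fixture(6)
  cfg <- permissive_config(subject_id = "S1")
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  write_session_result(run_session(rec$emg, rec$angle, cfg), d1)
  write_session_result(run_session(rec$emg, rec$angle, cfg), d2)
  for (f in c("session_result.csv", "session_result.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("disjoint EMG and angle streams are rejected", {
  rec <- sim_fixture(7)
  late <- angle_trace(rec$angle$time_s + 1e5, rec$angle$theta_deg)
  expect_error(run_session(rec$emg, late, permissive_config()),
               "do not overlap")
})

test_that("hold-duration attainment is reported but does not gate passing", {
  rec <- sim_fixture(8)   # 4 s holds within the 3-6 s target
  res <- run_session(rec$emg, rec$angle, permissive_config())
  expect_gte(res$hold_within_target, 0.8)
  expect_equal(unname(res$pass_flags), c(1L, 1L, 1L))
})
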