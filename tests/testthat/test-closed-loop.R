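test_that("control runs auto-complete and respect the gating contract", {
  set.seed(61)
  cfg <- closed_loop_config()
  res <- simulate_run(virtual_participant(), "CT", cfg, n_trials = 8)
  run <- res$run
  expect_equal(nrow(run$trials), 8L)
  # interval rule, with one processing block of quantization slack
  expect_true(all(diff(run$events$time_s) >=
                    cfg$trigger$min_interval_s - cfg$signal$block_s))
  # stimulation only ever fired with the background inside the target range
  expect_true(all(run$trials$background >= cfg$trigger$target_range$low))
  expect_true(all(run$trials$background <= cfg$trigger$target_range$high))
  # the loopback channel marks every stimulus at its event frame
  expect_true(all(run$signals["trigger_loopback", run$events$frame] ==
                    cfg$sim$loopback_amplitude_mV))
  # trials are consecutively numbered with strictly increasing times
  expect_equal(run$events$trial_index, 1:8)
  expect_true(all(diff(run$events$time_s) > 0))
})

test_that("identical seeds give identical persisted runs", {
  cfg <- closed_loop_config()
  plan <- data.frame(mode = "CT", trials = 3)
  a <- run_closed_loop(virtual_participant(), plan, cfg, seed = 71)
  b <- run_closed_loop(virtual_participant(), plan, cfg, seed = 71)
  ra <- a$sessions[[1]]$runs[[1]]
  rb <- b$sessions[[1]]$runs[[1]]
  expect_identical(ra$signals, rb$signals)
  expect_identical(ra$trials, rb$trials)
  expect_identical(ra$events, rb$events)
})

test_that("the chunked engine matches one-shot offline reprocessing", {
  # the background trace stored live, block by block with carried state,
  # must equal re-filtering the whole persisted recording in one pass
  set.seed(62)
  cfg <- closed_loop_config()
  run <- simulate_run(virtual_participant(), "CT", cfg, n_trials = 3)$run
  offline <- background_level(sample_block(run$signals, run$sample_rate,
                                           run$channel_roles), cfg$signal)
  expect_lt(max(abs(offline$target$levels - run$background$levels)), 1e-9)
})

test_that("training runs require a criterion and reinforce the participant", {
  cfg <- closed_loop_config()
  expect_error(simulate_run(virtual_participant(), "TT", cfg, n_trials = 5),
               "criterion")
  set.seed(63)
  p <- virtual_participant(plasticity_rate = 0.01)
  crit <- criterion_from_distribution(rlnorm(50, log(2.7), 0.15), 66, "down")
  res <- simulate_run(p, "TT", cfg, n_trials = 10, criterion = crit)
  expect_equal(nrow(res$run$trials), 10L)
  expect_false(anyNA(res$run$trials$success))
  n_succ <- sum(res$run$trials$success)
  expect_equal(res$participant$h_excitability, 0.99^n_succ,
               tolerance = 1e-12)
})

test_that("the M-wave stays within stability tolerance at fixed intensity", {
  set.seed(64)
  p <- virtual_participant()
  cfg <- closed_loop_config()
  run <- simulate_run(p, "CT", cfg, n_trials = 20)$run
  nominal <- m_amplitude(cfg$intensity_mA, p)
  rep <- assess_reference_stability(run$trials$reference, nominal,
                                    tolerance_pct = 15)
  expect_false(rep$flagged)
})

test_that("stimulus-test mode fires on its own shorter interval", {
  set.seed(65)
  cfg <- closed_loop_config()
  run <- simulate_run(virtual_participant(), "ST", cfg, n_trials = 5)$run
  expect_equal(run$events$time_s[1], cfg$trigger$hold_duration_s)
  expect_equal(diff(run$events$time_s),
               rep(cfg$trigger$min_interval_stimulus_test_s, 4))
})

test_that("a voluntary-contraction run yields a usable MVC estimate", {
  set.seed(66)
  cfg <- closed_loop_config()
  p <- virtual_participant()
  run <- simulate_run(p, "VC", cfg)$run
  expect_equal(run$mode, "VC")
  expect_equal(nrow(run$trials), 0L)
  mvc <- mvc_level(run)
  # the drive ramps to vc_peak_mV mid-run; the trace maximum should land
  # near it (window smoothing and noise allow some slack)
  expect_gt(mvc, 0.7 * cfg$vc_peak_mV)
  expect_lt(mvc, 1.3 * cfg$vc_peak_mV)
  expect_equal(mvc, max(run$background$levels))
})

test_that("closed-loop sessions persist runs, logs and criteria on disk", {
  base <- withr::local_tempdir()
  cfg <- closed_loop_config()
  plan <- data.frame(mode = c("CT", "TT"), trials = c(4, 3))
  out <- run_closed_loop(virtual_participant(), plan, cfg, seed = 72,
                         base_dir = base, participant_id = "SIM09")
  ses <- out$sessions[[1]]
  files <- list.files(ses$meta$dir)
  expect_true(any(grepl("_CT01\\.rds$", files)))
  expect_true(any(grepl("_TT02\\.rds$", files)))
  expect_true(any(grepl("_log\\.txt$", files)))
  # reload and compare bit-exactly
  ct_path <- file.path(ses$meta$dir, grep("_CT01\\.rds$", files, value = TRUE))
  back <- load_run(ct_path)
  expect_identical(back$trials, ses$runs[[1]]$trials)
  # the control run's criterion was adopted and logged
  log <- readLines(reflexop:::log_path(ses$meta))
  expect_true(any(grepl("criterion adopted: down-conditioning", log)))
  expect_equal(ses$criteria[[1]]$threshold,
               criterion_from_distribution(ses$runs[[1]]$trials$target,
                                           66, "down")$threshold)
})
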