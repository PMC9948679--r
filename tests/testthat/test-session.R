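now0 <- as.POSIXct("2024-03-05 09:30:00", tz = "UTC")

test_that("sessions start fresh or continue within the three-hour window", {
  base <- withr::local_tempdir()
  s1 <- start_or_continue_session("P001", now = now0, base_dir = base)
  expect_false(s1$continuation)
  expect_true(dir.exists(s1$dir))
  expect_match(basename(s1$dir), "^20240305-0930_P001$")
  expect_equal(next_run_number(s1), 1L)

  # relaunch 2 h later: continuation, same directory
  s2 <- start_or_continue_session("P001", now = now0 + 2 * 3600,
                                  base_dir = base)
  expect_true(s2$continuation)
  expect_equal(s2$dir, s1$dir)

  # relaunch 4 h later: a new session
  s3 <- start_or_continue_session("P001", now = now0 + 4 * 3600,
                                  base_dir = base)
  expect_false(s3$continuation)
  expect_false(s3$dir == s1$dir)

  # other participants never continue someone else's session
  s4 <- start_or_continue_session("P002", now = now0 + 600, base_dir = base)
  expect_false(s4$continuation)
  expect_error(start_or_continue_session("", now = now0, base_dir = base),
               "nonempty")
})

tiny_run <- function(mode = "CT", n = 50, fs = 100) {
  sig <- matrix(0, 3, n, dimnames = list(c("target", "antagonist",
                                           "trigger_loopback"), NULL))
  structure(
    list(mode = mode, sample_rate = fs,
         channel_roles = rownames(sig), signals = sig,
         events = data.frame(time_s = numeric(0), frame = integer(0),
                             trial_index = integer(0),
                             intensity_mA = numeric(0)),
         trials = data.frame(), background = background_trace(numeric(n), fs),
         config = list(), criterion = NULL, truncated = FALSE,
         notes = character(0)),
    class = "epoc_run")
}

test_that("runs are numbered sequentially across modes and never overwrite", {
  base <- withr::local_tempdir()
  s <- start_or_continue_session("P010", now = now0, base_dir = base)
  p1 <- save_run(tiny_run("RC"), s, run_number = next_run_number(s))
  p2 <- save_run(tiny_run("CT"), s, run_number = next_run_number(s))
  p3 <- save_run(tiny_run("TT"), s, run_number = next_run_number(s))
  expect_match(basename(p1), "^20240305-0930_P010_RC01\\.rds$")
  expect_match(basename(p2), "_CT02\\.rds$")
  expect_match(basename(p3), "_TT03\\.rds$")
  expect_equal(next_run_number(s), 4L)
  # overwriting is a hard error
  expect_error(save_run(tiny_run("CT"), s, run_number = 2), "refusing")
  # continuation resumes the numbering
  s2 <- start_or_continue_session("P010", now = now0 + 3600, base_dir = base)
  expect_true(s2$continuation)
  expect_equal(next_run_number(s2), 4L)
})

test_that("persisted runs round-trip bit-exactly with a JSON sidecar", {
  base <- withr::local_tempdir()
  s <- start_or_continue_session("P011", now = now0, base_dir = base)
  set.seed(50)
  run <- simulate_run(virtual_participant(), "CT", closed_loop_config(),
                      n_trials = 2)$run
  run$run_number <- 1L
  path <- save_run(run, s)
  back <- load_run(path)
  expect_identical(back$signals, run$signals)
  expect_identical(back$events, run$events)
  expect_identical(back$trials, run$trials)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_equal(side$mode, "CT")
  expect_equal(side$n_trials, 2L)
})

test_that("start_run/stop_run reserve a slot and forbid concurrent runs", {
  base <- withr::local_tempdir()
  s <- start_or_continue_session("P012", now = now0, base_dir = base)
  h <- start_run(s, "RC")
  expect_equal(h$run_number, 1L)
  expect_error(start_run(s, "CT"), "in progress")
  stop_run(h, tiny_run("RC"))
  h2 <- start_run(s, "CT")
  expect_equal(h2$run_number, 2L)
  stop_run(h2, tiny_run("CT"))
})

test_that("MVC is the maximum of the target background trace", {
  r <- tiny_run("VC")
  r$background <- background_trace(seq(0, 0.5, length.out = 50), 100)
  expect_equal(mvc_level(r), 0.5)  # monotone ramp -> final value
  r$background <- background_trace(rep(0.2, 50), 100)
  expect_equal(mvc_level(r), 0.2)  # constant -> that constant
  set.seed(51)
  burst <- abs(rnorm(50))
  r$background <- background_trace(burst, 100)
  expect_equal(mvc_level(r), max(burst))
  expect_error(mvc_level(tiny_run("CT")), "VC")
})

test_that("the session log is append-only, ordered and auto-stamped", {
  base <- withr::local_tempdir()
  s <- start_or_continue_session("P013", now = now0, base_dir = base)
  append_log(s, "first note", timestamp = now0)
  append_log(s, "second note", timestamp = now0 + 60)
  crit <- criterion_from_distribution(rlnorm(30), 66, "down")
  log_criterion_adoption(s, crit, timestamp = now0 + 120)
  log_distribution_summary(s, compute_distribution(rlnorm(30)),
                           timestamp = now0 + 180)
  lines <- readLines(reflexop:::log_path(s))
  expect_match(lines[1], "first note")
  expect_match(lines[2], "second note")
  expect_match(lines[3],
               "criterion adopted: down-conditioning, percentile 66, threshold")
  expect_true(any(grepl("distribution summary: n 30", lines)))
  expect_true(all(grepl("^\\[2024-03-05 ", lines)))
})

test_that("session templates carry the protocol's run structure", {
  b <- session_template("baseline")
  expect_equal(b$runs$mode, c("RC", "CT", "CT", "CT", "RC"))
  expect_equal(b$runs$trials, c(NA, 75L, 75L, 75L, NA))
  cnd <- session_template("conditioning")
  expect_equal(cnd$runs$mode, c("RC", "CT", "TT", "TT", "TT", "RC"))
  expect_equal(cnd$runs$trials, c(NA, 20L, 75L, 75L, 75L, NA))
  fu <- session_template("follow_up")
  expect_equal(fu$runs, b$runs)
  fu2 <- session_template("follow_up", "conditioning")
  expect_equal(fu2$runs, cnd$runs)
})

test_that("protocol plans contain the scheduled session counts in order", {
  plan <- plan_protocol(impaired = FALSE)
  kinds <- vapply(plan, `[[`, "", "kind")
  expect_length(plan, 34)
  expect_equal(kinds, c(rep("baseline", 6), rep("conditioning", 24),
                        rep("follow_up", 4)))
  plan_i <- plan_protocol(impaired = TRUE)
  expect_length(plan_i, 40)
  expect_equal(sum(vapply(plan_i, `[[`, "", "kind") == "conditioning"), 30)
})

test_that("mode codes form a closed enumeration", {
  expect_equal(mode_code("RC"), "RC")
  expect_error(mode_code("XX"), "mode must be")
})
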