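# Shared fixtures, built in code.

# A quiet, noise-free participant for exact round-trip checks.
silent_participant <- function(...) {
  virtual_participant(background_drive = 0, drive_noise = 0,
                      response_noise = 0, plasticity_rate = 0, ...)
}

# Brute-force trailing-window mean, the oracle for sliding_mean().
brute_trailing_mean <- function(x, n) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - n + 1):i]), numeric(1))
}

# Brute-force fold of trigger_step() over per-frame levels; the oracle for
# run_gate() / gate_scan().
brute_gate <- function(lt, la, dt, config, mode = "normal",
                       state = trigger_state()) {
  times <- numeric(0)
  for (i in seq_along(lt)) {
    r <- trigger_step(state, lt[i], la[i], dt, config, mode)
    state <- r$state
    if (r$fire) times <- c(times, i * dt)
  }
  list(times = times, state = state)
}

# Random in-range mask converted to levels for a [0.3, 0.7] target range.
mask_levels <- function(mask) ifelse(mask, 0.5, 1.0)

range_03_07 <- function(...) {
  trigger_config(target_range = range_spec(0.3, 0.7),
                 antagonist_range = range_spec(), ...)
}

# A tiny epoch holding a given target-channel segment right after stimulus.
segment_epoch <- function(values, sample_rate = 1000) {
  n <- length(values)
  wf <- matrix(values, nrow = 1,
               dimnames = list("target", NULL))
  structure(list(waveforms = wf, pre_s = 0, post_s = n / sample_rate,
                 sample_rate = sample_rate,
                 event = list(time_s = 0, frame = 0L, trial_index = 1L),
                 background_at_trigger = NULL),
            class = "epoch")
}
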