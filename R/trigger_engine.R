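#' Background-EMG range restriction
#'
#' A closed interval of acceptable background level. Either bound may be left
#' blank (`NULL`), imposing no restriction on that side.
#'
#' @param low,high Bounds in millivolts, or `NULL` for unbounded.
#' @return An object of class `range_spec`.
#' @export
range_spec <- function(low = NULL, high = NULL) {
  low <- if (is.null(low)) -Inf else as.numeric(low)
  high <- if (is.null(high)) Inf else as.numeric(high)
  if (low > high) stop("range low bound exceeds high bound")
  structure(list(low = low, high = high), class = "range_spec")
}

#' Is a background level inside a range?
#'
#' Inclusive at both bounds; blank bounds impose no restriction.
#'
#' @param level Non-negative numeric vector of background levels, mV.
#' @param range A [range_spec()].
#' @return Logical vector.
#' @export
in_range <- function(level, range) {
  stopifnot(inherits(range, "range_spec"))
  if (any(level < 0)) stop("background levels must be non-negative")
  level >= range$low & level <= range$high
}

#' Stimulation-contingency configuration
#'
#' @param target_range,antagonist_range [range_spec()] objects the target and
#'   antagonist background EMG must stay within to enable stimulation.
#' @param hold_duration_s How long (s) the EMG must remain continuously in
#'   range before a stimulus may be triggered. Default 2 s.
#' @param min_interval_s Minimum time (s) since the previous stimulus in
#'   normal usage. Default 5 s.
#' @param min_interval_stimulus_test_s Minimum inter-stimulus interval (s)
#'   used in Stimulus Test mode, configured separately and typically shorter.
#'   Default 3 s.
#' @return An object of class `trigger_config`.
#' @export
trigger_config <- function(target_range = range_spec(),
                           antagonist_range = range_spec(),
                           hold_duration_s = 2,
                           min_interval_s = 5,
                           min_interval_stimulus_test_s = 3) {
  stopifnot(inherits(target_range, "range_spec"),
            inherits(antagonist_range, "range_spec"))
  if (hold_duration_s < 0) stop("hold_duration_s must be >= 0")
  if (min_interval_s <= 0 || min_interval_stimulus_test_s <= 0) {
    stop("minimum intervals must be > 0")
  }
  structure(
    list(target_range = target_range, antagonist_range = antagonist_range,
         hold_duration_s = hold_duration_s, min_interval_s = min_interval_s,
         min_interval_stimulus_test_s = min_interval_stimulus_test_s),
    class = "trigger_config"
  )
}

#' Elapsed-time bookkeeping for the stimulation gate
#'
#' @param time_since_last_s Seconds since the previous stimulus; `Inf` at run
#'   start, so the interval rule never blocks the first stimulus.
#' @param in_range_elapsed_s Seconds of uninterrupted in-range time.
#' @return An object of class `trigger_state`.
#' @export
trigger_state <- function(time_since_last_s = Inf, in_range_elapsed_s = 0) {
  stopifnot(time_since_last_s >= 0, in_range_elapsed_s >= 0)
  structure(list(time_since_last_s = time_since_last_s,
                 in_range_elapsed_s = in_range_elapsed_s),
            class = "trigger_state")
}

# Minimum interval for a mode.
mode_interval <- function(config, mode) {
  if (identical(mode, "stimulus_test")) config$min_interval_stimulus_test_s
  else config$min_interval_s
}

#' Advance the stimulation gate by one frame
#'
#' The in-range timer advances by `dt` iff both muscles are within their
#' ranges this frame and resets to zero otherwise; a stimulus fires iff the
#' in-range timer has reached the hold duration and the inter-stimulus timer
#' has reached the mode's minimum interval. On firing, both timers reset, so
#' each trial requires a fresh hold. In Stimulus Test mode the range
#' conditions are waived and the (shorter) stimulus-test interval applies.
#'
#' @param state A [trigger_state()].
#' @param level_target,level_antagonist Current background levels, mV.
#' @param dt Frame duration, s.
#' @param config A [trigger_config()].
#' @param mode One of `"normal"`, `"stimulus_test"`.
#' @return List with elements `state` (updated [trigger_state()]) and `fire`
#'   (logical: whether a stimulus is emitted on this frame).
#' @export
trigger_step <- function(state, level_target, level_antagonist, dt, config,
                         mode = "normal") {
  stopifnot(inherits(state, "trigger_state"), dt > 0)
  if (level_target < 0 || level_antagonist < 0) {
    stop("background levels must be non-negative")
  }
  ok <- identical(mode, "stimulus_test") ||
    (in_range(level_target, config$target_range) &&
       in_range(level_antagonist, config$antagonist_range))
  elapsed <- if (ok) state$in_range_elapsed_s + dt else 0
  since <- state$time_since_last_s + dt
  fire <- elapsed >= config$hold_duration_s - 1e-12 &&
    since >= mode_interval(config, mode) - 1e-12
  if (fire) {
    elapsed <- 0
    since <- 0
  }
  list(state = trigger_state(since, elapsed), fire = fire)
}

# Fast event scan over a logical in-range mask. Equivalent to folding
# trigger_step() frame by frame (frame i covers time i*dt from scan start),
# but jumps between in-range segments, so cost scales with the number of
# events and segments rather than frames.
#
# Returns integer frame indices of fired stimuli plus the final state.
gate_scan <- function(mask, dt, hold_s, interval_s, state) {
  n <- length(mask)
  if (n == 0L) return(list(frames = integer(0), state = state))
  hold_f <- max(0L, as.integer(ceiling(hold_s / dt - 1e-9)))
  int_f <- max(1L, as.integer(ceiling(interval_s / dt - 1e-9)))
  carry <- state$in_range_elapsed_s
  since0 <- state$time_since_last_s
  # first frame at which the interval rule is met before any in-scan fire
  t_int0 <- if (is.infinite(since0)) 1L else {
    max(1L, as.integer(ceiling((interval_s - since0) / dt - 1e-9)))
  }
  frames <- integer(0)
  e <- 0L           # frame of last in-scan fire (0 = none)
  fired <- FALSE

  if (hold_f == 0L) {
    # hold satisfied at every frame: fire purely on the interval rule
    t <- t_int0
    while (t <= n) {
      frames <- c(frames, t)
      e <- t
      fired <- TRUE
      t <- t + int_f
    }
  } else {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]
    ends <- ends[keep]
    # frames of in-range run needed to satisfy the hold, for the leading run
    # (which inherits carried elapsed time) and for all later runs
    k_lead <- max(0L, as.integer(ceiling((hold_s - carry) / dt - 1e-9)))
    j <- 1L
    repeat {
      t_int <- if (fired) e + int_f else t_int0
      fire_t <- NA_integer_
      while (j <= length(starts)) {
        eff_start <- max(starts[j], e + 1L)
        kr <- if (starts[j] == 1L && !fired) k_lead else hold_f
        t <- max(t_int, eff_start + max(kr, 1L) - 1L)
        if (t <= ends[j]) {
          fire_t <- t
          break
        }
        j <- j + 1L
      }
      if (is.na(fire_t)) break
      frames <- c(frames, fire_t)
      e <- fire_t
      fired <- TRUE
    }
  }
  since <- if (fired) (n - e) * dt
           else if (is.infinite(since0)) Inf else since0 + n * dt
  if (mask[n]) {
    last_start <- n + 1L - match(FALSE, rev(mask), nomatch = n + 1L) + 1L
    eff_start <- max(last_start, e + 1L)
    k <- n - eff_start + 1L
    elapsed <- k * dt + if (last_start == 1L && !fired) carry else 0
  } else {
    elapsed <- 0
  }
  list(frames = frames, state = trigger_state(since, elapsed))
}

#' Batch stimulation gating over whole traces
#'
#' Applies the per-frame gate of [trigger_step()] across a pair of
#' background traces and returns every emitted stimulus event. The result is
#' identical to folding [trigger_step()] over the frames.
#'
#' @param trace_target,trace_antagonist [background_trace()] objects of equal
#'   length and sample rate.
#' @param config A [trigger_config()].
#' @param mode `"normal"` or `"stimulus_test"`.
#' @param state Initial [trigger_state()]; defaults to run start.
#' @param first_trial_index Trial index assigned to the first emitted event.
#' @return A data frame of stimulus events with columns `time_s`, `frame`,
#'   `trial_index`; the final gate state is attached as attribute `"state"`.
#' @export
run_gate <- function(trace_target, trace_antagonist, config,
                     mode = "normal", state = trigger_state(),
                     first_trial_index = 1L) {
  stopifnot(inherits(trace_target, "background_trace"),
            inherits(trace_antagonist, "background_trace"))
  if (length(trace_target$levels) != length(trace_antagonist$levels)) {
    stop("target and antagonist traces differ in length")
  }
  dt <- 1 / trace_target$sample_rate
  mask <- if (identical(mode, "stimulus_test")) {
    rep(TRUE, length(trace_target$levels))
  } else {
    in_range(trace_target$levels, config$target_range) &
      in_range(trace_antagonist$levels, config$antagonist_range)
  }
  sc <- gate_scan(mask, dt, config$hold_duration_s,
                  mode_interval(config, mode), state)
  ev <- data.frame(
    time_s = sc$frames * dt,
    frame = sc$frames,
    trial_index = if (length(sc$frames)) {
      seq(first_trial_index, length.out = length(sc$frames))
    } else integer(0)
  )
  attr(ev, "state") <- sc$state
  ev
}
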