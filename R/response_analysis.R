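#' Measurement windows for the reference and target responses
#'
#' Post-stimulus latency intervals, in milliseconds, within which the
#' reference (M-wave) and target (H-reflex) responses are measured. Intervals
#' are half-open `[start, end)` and the reference interval must end at or
#' before the target interval starts. Defaults cover typical soleus latencies
#' (M-wave roughly 6-25 ms, H-reflex roughly 25-50 ms after tibial-nerve
#' stimulation); they are starting values to be adjusted per participant and
#' then persisted.
#'
#' @param reference_ms,target_ms Numeric length-2 vectors `c(start, end)` in
#'   ms post-stimulus.
#' @return An object of class `response_windows`.
#' @export
response_windows <- function(reference_ms = c(6, 23), target_ms = c(28, 45)) {
  stopifnot(length(reference_ms) == 2L, length(target_ms) == 2L)
  ok <- 0 <= reference_ms[1] && reference_ms[1] < reference_ms[2] &&
    reference_ms[2] <= target_ms[1] && target_ms[1] < target_ms[2]
  if (!ok) {
    stop("windows must satisfy 0 <= ref.start < ref.end <= tgt.start < tgt.end")
  }
  structure(list(reference_ms = as.numeric(reference_ms),
                 target_ms = as.numeric(target_ms)),
            class = "response_windows")
}

#' A single stimulus-locked epoch
#'
#' Extracts, per channel, the waveform segment around one stimulus so the
#' evoked response can be measured. The sample at position
#' `round(pre_s * sample_rate) + 1` is the stimulus-onset frame (time zero).
#'
#' @param signals Channels x frames numeric matrix of the whole run (mV), with
#'   row names giving channel roles, or a `sample_block`.
#' @param event One-row data frame (or list) with at least `time_s` and
#'   `frame`; typically a row of the event table from [run_gate()].
#' @param pre_s,post_s Seconds of signal kept before/after stimulus onset.
#'   Defaults 0.05 and 0.1 cover the M-wave and H-reflex latencies.
#' @param sample_rate Hz (taken from `signals` if it is a `sample_block`).
#' @param background Optional numeric vector: background level per channel at
#'   the trigger frame, copied into the epoch.
#' @return An object of class `epoch` with fields `waveforms` (channels x
#'   frames), `pre_s`, `post_s`, `sample_rate`, `event`,
#'   `background_at_trigger`.
#' @export
extract_epoch <- function(signals, event, pre_s = 0.05, post_s = 0.1,
                          sample_rate = NULL, background = NULL) {
  if (inherits(signals, "sample_block")) {
    sample_rate <- signals$sample_rate
    signals <- signals$samples
  }
  stopifnot(is.matrix(signals), !is.null(sample_rate))
  fs <- sample_rate
  i0 <- if (!is.null(event$frame)) as.integer(event$frame)
        else as.integer(round(event$time_s * fs))
  pre_n <- as.integer(round(pre_s * fs))
  post_n <- as.integer(round(post_s * fs))
  lo <- i0 - pre_n        # stimulus frame lands at local index pre_n + 1
  hi <- i0 + post_n - 1L
  if (lo < 1L || hi > ncol(signals)) {
    stop(sprintf(
      "epoch rejected: event at frame %d needs frames [%d, %d] but run has %d",
      i0, lo, hi, ncol(signals)))
  }
  wf <- signals[, lo:hi, drop = FALSE]
  structure(
    list(waveforms = wf, pre_s = pre_s, post_s = post_s, sample_rate = fs,
         event = event, background_at_trigger = background),
    class = "epoch"
  )
}

# Map a half-open [start, end) ms window to 1-based epoch column indices.
# Frame offsets from stimulus onset are floor(start*fs/1000) ..
# floor(end*fs/1000) - 1.
window_frames <- function(epoch, window_ms) {
  fs <- epoch$sample_rate
  onset <- as.integer(round(epoch$pre_s * fs)) + 1L
  a <- as.integer(floor(window_ms[1] * fs / 1000 + 1e-9))
  b <- as.integer(floor(window_ms[2] * fs / 1000 + 1e-9)) - 1L
  if (b < a) stop("window is empty after discretization")
  if (window_ms[2] > epoch$post_s * 1000 + 1e-9) {
    stop("window extends beyond the epoch's post-stimulus span")
  }
  onset + (a:b)
}

#' Size of a response within a latency window
#'
#' Quantifies one windowed segment of an epoch either as its peak-to-peak
#' amplitude (`max - min`) or its mean rectified amplitude (`mean(abs(x))`).
#'
#' @param epoch An [extract_epoch()] result.
#' @param window_ms Length-2 numeric `c(start, end)` in ms post-stimulus,
#'   half-open.
#' @param method `"peak_to_peak"` (default) or `"mean_rectified"`.
#' @param channel Channel role (row name) to measure; default `"target"`.
#' @return An object of class `response_size` with fields `value` (mV, always
#'   non-negative), `method`, `window_ms`.
#' @export
response_size <- function(epoch, window_ms,
                          method = c("peak_to_peak", "mean_rectified"),
                          channel = "target") {
  stopifnot(inherits(epoch, "epoch"))
  method <- match.arg(method)
  seg <- epoch$waveforms[channel, window_frames(epoch, window_ms)]
  value <- if (method == "peak_to_peak") max(seg) - min(seg) else mean(abs(seg))
  structure(list(value = value, method = method,
                 window_ms = as.numeric(window_ms)),
            class = "response_size")
}

#' @export
print.response_size <- function(x, ...) {
  cat(sprintf("<response_size> %.4g mV (%s over [%g, %g) ms)\n",
              x$value, x$method, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Measure the reference and target responses of one trial
#'
#' @param epoch An [extract_epoch()] result.
#' @param windows A [response_windows()].
#' @param method Passed to [response_size()].
#' @param channel Channel role to measure (default `"target"`, the muscle in
#'   which both the M-wave and the H-reflex appear).
#' @return List with elements `reference` and `target`, each a
#'   [response_size()].
#' @export
measure_trial <- function(epoch, windows = response_windows(),
                          method = c("peak_to_peak", "mean_rectified"),
                          channel = "target") {
  stopifnot(inherits(windows, "response_windows"))
  method <- match.arg(method)
  list(
    reference = response_size(epoch, windows$reference_ms, method, channel),
    target = response_size(epoch, windows$target_ms, method, channel)
  )
}

#' Build the per-trial measurement table of a run
#'
#' Extracts an epoch around every stimulus event of a recorded run and
#' measures the reference and target responses; the offline counterpart of
#' the measurements made live during the run.
#'
#' @param run A run record (see [save_run()]) or a list with elements
#'   `signals` (channels x frames matrix), `sample_rate`, `events` (data
#'   frame with `time_s`, `frame`, `trial_index`, optionally `intensity_mA`),
#'   and optionally `background` (target-channel [background_trace()]).
#' @param windows A [response_windows()].
#' @param method Passed to [response_size()].
#' @param pre_s,post_s Epoch span, seconds.
#' @return Data frame with one row per trial: `trial`, `time_s`,
#'   `intensity_mA`, `reference`, `target`, `background`, `success`.
#' @export
measure_run <- function(run, windows = response_windows(),
                        method = c("peak_to_peak", "mean_rectified"),
                        pre_s = 0.05, post_s = 0.1) {
  method <- match.arg(method)
  ev <- run$events
  n <- nrow(ev)
  bg <- if (!is.null(run$background)) run$background$levels else NULL
  out <- data.frame(
    trial = integer(n), time_s = numeric(n), intensity_mA = numeric(n),
    reference = numeric(n), target = numeric(n), background = numeric(n),
    success = rep(NA, n)
  )
  for (i in seq_len(n)) {
    e <- ev[i, , drop = FALSE]
    ep <- extract_epoch(run$signals, e, pre_s, post_s, run$sample_rate)
    m <- measure_trial(ep, windows, method)
    out$trial[i] <- if (!is.null(e$trial_index)) e$trial_index else i
    out$time_s[i] <- e$time_s
    out$intensity_mA[i] <- if (!is.null(e$intensity_mA)) e$intensity_mA else NA_real_
    out$reference[i] <- m$reference$value
    out$target[i] <- m$target$value
    out$background[i] <- if (!is.null(bg)) bg[e$frame] else NA_real_
  }
  out
}
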