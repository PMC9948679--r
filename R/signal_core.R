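#' Signal-processing configuration
#'
#' Bundles the parameters that turn raw multichannel EMG into continuous
#' background-activity traces: the high-pass cutoff that removes DC offset and
#' motion artifact, the trailing-window length over which the rectified signal
#' is averaged, and the sample rate.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param highpass_cutoff_hz High-pass cutoff in Hz. Must lie strictly between
#'   0 and the Nyquist frequency. Default 10 Hz: below the surface-EMG band,
#'   above postural drift.
#' @param background_window_s Length of the trailing averaging window in
#'   seconds. Default 0.2 s: responsive enough for visual feedback while
#'   smoothing over individual motor-unit bursts.
#' @param amplifier_gain Dimensionless hardware gain divided out so that
#'   signals are expressed in millivolts at the skin. Default 500.
#' @param block_s Nominal processing-block duration in seconds; timing
#'   tolerances elsewhere are quantized to one block. Default 0.02 s.
#' @return An object of class `signal_config`.
#' @export
signal_config <- function(sample_rate,
                          highpass_cutoff_hz = 10,
                          background_window_s = 0.2,
                          amplifier_gain = 500,
                          block_s = 0.02) {
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  if (!(highpass_cutoff_hz > 0 && highpass_cutoff_hz < sample_rate / 2)) {
    stop("highpass_cutoff_hz must lie in (0, sample_rate/2)")
  }
  if (background_window_s <= 0) stop("background_window_s must be > 0")
  if (background_window_s * sample_rate < 1) {
    stop("background window shorter than one sample")
  }
  if (background_window_s > 60) {
    stop("background_window_s too long for a practical streaming buffer")
  }
  structure(
    list(
      sample_rate = sample_rate,
      highpass_cutoff_hz = highpass_cutoff_hz,
      background_window_s = background_window_s,
      amplifier_gain = amplifier_gain,
      block_s = block_s
    ),
    class = "signal_config"
  )
}

#' A chunk of multichannel raw signal
#'
#' @param samples Numeric matrix, channels x frames, in millivolts.
#' @param sample_rate Hz.
#' @param channel_roles Character vector naming each row; the first two roles
#'   must include `"target"` and `"antagonist"`; a `"trigger_loopback"`
#'   channel records the stimulus pulse for offline timing verification.
#' @param start_time Seconds from run start of the first frame.
#' @return An object of class `sample_block`.
#' @export
sample_block <- function(samples, sample_rate,
                         channel_roles = c("target", "antagonist",
                                           "trigger_loopback"),
                         start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (ncol(samples) < 1L) stop("a sample block needs at least one frame")
  if (nrow(samples) < 2L) stop("at least two channels (target, antagonist) required")
  if (length(channel_roles) != nrow(samples)) {
    stop("channel_roles must name every row of `samples`")
  }
  if (!all(c("target", "antagonist") %in% channel_roles)) {
    stop("channel_roles must include 'target' and 'antagonist'")
  }
  stopifnot(sample_rate > 0, start_time >= 0)
  rownames(samples) <- channel_roles
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_roles = channel_roles, start_time = start_time),
    class = "sample_block"
  )
}

#' A per-frame background-activity trace
#'
#' Mean rectified value of the high-pass-filtered signal in a trailing window,
#' one value per input frame, in millivolts.
#'
#' @param levels Non-negative numeric vector.
#' @param sample_rate Hz.
#' @return An object of class `background_trace`.
#' @export
background_trace <- function(levels, sample_rate) {
  stopifnot(is.numeric(levels), all(is.finite(levels)), all(levels >= 0),
            sample_rate > 0)
  structure(list(levels = as.numeric(levels), sample_rate = sample_rate),
            class = "background_trace")
}

#' @export
length.background_trace <- function(x) length(x$levels)

#' @export
print.background_trace <- function(x, ...) {
  cat(sprintf("<background_trace> %d frames @ %g Hz, mean %.4g mV\n",
              length(x$levels), x$sample_rate, mean(x$levels)))
  invisible(x)
}

# Second-order Butterworth high-pass coefficients for a config.
hp_coefs <- function(config) {
  bf <- signal::butter(2, config$highpass_cutoff_hz / (config$sample_rate / 2),
                       type = "high")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Fresh carried state for one channel of the causal biquad: the two most
# recent raw inputs and filtered outputs (zero history at run start).
hp_state_init <- function() list(x1 = 0, x2 = 0, y1 = 0, y2 = 0)

# Direct-form-I biquad on one block with carried state. Exact: filtering a
# stream block-by-block equals filtering the concatenation.
hp_filter_block <- function(x, coefs, state) {
  n <- length(x)
  v <- stats::filter(c(state$x2, state$x1, x), coefs$b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[-(1:2)]
  y <- as.numeric(stats::filter(v, -coefs$a[2:3], method = "recursive",
                                init = c(state$y1, state$y2)))
  state$x2 <- if (n > 1L) x[n - 1L] else state$x1
  state$x1 <- x[n]
  state$y2 <- if (n > 1L) y[n - 1L] else state$y1
  state$y1 <- y[n]
  list(y = y, state = state)
}

#' Causal high-pass filter
#'
#' Applies a second-order Butterworth high-pass filter causally (zero initial
#' state), attenuating DC and slow drift while leaving the EMG band intact.
#' The same filter, applied block-by-block with carried state inside
#' [background_level()], produces bit-identical output, so streaming and
#' offline analyses agree exactly.
#'
#' @param x Numeric vector, millivolts.
#' @param config A [signal_config()].
#' @return Filtered numeric vector of the same length.
#' @export
highpass <- function(x, config) {
  stopifnot(inherits(config, "signal_config"))
  if (length(x) < 1L) stop("signal must contain at least one sample")
  if (any(!is.finite(x))) stop("non-finite samples in signal")
  hp_filter_block(x, hp_coefs(config), hp_state_init())$y
}

#' Full-wave rectification
#'
#' @param x Numeric vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

# Trailing-window mean with carried state. `state` holds up to (n-1) most
# recent samples plus the total sample count seen so far, so prefix windows
# (fewer than n samples available) are averaged over what exists.
sliding_mean_block <- function(x, n, state) {
  buf <- state$buf
  seen <- state$seen
  z <- c(buf, x)
  L <- length(buf)
  cs <- cumsum(c(0, z))
  i <- seq_along(x)
  w <- pmin(n, seen + i)          # effective window length per output frame
  hi <- L + i
  means <- (cs[hi + 1L] - cs[hi - w + 1L]) / w
  keep <- min(n - 1L, length(z))
  state$buf <- if (keep > 0L) z[(length(z) - keep + 1L):length(z)] else numeric(0)
  state$seen <- seen + length(x)
  list(levels = means, state = state)
}

sliding_state_init <- function() list(buf = numeric(0), seen = 0)

#' Trailing sliding-window mean
#'
#' Each output frame is the mean of the trailing window ending at that frame;
#' during the first `window_s` of a run the mean is taken over however many
#' samples exist.
#'
#' @param x Numeric vector (typically rectified, filtered EMG), millivolts.
#' @param window_s Window length in seconds.
#' @param sample_rate Hz.
#' @return A [background_trace()] of the same length as `x`.
#' @export
sliding_mean <- function(x, window_s, sample_rate) {
  n <- max(1L, round(window_s * sample_rate))
  if (window_s * sample_rate < 1) stop("window must span at least one sample")
  if (window_s > 60) stop("window longer than the practical streaming buffer")
  out <- sliding_mean_block(x, n, sliding_state_init())
  background_trace(pmax(out$levels, 0), sample_rate)
}

# Combined per-channel streaming state for highpass -> rectify -> sliding mean.
emg_state_init <- function(config, n_channels) {
  list(
    coefs = hp_coefs(config),
    n_win = max(1L, round(config$background_window_s * config$sample_rate)),
    hp = replicate(n_channels, hp_state_init(), simplify = FALSE),
    sm = replicate(n_channels, sliding_state_init(), simplify = FALSE),
    n_channels = n_channels
  )
}

# Process one channels x frames matrix; returns the per-channel level matrix
# and the updated state.
emg_process_block <- function(samples, state) {
  levels <- matrix(0, nrow = nrow(samples), ncol = ncol(samples))
  for (ch in seq_len(nrow(samples))) {
    f <- hp_filter_block(samples[ch, ], state$coefs, state$hp[[ch]])
    state$hp[[ch]] <- f$state
    s <- sliding_mean_block(abs(f$y), state$n_win, state$sm[[ch]])
    state$sm[[ch]] <- s$state
    levels[ch, ] <- pmax(s$levels, 0)
  }
  list(levels = levels, state = state)
}

#' Background EMG level of a block stream
#'
#' Composes [highpass()], [rectify()] and [sliding_mean()] per channel with
#' carried filter and window state, so that any partition of a recording into
#' blocks yields the identical trace as single-shot processing.
#'
#' @param blocks A single [sample_block()] or a list of contiguous ones
#'   (successive `start_time`s must advance by exactly `frames/sample_rate`).
#' @param config A [signal_config()].
#' @return Named list of [background_trace()] objects, one per channel role.
#' @export
background_level <- function(blocks, config) {
  stopifnot(inherits(config, "signal_config"))
  if (inherits(blocks, "sample_block")) blocks <- list(blocks)
  if (length(blocks) == 0L) stop("empty block stream")
  roles <- blocks[[1L]]$channel_roles
  nch <- length(roles)
  state <- emg_state_init(config, nch)
  out <- vector("list", length(blocks))
  t_expect <- blocks[[1L]]$start_time
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    stopifnot(inherits(b, "sample_block"))
    if (nrow(b$samples) != nch || !identical(b$channel_roles, roles)) {
      stop("inconsistent channel layout across blocks")
    }
    if (abs(b$sample_rate - config$sample_rate) > 1e-9) {
      stop("block sample rate does not match config")
    }
    if (abs(b$start_time - t_expect) > 0.5 / config$sample_rate) {
      stop("blocks are not contiguous")
    }
    t_expect <- b$start_time + ncol(b$samples) / config$sample_rate
    r <- emg_process_block(b$samples, state)
    state <- r$state
    out[[i]] <- r$levels
  }
  levels <- do.call(cbind, out)
  traces <- lapply(seq_len(nch), function(ch) {
    background_trace(levels[ch, ], config$sample_rate)
  })
  names(traces) <- roles
  traces
}
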