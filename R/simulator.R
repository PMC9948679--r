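#' A virtual participant
#'
#' Parameterizes a synthetic generator of background EMG and stimulus-evoked
#' responses. M-wave recruitment follows a logistic sigmoid of stimulus
#' intensity (rises, then saturates); H-reflex recruitment is a logistic rise
#' multiplied by a logistic suppression at higher intensities (rises, then
#' falls, as antidromic collision occludes the reflex). These functional
#' forms are modeling choices that reproduce the qualitative recruitment
#' shapes; every parameter is configurable.
#'
#' @param m_max Maximal M-wave amplitude, mV.
#' @param h_max Maximal H-reflex amplitude (at excitability 1), mV.
#' @param i50_m,i50_h,i_collision Sigmoid midpoints, mA: half-maximal M-wave,
#'   half-maximal H-reflex rise, and half-suppression of the H-reflex. The
#'   default ordering `i50_h < i50_m < i_collision` yields the classic
#'   recruitment shapes.
#' @param slope_m,slope_h,slope_c Sigmoid slopes, 1/mA.
#' @param latency_m_ms,latency_h_ms Response-onset latencies, ms
#'   post-stimulus (M before H).
#' @param background_drive Mean rectified background EMG level the
#'   participant aims for, mV.
#' @param drive_noise Relative SD of the slowly fluctuating drive.
#' @param response_noise Relative SD of trial-to-trial response amplitude.
#' @param plasticity_rate Fractional change of H-reflex excitability per
#'   reinforced (successful) training trial; 0 disables plasticity.
#' @param h_excitability Multiplicative excitability state, initial 1.
#' @return An object of class `virtual_participant`.
#' @export
virtual_participant <- function(m_max = 6, h_max = 3,
                                i50_m = 18, i50_h = 12, i_collision = 28,
                                slope_m = 0.35, slope_h = 0.4, slope_c = 0.35,
                                latency_m_ms = 8, latency_h_ms = 30,
                                background_drive = 0.025,
                                drive_noise = 0.15,
                                response_noise = 0.15,
                                plasticity_rate = 0.005,
                                h_excitability = 1) {
  stopifnot(m_max >= 0, h_max >= 0, latency_m_ms < latency_h_ms,
            h_excitability > 0, background_drive >= 0,
            drive_noise >= 0, response_noise >= 0, plasticity_rate >= 0)
  structure(
    list(m_max = m_max, h_max = h_max, i50_m = i50_m, i50_h = i50_h,
         i_collision = i_collision, slope_m = slope_m, slope_h = slope_h,
         slope_c = slope_c, latency_m_ms = latency_m_ms,
         latency_h_ms = latency_h_ms, background_drive = background_drive,
         drive_noise = drive_noise, response_noise = response_noise,
         plasticity_rate = plasticity_rate, h_excitability = h_excitability),
    class = "virtual_participant"
  )
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Programmed M-wave amplitude at a stimulus intensity
#'
#' `m_max * logistic((I - i50_m) * slope_m)`: monotone nondecreasing in `I`,
#' saturating at `m_max`.
#'
#' @param I Stimulus intensity, mA (vectorized).
#' @param p A [virtual_participant()].
#' @return Amplitude in mV.
#' @export
m_amplitude <- function(I, p) {
  stopifnot(all(I >= 0))
  p$m_max * logistic((I - p$i50_m) * p$slope_m)
}

#' Programmed H-reflex amplitude at a stimulus intensity
#'
#' `h_excitability * h_max * logistic((I - i50_h) * slope_h) *
#' (1 - logistic((I - i_collision) * slope_c))`: unimodal in `I` for the
#' default midpoint ordering, and exactly proportional to the excitability
#' state.
#'
#' @inheritParams m_amplitude
#' @return Amplitude in mV.
#' @export
h_amplitude <- function(I, p) {
  stopifnot(all(I >= 0))
  p$h_excitability * p$h_max * logistic((I - p$i50_h) * p$slope_h) *
    (1 - logistic((I - p$i_collision) * p$slope_c))
}

#' Reinforcement-driven plasticity update
#'
#' On a successful trial the H-reflex excitability state is multiplied by
#' `(1 - plasticity_rate)` for down-conditioning or `(1 + plasticity_rate)`
#' for up-conditioning; unsuccessful trials leave it unchanged. The state is
#' clipped to \[0.2, 2.0\].
#'
#' @param p A [virtual_participant()].
#' @param success Logical: was the trial reinforced?
#' @param direction `"down"` or `"up"`.
#' @return The updated participant.
#' @export
apply_reinforcement <- function(p, success, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (isTRUE(success)) {
    f <- if (direction == "down") 1 - p$plasticity_rate else 1 + p$plasticity_rate
    p$h_excitability <- min(2.0, max(0.2, p$h_excitability * f))
  }
  p
}

#' Simulator configuration
#'
#' @param sample_rate Hz; default 2000, comfortably resolving the 6-45 ms
#'   response latencies.
#' @param template_duration_ms Duration of the biphasic evoked-response
#'   template, ms.
#' @param noise_band_hz Band of the background-EMG noise process, Hz.
#' @param antagonist_drive Mean rectified level of the antagonist channel, mV.
#' @param loopback_amplitude_mV Height of the stimulus pulse recorded on the
#'   trigger-loopback channel.
#' @param ou_tau_s Relaxation time of the drive fluctuation process, s.
#' @param seed Optional RNG seed applied by [synth_continuous()] for
#'   scenario-level reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 2000, template_duration_ms = 12,
                       noise_band_hz = c(20, 250), antagonist_drive = 0.005,
                       loopback_amplitude_mV = 5, ou_tau_s = 2, seed = NULL) {
  stopifnot(sample_rate > 0, template_duration_ms > 0,
            length(noise_band_hz) == 2L,
            noise_band_hz[1] > 0, noise_band_hz[2] < sample_rate / 2)
  structure(
    list(sample_rate = sample_rate,
         template_duration_ms = template_duration_ms,
         noise_band_hz = noise_band_hz, antagonist_drive = antagonist_drive,
         loopback_amplitude_mV = loopback_amplitude_mV,
         ou_tau_s = ou_tau_s, seed = seed),
    class = "sim_config"
  )
}

# Unit biphasic template: one positive and one negative lobe under a Hann
# envelope, normalized so its peak-to-peak amplitude is exactly 1 on the
# discrete sample grid (so a programmed amplitude A is recovered exactly by
# a peak-to-peak measurement in a window containing the whole template).
evoked_template <- function(duration_ms, sample_rate) {
  n <- max(4L, as.integer(round(duration_ms / 1000 * sample_rate)))
  i <- 0:(n - 1L)
  w <- sin(2 * pi * i / n) * (0.5 - 0.5 * cos(2 * pi * i / (n - 1L)))
  w / (max(w) - min(w))
}

# Generic causal IIR block filter with carried state (x_prev and y_prev are
# most-recent-first). Streaming-exact like the high-pass in signal_core.
iir_block <- function(x, b, a, state = NULL) {
  nb <- length(b)
  na <- length(a)
  if (is.null(state)) {
    state <- list(x_prev = numeric(nb - 1L), y_prev = numeric(na - 1L))
  }
  v <- stats::filter(c(rev(state$x_prev), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  y <- as.numeric(stats::filter(v, -a[2:na], method = "recursive",
                                init = state$y_prev))
  # carried tails are most-recent-first over the chronological history
  hist_x <- c(rev(state$x_prev), x)
  hist_y <- c(rev(state$y_prev), y)
  state$x_prev <- rev(utils::tail(hist_x, nb - 1L))
  state$y_prev <- rev(utils::tail(hist_y, na - 1L))
  list(y = y, state = state)
}

# Band-pass coefficients and noise gain for the background-EMG process. The
# gain g is the RMS amplification of unit white noise by the filter
# (sqrt of the summed squared impulse response), so dividing by g and
# multiplying by drive * sqrt(pi/2) makes the expected mean rectified value
# of the (approximately Gaussian) output equal the drive level: for X ~
# N(0, sigma^2), E|X| = sigma * sqrt(2/pi).
noise_shaper <- function(config) {
  bf <- signal::butter(2, config$noise_band_hz / (config$sample_rate / 2),
                       type = "pass")
  b <- as.numeric(bf$b)
  a <- as.numeric(bf$a)
  imp <- iir_block(c(1, numeric(4095)), b, a)$y
  list(b = b, a = a, gain = sqrt(sum(imp^2)))
}

# Ornstein-Uhlenbeck-like drive: AR(1) relaxation toward mu with stationary
# relative SD = drive_noise. Vectorized via the recursive filter.
ou_drive <- function(n, mu, rel_sd, tau_s, dt, last = mu) {
  if (rel_sd <= 0 || mu <= 0) return(rep(mu, n))
  a <- dt / tau_s
  sig <- rel_sd * mu * sqrt(2 / tau_s)
  innov <- a * mu + sig * sqrt(dt) * stats::rnorm(n)
  d <- as.numeric(stats::filter(innov, 1 - a, method = "recursive",
                                init = last))
  pmax(d, 0)
}

#' Synthesize a continuous multichannel EMG recording
#'
#' Generates the three channels a live recording would contain: the target
#' muscle (band-limited noise whose mean rectified level tracks the
#' participant's fluctuating drive, plus a calibrated biphasic M-wave and
#' H-reflex template after each stimulus), the antagonist muscle (low-level
#' noise), and the trigger loopback (a pulse at each stimulus).
#'
#' @param p A [virtual_participant()].
#' @param events Data frame of stimulus events with columns `time_s` and
#'   `intensity_mA` (may have zero rows).
#' @param duration_s Recording length, s.
#' @param config A [sim_config()].
#' @return A [sample_block()] with channels `target`, `antagonist`,
#'   `trigger_loopback`.
#' @export
synth_continuous <- function(p, events, duration_s, config = sim_config()) {
  stopifnot(inherits(p, "virtual_participant"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sample_rate
  n <- as.integer(round(duration_s * fs))
  if (nrow(events) > 0 && any(events$time_s < 0 | events$time_s > duration_s)) {
    stop("events must lie within the recording duration")
  }
  if (nrow(events) > 1 && any(diff(sort(events$time_s)) < 0.1)) {
    warning("stimulus events closer than the epoch span overlap")
  }
  sh <- noise_shaper(config)
  k <- sqrt(pi / 2) / sh$gain
  target <- iir_block(stats::rnorm(n), sh$b, sh$a)$y
  antag <- iir_block(stats::rnorm(n), sh$b, sh$a)$y
  drive <- ou_drive(n, p$background_drive, p$drive_noise, config$ou_tau_s,
                    1 / fs)
  target <- target * (drive * k)
  antag <- antag * (config$antagonist_drive * k)
  loop <- numeric(n)
  tmpl <- evoked_template(config$template_duration_ms, fs)
  add_template <- function(x, at, amp) {
    idx <- at + seq_along(tmpl) - 1L
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amp * tmpl[ok]
    x
  }
  pulse_n <- max(1L, as.integer(round(0.001 * fs)))
  for (i in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$time_s[i] * fs))
    I <- events$intensity_mA[i]
    amp_m <- max(0, m_amplitude(I, p) * (1 + p$response_noise * stats::rnorm(1)))
    amp_h <- max(0, h_amplitude(I, p) * (1 + p$response_noise * stats::rnorm(1)))
    target <- add_template(target, i0 + as.integer(round(p$latency_m_ms / 1000 * fs)), amp_m)
    target <- add_template(target, i0 + as.integer(round(p$latency_h_ms / 1000 * fs)), amp_h)
    j <- i0:min(n, i0 + pulse_n - 1L)
    loop[j[j >= 1L]] <- config$loopback_amplitude_mV
  }
  sample_block(rbind(target, antag, loop), fs,
               c("target", "antagonist", "trigger_loopback"), 0)
}

#' Simulate a recruitment-curve sweep trial by trial
#'
#' Synthesizes one short stimulus-locked recording per trial across an
#' intensity schedule (each intensity held for `trials_per_intensity`
#' consecutive trials) and measures the reference and target responses
#' through the standard epoch-extraction path.
#'
#' @param p A [virtual_participant()].
#' @param intensities Intensity ladder, mA.
#' @param trials_per_intensity Trials at each intensity; default 4.
#' @param config A [sim_config()].
#' @param windows A [response_windows()].
#' @param method Measurement method; see [response_size()].
#' @return A trial table (as from [measure_run()]) with `intensity_mA` set.
#' @export
simulate_sweep <- function(p, intensities = seq(5, 41, by = 2),
                           trials_per_intensity = 4,
                           config = sim_config(),
                           windows = response_windows(),
                           method = "peak_to_peak") {
  schedule <- rep(intensities, each = trials_per_intensity)
  fs <- config$sample_rate
  pre_s <- 0.05
  post_s <- 0.1
  t0 <- pre_s + 0.01  # stimulus onset, leaving a full pre-window
  rows <- vector("list", length(schedule))
  cfg1 <- config
  cfg1$seed <- NULL  # one seed for the sweep, set by the caller
  for (i in seq_along(schedule)) {
    ev <- data.frame(time_s = t0, intensity_mA = schedule[i])
    blk <- synth_continuous(p, ev, t0 + post_s + 0.01, cfg1)
    ep <- extract_epoch(blk, list(time_s = t0,
                                  frame = as.integer(round(t0 * fs))),
                        pre_s, post_s)
    m <- measure_trial(ep, windows, method)
    rows[[i]] <- data.frame(trial = i, time_s = (i - 1) * 5,
                            intensity_mA = schedule[i],
                            reference = m$reference$value,
                            target = m$target$value,
                            background = NA_real_, success = NA)
  }
  do.call(rbind, rows)
}
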