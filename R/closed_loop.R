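#' Full-system configuration for closed-loop simulation
#'
#' Bundles the simulator, signal-processing, triggering and measurement
#' settings that a live protocol would hold in its declarative configuration
#' file.
#'
#' @param sim A [sim_config()].
#' @param signal A [signal_config()]; defaults to the simulator sample rate.
#' @param trigger A [trigger_config()]. The default target range
#'   (0.01-0.04 mV) brackets the default virtual participant's standing
#'   drive; the antagonist is capped at 0.02 mV.
#' @param windows A [response_windows()].
#' @param method Measurement method; see [response_size()].
#' @param intensity_mA Stimulus intensity used for control and training
#'   trials, mA. Default 20: on the ascending slope of the default
#'   participant's H-reflex recruitment with a clearly visible M-wave.
#' @param rc_intensities,rc_trials_per_intensity Recruitment-curve intensity
#'   ladder (mA) and trials at each rung. Defaults: 5 to 41 mA in 2 mA steps,
#'   4 trials per step.
#' @param percentile Target percentile for conditioning criteria. Default 66.
#' @param direction Conditioning direction, `"down"` or `"up"`.
#' @param pre_s,post_s Epoch span, s.
#' @param st_trials Trials per stimulus-test run.
#' @param vc_duration_s,vc_peak_mV Voluntary-contraction run length and peak
#'   drive.
#' @return An object of class `closed_loop_config`.
#' @export
closed_loop_config <- function(sim = sim_config(),
                               signal = signal_config(sim$sample_rate),
                               trigger = trigger_config(
                                 target_range = range_spec(0.01, 0.04),
                                 antagonist_range = range_spec(NULL, 0.02)),
                               windows = response_windows(),
                               method = "peak_to_peak",
                               intensity_mA = 20,
                               rc_intensities = seq(5, 41, by = 2),
                               rc_trials_per_intensity = 4,
                               percentile = 66,
                               direction = c("down", "up"),
                               pre_s = 0.05, post_s = 0.1,
                               st_trials = 10,
                               vc_duration_s = 10, vc_peak_mV = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(sim, "sim_config"), inherits(signal, "signal_config"),
            inherits(trigger, "trigger_config"),
            inherits(windows, "response_windows"))
  if (abs(sim$sample_rate - signal$sample_rate) > 1e-9) {
    stop("simulator and signal-processing sample rates must match")
  }
  structure(
    list(sim = sim, signal = signal, trigger = trigger, windows = windows,
         method = method, intensity_mA = intensity_mA,
         rc_intensities = rc_intensities,
         rc_trials_per_intensity = rc_trials_per_intensity,
         percentile = percentile, direction = direction,
         pre_s = pre_s, post_s = post_s, st_trials = st_trials,
         vc_duration_s = vc_duration_s, vc_peak_mV = vc_peak_mV),
    class = "closed_loop_config"
  )
}

# Closed-loop buffers, kept in an environment and stored as fixed-size
# chunks (lists of vectors) so that per-event writes and state recovery touch
# only a few chunks instead of copying run-length arrays. Sequential
# generator states (band-pass noise filters, drive process) live alongside.
cl_state_new <- function(cfg) {
  st <- new.env(parent = emptyenv())
  fs <- cfg$sim$sample_rate
  st$L <- as.integer(fs)          # one-second chunks
  st$N <- 0L                      # frames generated (and processed)
  for (nm in c("raw_t", "raw_a", "raw_l", "filt_t", "rect_t",
               "trace_t", "trace_a")) {
    assign(nm, list(), envir = st)
  }
  st$shaper <- noise_shaper(cfg$sim)
  st$k <- sqrt(pi / 2) / st$shaper$gain
  st$bp_t <- NULL
  st$bp_a <- NULL
  st$hp_a_state <- hp_state_init()
  st$sm_a_state <- NULL
  st$drive_last <- NULL
  st$hp <- hp_coefs(cfg$signal)
  st$n_win <- max(1L, round(cfg$signal$background_window_s * fs))
  st$sm_a_state <- list(buf = numeric(0), seen = 0)
  st$tmpl <- evoked_template(cfg$sim$template_duration_ms, fs)
  st$pulse_n <- max(1L, as.integer(round(0.001 * fs)))
  st
}

# Read frames [lo, hi] of a chunked array as one vector.
cl_get <- function(st, name, lo, hi) {
  L <- st$L
  lst <- get(name, envir = st)
  c1 <- (lo - 1L) %/% L + 1L
  c2 <- (hi - 1L) %/% L + 1L
  if (c1 == c2) {
    off <- (c1 - 1L) * L
    return(lst[[c1]][(lo - off):(hi - off)])
  }
  parts <- vector("list", c2 - c1 + 1L)
  for (cc in c1:c2) {
    off <- (cc - 1L) * L
    a <- max(lo, off + 1L)
    b <- min(hi, off + L)
    parts[[cc - c1 + 1L]] <- lst[[cc]][(a - off):(b - off)]
  }
  unlist(parts, use.names = FALSE)
}

# Overwrite frames starting at lo with `values` (or add them with add = TRUE).
cl_set <- function(st, name, lo, values, add = FALSE) {
  L <- st$L
  lst <- get(name, envir = st)
  hi <- lo + length(values) - 1L
  c1 <- (lo - 1L) %/% L + 1L
  c2 <- (hi - 1L) %/% L + 1L
  for (cc in c1:c2) {
    off <- (cc - 1L) * L
    a <- max(lo, off + 1L)
    b <- min(hi, off + L)
    li <- (a - off):(b - off)
    vi <- (a - lo + 1L):(b - lo + 1L)
    if (add) lst[[cc]][li] <- lst[[cc]][li] + values[vi]
    else lst[[cc]][li] <- values[vi]
  }
  assign(name, lst, envir = st)
  invisible(NULL)
}

# Recompute filtered/rectified/trace for the target channel over [from, to],
# recovering the causal filter and window state from the stored arrays at
# from - 1. Exactly equals one-shot processing of the whole raw channel.
cl_process_target <- function(st, from, to) {
  if (to < from) return(invisible(NULL))
  f0 <- from - 1L
  hp_state <- if (f0 >= 1L) {
    list(x1 = cl_get(st, "raw_t", f0, f0),
         x2 = if (f0 >= 2L) cl_get(st, "raw_t", f0 - 1L, f0 - 1L) else 0,
         y1 = cl_get(st, "filt_t", f0, f0),
         y2 = if (f0 >= 2L) cl_get(st, "filt_t", f0 - 1L, f0 - 1L) else 0)
  } else hp_state_init()
  r <- hp_filter_block(cl_get(st, "raw_t", from, to), st$hp, hp_state)
  cl_set(st, "filt_t", from, r$y)
  rect <- abs(r$y)
  cl_set(st, "rect_t", from, rect)
  lo <- max(1L, f0 - st$n_win + 2L)
  sm_state <- list(buf = if (f0 >= 1L) cl_get(st, "rect_t", lo, f0)
                         else numeric(0),
                   seen = f0)
  s <- sliding_mean_block(rect, st$n_win, sm_state)
  cl_set(st, "trace_t", from, pmax(s$levels, 0))
  invisible(NULL)
}

# Generate one chunk of background signal (no evoked responses yet) and
# process it. Drive can be overridden with a deterministic profile.
cl_generate <- function(st, p, cfg, drive_profile = NULL) {
  n_new <- st$L
  fs <- cfg$sim$sample_rate
  cc <- st$N %/% st$L + 1L
  ft <- iir_block(stats::rnorm(n_new), st$shaper$b, st$shaper$a, st$bp_t)
  st$bp_t <- ft$state
  fa <- iir_block(stats::rnorm(n_new), st$shaper$b, st$shaper$a, st$bp_a)
  st$bp_a <- fa$state
  drive <- if (!is.null(drive_profile)) drive_profile else {
    d <- ou_drive(n_new, p$background_drive, p$drive_noise, cfg$sim$ou_tau_s,
                  1 / fs, last = if (is.null(st$drive_last)) p$background_drive
                                 else st$drive_last)
    st$drive_last <- d[n_new]
    d
  }
  st$raw_t[[cc]] <- ft$y * (drive * st$k)
  st$raw_a[[cc]] <- fa$y * (cfg$sim$antagonist_drive * st$k)
  st$raw_l[[cc]] <- numeric(n_new)
  from <- st$N + 1L
  st$N <- st$N + n_new
  # target: placeholder chunks, then recompute through the shared path
  st$filt_t[[cc]] <- numeric(n_new)
  st$rect_t[[cc]] <- numeric(n_new)
  st$trace_t[[cc]] <- numeric(n_new)
  cl_process_target(st, from, st$N)
  # antagonist: never reinjected, so its state streams forward
  ra <- hp_filter_block(st$raw_a[[cc]], st$hp, st$hp_a_state)
  st$hp_a_state <- ra$state
  sa <- sliding_mean_block(abs(ra$y), st$n_win, st$sm_a_state)
  st$sm_a_state <- sa$state
  st$trace_a[[cc]] <- pmax(sa$levels, 0)
  invisible(NULL)
}

# Add the evoked templates and loopback pulse for a stimulus at frame f,
# then reprocess the affected span. Returns the realized amplitudes.
cl_inject <- function(st, p, cfg, f, intensity) {
  fs <- cfg$sim$sample_rate
  amp_m <- max(0, m_amplitude(intensity, p) *
                 (1 + p$response_noise * stats::rnorm(1)))
  amp_h <- max(0, h_amplitude(intensity, p) *
                 (1 + p$response_noise * stats::rnorm(1)))
  at_m <- f + as.integer(round(p$latency_m_ms / 1000 * fs))
  at_h <- f + as.integer(round(p$latency_h_ms / 1000 * fs))
  nt <- length(st$tmpl)
  cl_set(st, "raw_t", at_m, amp_m * st$tmpl[seq_len(min(nt, st$N - at_m + 1L))],
         add = TRUE)
  cl_set(st, "raw_t", at_h, amp_h * st$tmpl[seq_len(min(nt, st$N - at_h + 1L))],
         add = TRUE)
  np <- min(st$pulse_n, st$N - f + 1L)
  cl_set(st, "raw_l", f, rep(cfg$sim$loopback_amplitude_mV, np), add = TRUE)
  cl_process_target(st, at_m, st$N)
  c(m = amp_m, h = amp_h)
}

# Assemble the channels x frames signal matrix of the first n frames.
cl_signals <- function(st, n) {
  m <- rbind(cl_get(st, "raw_t", 1L, n),
             cl_get(st, "raw_a", 1L, n),
             cl_get(st, "raw_l", 1L, n))
  rownames(m) <- c("target", "antagonist", "trigger_loopback")
  m
}

#' Simulate one closed-loop run
#'
#' Drives the virtual participant's signal generator, the background-level
#' pipeline, the per-frame stimulation gate, epoch measurement and (in `TT`
#' mode) reinforcement for a single run in any mode. Control and training
#' runs auto-complete after `n_trials` trials; a recruitment-curve run walks
#' the configured intensity ladder.
#'
#' @param p A [virtual_participant()].
#' @param mode Mode code: `"ST"`, `"VC"`, `"RC"`, `"CT"` or `"TT"`.
#' @param cfg A [closed_loop_config()].
#' @param n_trials Trials to perform; defaults to the mode's convention
#'   (the recruitment schedule length for `RC`, 75 otherwise).
#' @param criterion Required for `TT`: the [criterion_from_distribution()]
#'   to classify trials against.
#' @param intensity Stimulus intensity for non-`RC` modes; defaults to
#'   `cfg$intensity_mA`.
#' @return List with the completed `run` (an `epoc_run`) and the updated
#'   `participant`.
#' @export
simulate_run <- function(p, mode, cfg, n_trials = NULL, criterion = NULL,
                         intensity = NULL) {
  stopifnot(mode %in% c("ST", "VC", "RC", "CT", "TT"))
  fs <- cfg$sim$sample_rate
  dt <- 1 / fs
  if (mode == "VC") {
    n <- as.integer(round(cfg$vc_duration_s * fs))
    st <- cl_state_new(cfg)
    prof <- p$background_drive +
      (cfg$vc_peak_mV - p$background_drive) *
        (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1L)))
    while (st$N < n) {
      seg <- prof[pmin(st$N + seq_len(st$L), n)]  # hold final value past end
      cl_generate(st, p, cfg, drive_profile = seg)
    }
    return(list(run = cl_run_record(st, "VC", cfg, empty_events(),
                                    empty_trials(), criterion = NULL,
                                    n_keep = n),
                participant = p))
  }
  if (mode == "TT" && is.null(criterion)) {
    stop("a training-trials run requires a conditioning criterion")
  }
  schedule <- switch(mode,
    RC = rep(cfg$rc_intensities, each = cfg$rc_trials_per_intensity),
    NULL)
  if (is.null(n_trials)) {
    n_trials <- switch(mode, RC = length(schedule), ST = cfg$st_trials, 75L)
  }
  if (mode == "RC") n_trials <- min(n_trials, length(schedule))
  if (is.null(intensity)) intensity <- cfg$intensity_mA
  gate_mode <- if (mode == "ST") "stimulus_test" else "normal"
  interval_s <- mode_interval(cfg$trigger, gate_mode)
  pre_n <- as.integer(round(cfg$pre_s * fs))
  post_n <- as.integer(round(cfg$post_s * fs))
  margin <- post_n + as.integer(round(0.05 * fs))
  max_frames <- as.integer((n_trials * (interval_s + 40) + 60) * fs)

  st <- cl_state_new(cfg)
  tstate <- trigger_state()
  pos <- 1L
  done <- 0L
  ev_time <- ev_frame <- ev_int <- numeric(0)
  tr_ref <- tr_tgt <- tr_bg <- numeric(0)
  tr_success <- logical(0)
  last_f <- 0L
  truncated <- FALSE

  while (done < n_trials) {
    if (st$N < pos) cl_generate(st, p, cfg)
    mask <- if (gate_mode == "stimulus_test") rep(TRUE, st$N - pos + 1L) else {
      in_range(cl_get(st, "trace_t", pos, st$N), cfg$trigger$target_range) &
        in_range(cl_get(st, "trace_a", pos, st$N), cfg$trigger$antagonist_range)
    }
    sc <- gate_scan(mask, dt, cfg$trigger$hold_duration_s, interval_s, tstate)
    if (length(sc$frames) == 0L) {
      tstate <- sc$state
      pos <- st$N + 1L
      if (st$N > max_frames) {
        warning(sprintf("run stopped after %d of %d trials (time guard)",
                        done, n_trials))
        truncated <- TRUE
        break
      }
      next
    }
    f <- pos + sc$frames[1L] - 1L
    trial_i <- done + 1L
    I <- if (!is.null(schedule)) schedule[trial_i] else intensity
    while (st$N < f + margin) cl_generate(st, p, cfg)
    cl_inject(st, p, cfg, f, I)
    bg <- cl_get(st, "trace_t", f, f)
    wf <- rbind(cl_get(st, "raw_t", f - pre_n, f + post_n - 1L),
                cl_get(st, "raw_a", f - pre_n, f + post_n - 1L),
                cl_get(st, "raw_l", f - pre_n, f + post_n - 1L))
    rownames(wf) <- c("target", "antagonist", "trigger_loopback")
    ep <- structure(
      list(waveforms = wf,
           pre_s = cfg$pre_s, post_s = cfg$post_s, sample_rate = fs,
           event = list(time_s = f * dt, frame = f, trial_index = trial_i),
           background_at_trigger = c(target = bg,
                                     antagonist = cl_get(st, "trace_a", f, f))),
      class = "epoch")
    m <- measure_trial(ep, cfg$windows, cfg$method)
    success <- NA
    if (mode == "TT") {
      success <- classify_trial(m$target$value, criterion)
      p <- apply_reinforcement(p, success, cfg$direction)
    }
    ev_time <- c(ev_time, f * dt)
    ev_frame <- c(ev_frame, f)
    ev_int <- c(ev_int, I)
    tr_ref <- c(tr_ref, m$reference$value)
    tr_tgt <- c(tr_tgt, m$target$value)
    tr_bg <- c(tr_bg, bg)
    tr_success <- c(tr_success, success)
    done <- trial_i
    last_f <- f
    tstate <- trigger_state(0, 0)
    pos <- f + 1L
  }
  n_keep <- if (done > 0L) max(pos - 1L, last_f + margin) else st$N
  n_keep <- min(n_keep, st$N)
  events <- data.frame(time_s = ev_time, frame = as.integer(ev_frame),
                       trial_index = seq_len(done), intensity_mA = ev_int)
  trials <- data.frame(trial = seq_len(done), time_s = ev_time,
                       intensity_mA = ev_int, reference = tr_ref,
                       target = tr_tgt, background = tr_bg,
                       success = tr_success)
  list(run = cl_run_record(st, mode, cfg, events, trials, criterion, n_keep,
                           truncated),
       participant = p)
}

empty_events <- function() {
  data.frame(time_s = numeric(0), frame = integer(0),
             trial_index = integer(0), intensity_mA = numeric(0))
}

empty_trials <- function() {
  data.frame(trial = integer(0), time_s = numeric(0),
             intensity_mA = numeric(0), reference = numeric(0),
             target = numeric(0), background = numeric(0),
             success = logical(0))
}

cl_run_record <- function(st, mode, cfg, events, trials, criterion, n_keep,
                          truncated = FALSE) {
  signals <- cl_signals(st, n_keep)
  structure(
    list(mode = mode, sample_rate = cfg$sim$sample_rate,
         channel_roles = rownames(signals),
         signals = signals,
         events = events, trials = trials,
         background = background_trace(cl_get(st, "trace_t", 1L, n_keep),
                                       cfg$sim$sample_rate),
         config = cfg, criterion = criterion, truncated = truncated,
         notes = character(0)),
    class = "epoc_run"
  )
}

#' @export
print.epoc_run <- function(x, ...) {
  cat(sprintf("<epoc_run> mode %s: %d trials, %.1f s of signal @ %g Hz\n",
              x$mode, nrow(x$trials), ncol(x$signals) / x$sample_rate,
              x$sample_rate))
  invisible(x)
}

#' Run a full closed-loop protocol against a virtual participant
#'
#' Executes one or more session templates end to end: the virtual
#' participant supplies streaming EMG; the background-level pipeline, the
#' stimulation gate, epoch measurement and trial classification operate on
#' it exactly as in a live session; and in training runs each reinforced
#' trial feeds back into the participant's H-reflex excitability. In a
#' conditioning session the criterion is set from the control run at the
#' configured percentile and updated after every training run.
#'
#' @param p A [virtual_participant()].
#' @param plan A [session_template()], a list of them, or a data frame with
#'   columns `mode` and `trials`.
#' @param cfg A [closed_loop_config()].
#' @param seed Optional integer seed governing all randomness.
#' @param base_dir If non-`NULL`, each session is persisted there (run
#'   containers, sidecars and log) via the session module.
#' @param participant_id Participant ID used for persisted sessions.
#' @param now Clock value for the first session; subsequent sessions are
#'   stamped 2 days apart. Injectable for deterministic tests.
#' @return An object of class `closed_loop_result`: a list with `sessions`
#'   (each holding `runs`, `criteria`, and `meta` when persisted) and the
#'   final `participant` state.
#' @export
run_closed_loop <- function(p, plan, cfg = closed_loop_config(), seed = NULL,
                            base_dir = NULL, participant_id = "SIM01",
                            now = as.POSIXct("2024-01-01 10:00:00",
                                             tz = "UTC")) {
  if (!is.null(seed)) set.seed(seed)
  templates <- if (inherits(plan, "session_template")) list(plan)
               else if (is.data.frame(plan)) {
                 list(structure(list(kind = "custom", runs = plan),
                                class = "session_template"))
               } else plan
  sessions <- vector("list", length(templates))
  for (si in seq_along(templates)) {
    tpl <- templates[[si]]
    stopifnot(inherits(tpl, "session_template"))
    session_now <- now + (si - 1) * 2 * 86400
    meta <- if (!is.null(base_dir)) {
      start_or_continue_session(participant_id, now = session_now,
                                base_dir = base_dir)
    } else NULL
    criterion <- NULL
    runs <- vector("list", nrow(tpl$runs))
    criteria <- vector("list", nrow(tpl$runs))
    for (ri in seq_len(nrow(tpl$runs))) {
      mode <- as.character(tpl$runs$mode[ri])
      n_tr <- tpl$runs$trials[ri]
      res <- simulate_run(p, mode, cfg,
                          n_trials = if (is.na(n_tr)) NULL else n_tr,
                          criterion = criterion)
      p <- res$participant
      run <- res$run
      if (!is.null(meta)) {
        run$run_number <- next_run_number(meta)
        run$participant_id <- participant_id
        saved <- save_run(run, meta)
        append_log(meta,
                   sprintf("run %02d (%s): %d trials completed",
                           run$run_number, mode, nrow(run$trials)),
                   timestamp = session_now)
      }
      if (mode %in% c("CT", "TT") && nrow(run$trials) > 0L) {
        dist <- compute_distribution(run$trials$target, cfg$percentile)
        criterion <- criterion_from_distribution(dist,
                                                 direction = cfg$direction)
        if (!is.null(meta)) {
          log_criterion_adoption(meta, criterion, timestamp = session_now)
        }
      }
      runs[[ri]] <- run
      criteria[[ri]] <- criterion
    }
    sessions[[si]] <- list(kind = tpl$kind, runs = runs, criteria = criteria,
                           meta = meta)
  }
  structure(list(sessions = sessions, participant = p),
            class = "closed_loop_result")
}
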