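#' Mode codes
#'
#' The five modes of operation: `ST` Stimulus Test, `VC` Voluntary
#' Contraction, `RC` Recruitment Curve, `CT` Control Trials, `TT` Training
#' Trials.
#'
#' @param code Character scalar.
#' @return The validated code.
#' @export
mode_code <- function(code) {
  codes <- c("ST", "VC", "RC", "CT", "TT")
  if (!(is.character(code) && length(code) == 1L && code %in% codes)) {
    stop("mode must be one of: ", paste(codes, collapse = ", "))
  }
  code
}

session_stamp <- function(now) format(now, "%Y%m%d-%H%M", tz = "UTC")

parse_session_stamp <- function(stamp) {
  as.POSIXct(stamp, format = "%Y%m%d-%H%M", tz = "UTC")
}

#' Start a new session or continue a recent one
#'
#' Creates a new date-and-time-stamped data directory marked with the
#' participant ID, or -- if a session for that participant was started
#' within the last three hours -- binds to the existing directory so that an
#' interrupted session can be resumed with run numbering intact.
#'
#' @param participant_id Nonempty string.
#' @param now Clock value (POSIXct); injectable so tests are deterministic.
#' @param base_dir Directory under which session folders live.
#' @return An object of class `session_meta` with fields `participant_id`,
#'   `start_timestamp`, `dir`, `continuation`.
#' @export
start_or_continue_session <- function(participant_id,
                                      now = Sys.time(),
                                      base_dir = ".") {
  if (!is.character(participant_id) || nchar(participant_id) == 0L) {
    stop("participant_id must be a nonempty string")
  }
  if (!dir.exists(base_dir)) dir.create(base_dir, recursive = TRUE)
  existing <- list.dirs(base_dir, recursive = FALSE, full.names = FALSE)
  pat <- paste0("^\\d{8}-\\d{4}_", participant_id, "$")
  mine <- grep(pat, existing, value = TRUE)
  if (length(mine) > 0L) {
    stamps <- vapply(strsplit(mine, "_"), `[[`, "", 1L)
    times <- parse_session_stamp(stamps)
    latest <- which.max(as.numeric(times))
    age_h <- as.numeric(difftime(now, times[latest], units = "hours"))
    if (is.finite(age_h) && age_h >= 0 && age_h <= 3) {
      return(structure(
        list(participant_id = participant_id,
             start_timestamp = times[latest],
             dir = file.path(base_dir, mine[latest]), continuation = TRUE),
        class = "session_meta"))
    }
  }
  name <- paste0(session_stamp(now), "_", participant_id)
  dir.create(file.path(base_dir, name), recursive = TRUE)
  structure(
    list(participant_id = participant_id,
         start_timestamp = parse_session_stamp(session_stamp(now)),
         dir = file.path(base_dir, name), continuation = FALSE),
    class = "session_meta"
  )
}

#' @export
print.session_meta <- function(x, ...) {
  cat(sprintf("<session_meta> %s @ %s (%s)\n", x$participant_id,
              format(x$start_timestamp, "%Y-%m-%d %H:%M", tz = "UTC"),
              if (x$continuation) "continued" else "new"))
  invisible(x)
}

run_file_pattern <- "^\\d{8}-\\d{4}_.+_(ST|VC|RC|CT|TT)(\\d{2})\\.rds$"

#' Next sequential run number of a session
#'
#' Run numbers form a gap-free increasing sequence across modes within a
#' session; the next number is one past the highest already on disk.
#'
#' @param session A `session_meta`.
#' @return Integer run number.
#' @export
next_run_number <- function(session) {
  files <- list.files(session$dir, pattern = run_file_pattern)
  if (length(files) == 0L) return(1L)
  nn <- as.integer(sub(run_file_pattern, "\\2", files))
  max(nn) + 1L
}

run_basename <- function(session, mode, run_number) {
  sprintf("%s_%s_%s%02d", session_stamp(session$start_timestamp),
          session$participant_id, mode_code(mode), run_number)
}

#' Persist a run container
#'
#' Writes the run record (raw signals, events, trial table, config snapshot)
#' to `<stamp>_<id>_<MODE><NN>.rds` in the session directory, together with
#' a human-readable JSON sidecar. Run files are never overwritten:
#' attempting to reuse a filename is a hard error.
#'
#' @param run An `epoc_run` (see [run_closed_loop()]), with `run_number` set
#'   (or supplied here).
#' @param session A `session_meta`.
#' @param run_number Overrides `run$run_number` if given.
#' @return Invisibly, the path of the saved `.rds` file.
#' @export
save_run <- function(run, session, run_number = NULL) {
  stopifnot(inherits(run, "epoc_run"), inherits(session, "session_meta"))
  if (!is.null(run_number)) run$run_number <- run_number
  if (is.null(run$run_number)) stop("run has no run_number")
  base <- run_basename(session, run$mode, run$run_number)
  path <- file.path(session$dir, paste0(base, ".rds"))
  if (file.exists(path)) {
    stop("refusing to overwrite existing run file: ", path)
  }
  saveRDS(run, path)
  sidecar <- list(
    participant_id = session$participant_id,
    session_start = format(session$start_timestamp, "%Y-%m-%d %H:%M",
                           tz = "UTC"),
    mode = run$mode, run_number = run$run_number,
    sample_rate_hz = run$sample_rate,
    n_frames = ncol(run$signals), n_trials = nrow(run$trials),
    channel_roles = run$channel_roles
  )
  jsonlite::write_json(sidecar, file.path(session$dir, paste0(base, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a persisted run container
#'
#' @param path Path to a `.rds` run file written by [save_run()].
#' @return The `epoc_run` object, bit-identical to what was saved.
#' @export
load_run <- function(path) {
  run <- readRDS(path)
  stopifnot(inherits(run, "epoc_run"))
  run
}

#' Reserve the next run of a session
#'
#' Thin bookkeeping wrapper for callers that record signals themselves:
#' allocates the next run number and filename. [stop_run()] assembles the
#' record and persists it. At most one run may be in progress per session.
#'
#' @param session A `session_meta`.
#' @param mode A mode code (see [mode_code()]).
#' @return An object of class `run_handle`.
#' @export
start_run <- function(session, mode) {
  stopifnot(inherits(session, "session_meta"))
  lock <- file.path(session$dir, ".run_in_progress")
  if (file.exists(lock)) stop("a run is already in progress in this session")
  handle <- structure(
    list(session = session, mode = mode_code(mode),
         run_number = next_run_number(session)),
    class = "run_handle"
  )
  writeLines(run_basename(session, mode, handle$run_number), lock)
  handle
}

#' Complete and persist a reserved run
#'
#' @param handle A [start_run()] handle.
#' @param run An `epoc_run` record of the recorded signals and trials.
#' @return Invisibly, the saved path.
#' @export
stop_run <- function(handle, run) {
  stopifnot(inherits(handle, "run_handle"))
  lock <- file.path(handle$session$dir, ".run_in_progress")
  run$mode <- handle$mode
  path <- save_run(run, handle$session, run_number = handle$run_number)
  if (file.exists(lock)) file.remove(lock)
  invisible(path)
}

#' Background EMG level at maximum voluntary contraction
#'
#' The maximum of the target-muscle background trace over a
#' voluntary-contraction run, used in some protocols as the reference scale
#' for background-EMG range settings.
#'
#' @param run An `epoc_run` recorded in `VC` mode.
#' @return MVC level in mV.
#' @export
mvc_level <- function(run) {
  stopifnot(inherits(run, "epoc_run"))
  if (!identical(run$mode, "VC")) {
    stop("mvc_level requires a voluntary-contraction (VC) run")
  }
  max(run$background$levels)
}

log_path <- function(session) {
  file.path(session$dir,
            sprintf("%s_%s_log.txt", session_stamp(session$start_timestamp),
                    session$participant_id))
}

#' Append to the session log
#'
#' The log is an append-only, date-stamped plain-text file in the session
#' data directory; it is written (never rewritten) as entries arrive.
#'
#' @param session A `session_meta`.
#' @param text Character vector of lines.
#' @param timestamp Clock value for the entry.
#' @return Invisibly, the log path.
#' @export
append_log <- function(session, text, timestamp = Sys.time()) {
  stopifnot(inherits(session, "session_meta"))
  stamp <- format(timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  con <- file(log_path(session), open = "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s", stamp, text), con)
  invisible(log_path(session))
}

#' Automatically log the adoption of a conditioning criterion
#'
#' @param session A `session_meta`.
#' @param criterion A [criterion_from_distribution()] result.
#' @param timestamp Clock value.
#' @return Invisibly, the log path.
#' @export
log_criterion_adoption <- function(session, criterion,
                                   timestamp = Sys.time()) {
  stopifnot(inherits(criterion, "conditioning_criterion"))
  append_log(session,
             sprintf("criterion adopted: %s-conditioning, percentile %g, threshold %.6g mV",
                     criterion$direction, criterion$target_percentile,
                     criterion$threshold),
             timestamp)
}

#' Append a response-distribution summary to the session log
#'
#' @param session A `session_meta`.
#' @param dist A [compute_distribution()] result.
#' @param timestamp Clock value.
#' @return Invisibly, the log path.
#' @export
log_distribution_summary <- function(session, dist, timestamp = Sys.time()) {
  stopifnot(inherits(dist, "response_distribution"))
  append_log(session, c(
    sprintf("distribution summary: n %d, mean %.6g mV, median %.6g mV",
            dist$n, dist$mean, dist$median),
    sprintf("  percentile lines (P%g): up %.6g mV, down %.6g mV",
            dist$percentile, dist$percentile_lines[["up"]],
            dist$percentile_lines[["down"]])
  ), timestamp)
}

#' Session templates
#'
#' The ordered run plan of one session. A baseline session is an initial
#' recruitment curve, 3 runs of 75 control trials, and a final recruitment
#' curve; a conditioning session is a recruitment curve, 1 run of 20 control
#' trials, 3 runs of 75 training trials, and a final recruitment curve; a
#' follow-up session may be configured as either.
#'
#' @param kind `"baseline"`, `"conditioning"` or `"follow_up"`.
#' @param follow_up_style For follow-up sessions: which template to mirror.
#' @return An object of class `session_template` with a `runs` data frame
#'   (`mode`, `trials`; `NA` trials means mode-determined, as for a
#'   recruitment-curve sweep).
#' @export
session_template <- function(kind = c("baseline", "conditioning", "follow_up"),
                             follow_up_style = c("baseline", "conditioning")) {
  kind <- match.arg(kind)
  follow_up_style <- match.arg(follow_up_style)
  runs <- switch(kind,
    baseline = data.frame(
      mode = c("RC", "CT", "CT", "CT", "RC"),
      trials = c(NA, 75L, 75L, 75L, NA)),
    conditioning = data.frame(
      mode = c("RC", "CT", "TT", "TT", "TT", "RC"),
      trials = c(NA, 20L, 75L, 75L, 75L, NA)),
    follow_up = session_template(follow_up_style)$runs
  )
  structure(list(kind = kind, runs = runs), class = "session_template")
}

#' @export
print.session_template <- function(x, ...) {
  cat(sprintf("<session_template> %s: %s\n", x$kind,
              paste(sprintf("%s%s", x$runs$mode,
                            ifelse(is.na(x$runs$trials), "",
                                   paste0("(", x$runs$trials, ")"))),
                    collapse = ", ")))
  invisible(x)
}

#' Plan a full conditioning protocol
#'
#' 6 baseline sessions, 24 conditioning sessions (30 for people with
#' neurological impairment) and 4 follow-up sessions, in order.
#'
#' @param impaired Logical: schedule 30 rather than 24 conditioning
#'   sessions.
#' @param follow_up_style Template style of the follow-up sessions.
#' @return List of [session_template()] objects.
#' @export
plan_protocol <- function(impaired = FALSE,
                          follow_up_style = c("baseline", "conditioning")) {
  follow_up_style <- match.arg(follow_up_style)
  n_cond <- if (impaired) 30L else 24L
  c(replicate(6, session_template("baseline"), simplify = FALSE),
    replicate(n_cond, session_template("conditioning"), simplify = FALSE),
    replicate(4, session_template("follow_up", follow_up_style),
              simplify = FALSE))
}
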