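#' Pool consecutive trials
#'
#' Averages consecutive groups of `k` response sizes in order; a final
#' partial group is averaged over its actual size. Used to pair pooled
#' responses with the stimulus intensity that was held constant across each
#' group during a recruitment-curve run.
#'
#' @param sizes Numeric vector of per-trial response sizes, mV.
#' @param k Trials to pool per group (>= 1).
#' @return Numeric vector of group means.
#' @export
pool_trials <- function(sizes, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (length(sizes) == 0L) return(numeric(0))
  g <- (seq_along(sizes) - 1L) %/% k
  as.numeric(tapply(sizes, g, mean))
}

#' Build a recruitment curve from a trial table
#'
#' Pools consecutive trials (the stimulus current is typically increased
#' every `pool` trials during a recruitment-curve run), pairs each pooled
#' group with its stimulus intensity, and records the maxima `m_max` (largest
#' pooled reference/M-wave size) and `h_max` (largest pooled target/H-reflex
#' size).
#'
#' @param trials Data frame with columns `reference` and `target` (as from
#'   [measure_run()]), in trial order.
#' @param intensities Optional per-trial stimulus intensities (mA). If the
#'   length does not match the trial count the schedule is ignored with a
#'   warning and the pooled-group index is used instead.
#' @param pool Trials to pool; default 4.
#' @param method Label recording how sizes were measured.
#' @return An object of class `recruitment_curve` with a `points` data frame
#'   (`intensity`, `reference`, `target`, `n`), `pool_size`, `m_max`,
#'   `h_max`, `method`.
#' @export
build_recruitment_curve <- function(trials, intensities = NULL, pool = 4,
                                    method = "peak_to_peak") {
  stopifnot(is.data.frame(trials), all(c("reference", "target") %in% names(trials)))
  n <- nrow(trials)
  if (n < pool) stop("need at least `pool` trials")
  ref <- pool_trials(trials$reference, pool)
  tgt <- pool_trials(trials$target, pool)
  g <- (seq_len(n) - 1L) %/% as.integer(pool)
  counts <- as.integer(table(g))
  if (!is.null(intensities) && length(intensities) != n) {
    warning("intensity schedule length does not match trial count; ",
            "using pooled-group index instead")
    intensities <- NULL
  }
  intensity <- if (is.null(intensities)) seq_along(ref)
               else as.numeric(tapply(intensities, g, mean))
  structure(
    list(points = data.frame(intensity = intensity, reference = ref,
                             target = tgt, n = counts),
         pool_size = as.integer(pool),
         m_max = max(ref), h_max = max(tgt), method = method),
    class = "recruitment_curve"
  )
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf(
    "<recruitment_curve> %d pooled points (pool %d, %s); M_max %.4g mV, H_max %.4g mV\n",
    nrow(x$points), x$pool_size, x$method, x$m_max, x$h_max))
  invisible(x)
}

#' Distribution of target response sizes
#'
#' Summarizes the response sizes of a control (or training) run: mean,
#' median, count, and the three percentile lines used to set conditioning
#' criteria (median, up-criterion, down-criterion at the configured target
#' percentile). Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7) so thresholds are reproducible bit-exactly.
#'
#' @param sizes Numeric vector of target response sizes, mV (at least one).
#' @param percentile Target percentile in (0, 100]; default 66.
#' @return An object of class `response_distribution` with fields `sizes`,
#'   `n`, `mean`, `median`, `percentile`, and `percentile_lines` (named:
#'   `median`, `up`, `down`).
#' @export
compute_distribution <- function(sizes, percentile = 66) {
  if (length(sizes) < 1L) stop("empty response-size sample")
  if (!(percentile > 0 && percentile <= 100)) {
    stop("percentile must lie in (0, 100]")
  }
  q <- function(p) as.numeric(stats::quantile(sizes, p / 100, type = 7, names = FALSE))
  structure(
    list(sizes = as.numeric(sizes), n = length(sizes),
         mean = mean(sizes), median = stats::median(sizes),
         percentile = percentile,
         percentile_lines = c(median = stats::median(sizes),
                              up = q(100 - percentile), down = q(percentile))),
    class = "response_distribution"
  )
}

#' @export
print.response_distribution <- function(x, ...) {
  cat(sprintf(
    "<response_distribution> n %d, mean %.4g, median %.4g mV; P%g lines: up %.4g, down %.4g\n",
    x$n, x$mean, x$median, x$percentile,
    x$percentile_lines[["up"]], x$percentile_lines[["down"]]))
  invisible(x)
}

#' Derive a conditioning criterion from a response distribution
#'
#' For down-conditioning the threshold is the P-th percentile of the defining
#' sample and a trial succeeds when its size is at or below it (the bottom
#' P% of the previously measured distribution); for up-conditioning the
#' threshold is the (100 - P)-th percentile and success is at or above it
#' (the top P%).
#'
#' @param dist A [compute_distribution()] result, or a raw numeric sample.
#' @param percentile Target percentile in (0, 100]; default 66, or the value
#'   stored in `dist`. At the boundary P = 100 the threshold is the sample
#'   extremum and every trial of the defining sample is successful.
#' @param direction `"down"` or `"up"`.
#' @return An object of class `conditioning_criterion` with fields
#'   `direction`, `threshold` (mV), `target_percentile`.
#' @export
criterion_from_distribution <- function(dist, percentile = NULL,
                                        direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!inherits(dist, "response_distribution")) {
    dist <- compute_distribution(dist,
                                 percentile = if (is.null(percentile)) 66 else percentile)
  }
  if (is.null(percentile)) percentile <- dist$percentile
  if (!(percentile > 0 && percentile <= 100)) {
    stop("percentile must lie in (0, 100]")
  }
  p <- if (direction == "down") percentile else 100 - percentile
  threshold <- as.numeric(stats::quantile(dist$sizes, p / 100, type = 7,
                                          names = FALSE))
  structure(
    list(direction = direction, threshold = threshold,
         target_percentile = percentile),
    class = "conditioning_criterion"
  )
}

#' @export
print.conditioning_criterion <- function(x, ...) {
  cat(sprintf("<conditioning_criterion> %s-conditioning, threshold %.4g mV (P%g)\n",
              x$direction, x$threshold, x$target_percentile))
  invisible(x)
}

#' Classify a trial against a conditioning criterion
#'
#' Down-conditioning: success iff size <= threshold. Up-conditioning:
#' success iff size >= threshold. Ties at the threshold count as success in
#' both directions (deterministic and participant-favorable).
#'
#' @param size Numeric vector of target response sizes, mV.
#' @param criterion A [criterion_from_distribution()] result.
#' @return Logical vector of success flags.
#' @export
classify_trial <- function(size, criterion) {
  stopifnot(inherits(criterion, "conditioning_criterion"))
  if (criterion$direction == "down") size <= criterion$threshold
  else size >= criterion$threshold
}

#' Cumulative success rate
#'
#' The running percentage of successful trials after each trial, as shown on
#' the participant's feedback display.
#'
#' @param outcomes Logical vector of per-trial success flags.
#' @return Numeric vector of the same length: `100 * cumsum / seq_along`.
#'   Zero trials yield a zero-length result (displayed as blank).
#' @export
success_rate <- function(outcomes) {
  if (length(outcomes) == 0L) return(numeric(0))
  stopifnot(is.logical(outcomes), !anyNA(outcomes))
  100 * cumsum(outcomes) / seq_along(outcomes)
}

#' Retrospective check of reference-response constancy
#'
#' The M-wave reflects the number of motor axons excited by the stimulus, so
#' keeping it roughly constant implies constant effective stimulation of the
#' afferents that elicit the H-reflex. This check compares a run's reference
#' sizes against the nominal size noted when the conditioning intensity was
#' chosen, flagging the run when its mean deviates by more than the
#' tolerance, and listing per-trial relative deviations so the onset of a
#' drift can be located.
#'
#' @param reference_sizes Numeric vector of per-trial reference sizes, mV.
#' @param nominal Nominal reference size, mV (> 0).
#' @param tolerance_pct Allowed relative deviation, percent of nominal;
#'   default 15.
#' @return An object of class `stability_report`: `nominal`, `run_mean`,
#'   `deviation` (relative, signed), `per_trial_deviation`, `trial_flags`,
#'   `first_flagged_trial` (NA if none), `flagged`.
#' @export
assess_reference_stability <- function(reference_sizes, nominal,
                                       tolerance_pct = 15) {
  if (length(reference_sizes) < 1L) stop("no reference sizes supplied")
  if (!(nominal > 0)) stop("nominal reference size must be > 0")
  tol <- tolerance_pct / 100
  dev <- (reference_sizes - nominal) / nominal
  run_mean <- mean(reference_sizes)
  flags <- abs(dev) > tol
  structure(
    list(nominal = nominal, run_mean = run_mean,
         deviation = (run_mean - nominal) / nominal,
         per_trial_deviation = dev, trial_flags = flags,
         first_flagged_trial = if (any(flags)) which(flags)[1L] else NA_integer_,
         tolerance_pct = tolerance_pct,
         flagged = abs(run_mean - nominal) > tol * nominal),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> run mean %.4g mV vs nominal %.4g mV (%+.1f%%): %s\n",
    x$run_mean, x$nominal, 100 * x$deviation,
    if (x$flagged) "FLAGGED" else "within tolerance"))
  invisible(x)
}
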