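#' Specify a synthetic unit
#'
#' Describes the ground-truth response profile of one simulated unit: a
#' baseline firing rate, additive rate changes during the stimulus and choice
#' windows, and per-condition gamma-renewal shape parameters. A classically
#' responsive (CR) unit carries its task information in `stim_delta` /
#' `choice_delta`; a non-classically responsive (NCR) unit is rate-flat
#' (deltas 0) but may differ between conditions in ISI shape, so that spike
#' timing - not rate - codes the stimulus.
#'
#' @param unit_id Unit identifier (coerced to character).
#' @param baseline_rate Baseline rate, spikes/s, > 0.
#' @param stim_delta Signed rate change (spikes/s) during the tone window.
#' @param choice_delta Signed rate change (spikes/s) during the 100-ms choice
#'   window.
#' @param isi_shape_target,isi_shape_nontarget Gamma-renewal shape parameters
#'   (> 0) in effect between tone onset and the end of the response window on
#'   target / nontarget trials. Shape 1 is Poisson; shape > 1 is more regular
#'   firing, < 1 burstier.
#' @param true_label Ground-truth label, `"CR"` or `"NCR"`.
#' @return A `unit_gen_spec` list.
#' @export
unit_gen_spec <- function(unit_id, baseline_rate, stim_delta = 0,
                          choice_delta = 0, isi_shape_target = 1,
                          isi_shape_nontarget = 1,
                          true_label = c("CR", "NCR")) {
  true_label <- match.arg(true_label)
  stopifnot(baseline_rate > 0, isi_shape_target > 0, isi_shape_nontarget > 0)
  if (baseline_rate + min(stim_delta, 0) < 0 ||
      baseline_rate + min(choice_delta, 0) < 0) {
    stop("negative instantaneous rate: baseline_rate + delta < 0")
  }
  structure(
    list(unit_id = as.character(unit_id), baseline_rate = baseline_rate,
         stim_delta = stim_delta, choice_delta = choice_delta,
         isi_shape_target = isi_shape_target,
         isi_shape_nontarget = isi_shape_nontarget, true_label = true_label),
    class = "unit_gen_spec")
}

#' Specify a synthetic session
#'
#' Trial structure mirrors the behavioral task: 100-ms tones, a 2.5-s
#' response window, inter-tone onset intervals drawn uniformly from 3-7 s.
#' `shared_gain_sd` controls a per-trial multiplicative gain (log-normal,
#' mean 1) shared by all units, which induces positive pairwise spike-count
#' correlations without changing any unit's ground-truth label.
#'
#' @param n_units,n_trials Counts.
#' @param p_target Probability a trial is a target trial (exact counts are
#'   used: `round(n_trials * p_target)` targets, shuffled).
#' @param tone_duration,response_window Seconds; defaults 0.1 and 2.5.
#' @param iti_range Inter-trial onset interval range, seconds.
#' @param shared_gain_sd Standard deviation of log gain, >= 0.
#' @param p_hit,p_fa Per-trial probabilities of a response on target /
#'   nontarget trials (drive hit / false-alarm outcomes).
#' @param seed Integer seed; the session is a pure function of the spec.
#' @return A `session_gen_spec` list.
#' @export
session_gen_spec <- function(n_units, n_trials, p_target = 0.5,
                             tone_duration = 0.1, response_window = 2.5,
                             iti_range = c(3, 7), shared_gain_sd = 0,
                             p_hit = 0.85, p_fa = 0.2, seed = 1L) {
  stopifnot(n_units >= 1, n_trials >= 2, p_target > 0, p_target < 1,
            tone_duration < response_window, shared_gain_sd >= 0,
            p_hit > 0, p_hit < 1, p_fa > 0, p_fa < 1)
  structure(
    list(n_units = as.integer(n_units), n_trials = as.integer(n_trials),
         p_target = p_target, tone_duration = tone_duration,
         response_window = response_window, iti_range = iti_range,
         shared_gain_sd = shared_gain_sd, p_hit = p_hit, p_fa = p_fa,
         seed = as.integer(seed)),
    class = "session_gen_spec")
}

# Draw one gamma-renewal segment on [a, b) with rate `rate` and shape `shape`.
# The first event time is drawn from the equilibrium (stationary
# forward-recurrence) distribution U * Gamma(shape + 1, shape * rate), so the
# expected number of events in the segment is exactly rate * (b - a) for any
# shape; subsequent intervals are ordinary Gamma(shape, shape * rate).
draw_segment <- function(a, b, rate, shape) {
  len <- b - a
  if (rate <= 0 || len <= 0) return(numeric(0))
  t0 <- a + runif(1) * rgamma(1, shape + 1, rate = shape * rate)
  if (t0 >= b) return(numeric(0))
  times <- t0
  # draw ISIs in batches until past the segment end
  cur <- t0
  repeat {
    nbatch <- max(8L, ceiling((b - cur) * rate * 1.5))
    isis <- rgamma(nbatch, shape, rate = shape * rate)
    tt <- cur + cumsum(isis)
    keep <- tt < b
    times <- c(times, tt[keep])
    if (!all(keep)) break
    cur <- tt[length(tt)]
  }
  times
}

#' Simulate one unit's spike train for a session
#'
#' Generates a gamma-renewal spike train whose rate is piecewise constant:
#' `baseline_rate * gain` inside each trial span, `baseline_rate +
#' stim_delta` (times gain) during the tone, and `baseline_rate +
#' choice_delta` (times gain) in the 100-ms choice window (centered on the
#' trial's response on go trials, or on the session's mean go latency on
#' no-go trials; the choice window takes precedence where it overlaps the
#' tone). The ISI shape parameter between tone onset and the end of the
#' response window is set per trial by the stimulus condition; elsewhere the
#' process is Poisson (shape 1). The renewal age is reset at every rate or
#' shape boundary, with each segment started from the equilibrium
#' distribution so finite-window rates are unbiased. Spikes closer than 1 ms
#' to the previous spike are deleted (refractory period).
#'
#' @param spec A [unit_gen_spec()].
#' @param trials A trial table as produced by [simulate_session()] (columns
#'   `onset_s`, `stimulus`, `response_time_s`, `outcome`).
#' @param gain Per-trial positive multiplicative gains (length = rows of
#'   `trials`); use `rep(1, nrow(trials))` for none.
#' @param seed Integer seed.
#' @param tone_duration,response_window Seconds.
#' @param session_end End of the simulated span; defaults to last onset +
#'   `response_window` + 1.
#' @return Sorted numeric vector of spike times (seconds).
#' @export
simulate_unit <- function(spec, trials, gain, seed,
                          tone_duration = 0.1, response_window = 2.5,
                          session_end = NULL) {
  stopifnot(inherits(spec, "unit_gen_spec"))
  if (is.null(trials) || nrow(trials) == 0) stop("empty trials")
  if (length(gain) != nrow(trials)) stop("gain length must equal n trials")
  if (any(gain <= 0)) stop("gains must be positive")
  onsets <- trials$onset_s
  if (is.unsorted(onsets)) stop("trials must be ordered by onset")
  span_start <- onsets - 0.5
  span_end <- onsets + response_window
  if (any(span_start[-1] < span_end[-length(span_end)])) {
    stop("trials overlap in session time")
  }
  if (is.null(session_end)) session_end <- max(span_end) + 1

  go <- !is.na(trials$response_time_s)
  mean_lat <- if (any(go)) mean(trials$response_time_s[go] - onsets[go]) else 0.5
  centers <- ifelse(go, trials$response_time_s, onsets + mean_lat)

  with_seed(seed, {
    spikes <- vector("list", nrow(trials) * 4L + 1L)
    si <- 0L
    cursor <- 0
    for (t in seq_len(nrow(trials))) {
      on <- onsets[t]
      g <- gain[t]
      shape_t <- if (trials$stimulus[t] == "target") spec$isi_shape_target
                 else spec$isi_shape_nontarget
      # inter-trial gap: baseline rate, Poisson, gain 1
      si <- si + 1L
      spikes[[si]] <- draw_segment(cursor, on, spec$baseline_rate, 1)
      # breakpoints within the trial span [onset, onset + response_window)
      c0 <- max(on, centers[t] - 0.05)
      c1 <- min(on + response_window, centers[t] + 0.05)
      brk <- sort(unique(c(on, on + tone_duration, c0, c1,
                           on + response_window)))
      brk <- brk[brk >= on & brk <= on + response_window]
      for (s in seq_len(length(brk) - 1L)) {
        a <- brk[s]; b <- brk[s + 1L]
        mid <- (a + b) / 2
        r <- spec$baseline_rate
        if (mid >= on && mid < on + tone_duration) r <- r + spec$stim_delta
        if (mid >= c0 && mid < c1) {
          r <- spec$baseline_rate + spec$choice_delta  # choice overrides tone
        }
        si <- si + 1L
        spikes[[si]] <- draw_segment(a, b, r * g, shape_t)
      }
      cursor <- on + response_window
    }
    si <- si + 1L
    spikes[[si]] <- draw_segment(cursor, session_end, spec$baseline_rate, 1)
    out <- sort(unlist(spikes[seq_len(si)]))
    # enforce 1-ms refractory period by deletion
    while (length(out) > 1 && any(diff(out) < 0.001)) {
      out <- out[c(TRUE, diff(out) >= 0.001)]
    }
    out
  })
}

#' Simulate a session of simultaneously recorded units
#'
#' Builds one shared trial table (onsets, stimulus labels, outcomes, response
#' times) and generates every unit's spike train against it with a shared
#' per-trial log-normal gain, then returns the ground truth needed to score
#' any downstream stage.
#'
#' @param spec A [session_gen_spec()].
#' @param unit_specs List of [unit_gen_spec()]s (length `spec$n_units`).
#' @return A `recording_session` list with elements `trials` (data frame:
#'   `trial_id`, `onset_s`, `stimulus`, `response_time_s`, `outcome`),
#'   `spikes` (named list of spike-time vectors), and `ground_truth` (unit
#'   specs, gains, and the session spec).
#' @export
simulate_session <- function(spec, unit_specs) {
  stopifnot(inherits(spec, "session_gen_spec"),
            length(unit_specs) == spec$n_units)
  for (u in unit_specs) stopifnot(inherits(u, "unit_gen_spec"))
  seeds <- derive_seeds(spec$seed, spec$n_units + 1L)
  trial_bits <- with_seed(seeds[1], {
    n <- spec$n_trials
    n_target <- round(n * spec$p_target)
    stimulus <- sample(rep(c("target", "nontarget"), c(n_target, n - n_target)))
    iti <- runif(n, spec$iti_range[1], spec$iti_range[2])
    onset <- cumsum(iti)
    respond <- ifelse(stimulus == "target",
                      rbinom(n, 1, spec$p_hit), rbinom(n, 1, spec$p_fa)) == 1
    lat <- pmin(pmax(exp(rnorm(n, log(0.6), 0.35)), 0.15),
                spec$response_window - 0.1)
    gain <- if (spec$shared_gain_sd > 0) {
      exp(rnorm(n, -spec$shared_gain_sd^2 / 2, spec$shared_gain_sd))
    } else rep(1, n)
    list(stimulus = stimulus, onset = onset, respond = respond, lat = lat,
         gain = gain)
  })
  outcome <- with(trial_bits, ifelse(
    stimulus == "target", ifelse(respond, "hit", "miss"),
    ifelse(respond, "false_alarm", "correct_reject")))
  trials <- data.frame(
    trial_id = seq_len(spec$n_trials),
    onset_s = trial_bits$onset,
    stimulus = trial_bits$stimulus,
    response_time_s = ifelse(trial_bits$respond,
                             trial_bits$onset + trial_bits$lat, NA_real_),
    outcome = outcome,
    stringsAsFactors = FALSE)
  spikes <- lapply(seq_along(unit_specs), function(i) {
    simulate_unit(unit_specs[[i]], trials, trial_bits$gain, seeds[i + 1L],
                  tone_duration = spec$tone_duration,
                  response_window = spec$response_window)
  })
  names(spikes) <- vapply(unit_specs, `[[`, character(1), "unit_id")
  structure(
    list(trials = trials, spikes = spikes,
         ground_truth = list(unit_specs = unit_specs, gain = trial_bits$gain,
                             session_spec = spec)),
    class = "recording_session")
}

#' Simulate a multi-day learning curve
#'
#' Per-day binomial draws of hits and false alarms against specified
#' trajectories, returning trial-level outcome tables from which d' and
#' percent correct can be recomputed.
#'
#' @param days Number of training days.
#' @param hit_traj,fa_traj Per-day hit / false-alarm probabilities in (0,1)
#'   (length `days`, or length 1 recycled).
#' @param trials_per_day Trials per day (split evenly target/nontarget).
#' @param seed Integer seed.
#' @return List with `sessions` (list of per-day trial data frames with
#'   `stimulus` and `outcome`) and `summary` (data frame: `day`, `hits`,
#'   `false_alarms`, `n_target`, `n_nontarget`).
#' @export
simulate_learning_curve <- function(days, hit_traj, fa_traj, trials_per_day,
                                    seed) {
  if (days < 1) stop("empty trajectory")
  hit_traj <- rep_len(hit_traj, days)
  fa_traj <- rep_len(fa_traj, days)
  stopifnot(all(hit_traj > 0 & hit_traj < 1), all(fa_traj > 0 & fa_traj < 1))
  n_t <- ceiling(trials_per_day / 2)
  n_n <- trials_per_day - n_t
  with_seed(seed, {
    sessions <- vector("list", days)
    summ <- data.frame(day = seq_len(days), hits = NA_integer_,
                       false_alarms = NA_integer_, n_target = n_t,
                       n_nontarget = n_n)
    for (d in seq_len(days)) {
      resp_t <- rbinom(n_t, 1, hit_traj[d]) == 1
      resp_n <- rbinom(n_n, 1, fa_traj[d]) == 1
      sessions[[d]] <- data.frame(
        day = d,
        stimulus = rep(c("target", "nontarget"), c(n_t, n_n)),
        outcome = c(ifelse(resp_t, "hit", "miss"),
                    ifelse(resp_n, "false_alarm", "correct_reject")),
        stringsAsFactors = FALSE)
      summ$hits[d] <- sum(resp_t)
      summ$false_alarms[d] <- sum(resp_n)
    }
    list(sessions = sessions, summary = summ)
  })
}

#' Simulate a kinematic speed trace with a step change
#'
#' @param n_frames Trace length in frames (> 0).
#' @param onset_frame Frame of the speed step; must leave 100 frames on both
#'   sides.
#' @param pre_speed,post_speed Mean speed before / from the onset frame.
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of per-frame speeds.
#' @export
simulate_speed_trace <- function(n_frames, onset_frame, pre_speed, post_speed,
                                 noise_sd = 0, seed = 1L) {
  if (n_frames <= 0) stop("zero-length trace")
  if (onset_frame <= 100 || onset_frame >= n_frames - 100) {
    stop("onset too close to trace edges (need 100 frames on both sides)")
  }
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    base <- c(rep(pre_speed, onset_frame - 1), rep(post_speed,
                                                   n_frames - onset_frame + 1))
    base + rnorm(n_frames, 0, noise_sd)
  })
}

#' Ground-truth unit specs for a mixed population
#'
#' Draws unit specs emulating the recorded population: log-normal baseline
#' rates (median ~4 spikes/s with a wide spread, matching typical
#' spontaneous-rate distributions in auditory cortex), a fraction of
#' rate-flat NCR units, and CR units carrying a clear stimulus rate change.
#' NCR units optionally code the stimulus in ISI shape alone (gamma shape
#' differing between conditions at matched rate).
#'
#' @param n_units Number of units.
#' @param p_ncr Fraction of NCR units (default 0.5).
#' @param seed Integer seed.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline-rate
#'   parameters (defaults `log(4)` and 0.6); rates are truncated to
#'   \[1, 20\] spikes/s.
#' @param stim_delta_cr Stimulus rate change for CR units (spikes/s,
#'   default 5; recycled or sampled if length > 1).
#' @param ncr_shapes Length-2 vector of target/nontarget gamma shapes for
#'   timing-coding NCR units (default `c(0.6, 2.5)`); use `c(1, 1)` for
#'   uninformative NCR units.
#' @return List of [unit_gen_spec()]s with `true_label` set.
#' @export
population_gen_specs <- function(n_units, p_ncr = 0.5, seed = 1L,
                                 baseline_meanlog = log(4),
                                 baseline_sdlog = 0.6, stim_delta_cr = 5,
                                 ncr_shapes = c(0.6, 2.5)) {
  n_ncr <- round(n_units * p_ncr)
  with_seed(seed, {
    base <- pmin(pmax(exp(rnorm(n_units, baseline_meanlog, baseline_sdlog)),
                      1), 20)
    deltas <- rep_len(stim_delta_cr, n_units)
    lapply(seq_len(n_units), function(i) {
      if (i <= n_units - n_ncr) {
        unit_gen_spec(sprintf("cr%03d", i), base[i], stim_delta = deltas[i],
                      true_label = "CR")
      } else {
        unit_gen_spec(sprintf("ncr%03d", i), base[i], stim_delta = 0,
                      isi_shape_target = ncr_shapes[1],
                      isi_shape_nontarget = ncr_shapes[2], true_label = "NCR")
      }
    })
  })
}
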