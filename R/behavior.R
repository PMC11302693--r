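#' Behavioral sensitivity (d') and percent correct
#'
#' d' = z(hit rate) - z(false-alarm rate), the standard signal-detection
#' convention for go/no-go data (it supports negative values after a rule
#' reversal). Rates are clipped to `[clip, 1 - clip]` per stimulus class
#' before the probit transform; by default `clip = 1/(2N)` with N the number
#' of trials of that class, so perfect performance stays finite.
#'
#' @param trials Trial data frame with columns `stimulus`
#'   (`"target"`/`"nontarget"`) and `outcome` (`"hit"`, `"miss"`,
#'   `"false_alarm"`, `"correct_reject"`).
#' @param clip Optional fixed clipping probability; `NULL` for 1/(2N).
#' @return List with `dprime`, `percent_correct`, `hit_rate`, `fa_rate`,
#'   `n_trials`.
#' @export
compute_dprime <- function(trials, clip = NULL) {
  is_t <- trials$stimulus == "target"
  n_t <- sum(is_t)
  n_n <- sum(!is_t)
  if (n_t == 0 || n_n == 0) stop("need >= 1 trial of each stimulus class")
  hits <- sum(trials$outcome == "hit")
  fas <- sum(trials$outcome == "false_alarm")
  crs <- sum(trials$outcome == "correct_reject")
  clip_t <- if (is.null(clip)) 1 / (2 * n_t) else clip
  clip_n <- if (is.null(clip)) 1 / (2 * n_n) else clip
  h <- min(max(hits / n_t, clip_t), 1 - clip_t)
  f <- min(max(fas / n_n, clip_n), 1 - clip_n)
  list(dprime = qnorm(h) - qnorm(f),
       percent_correct = 100 * (hits + crs) / (n_t + n_n),
       hit_rate = hits / n_t, fa_rate = fas / n_n, n_trials = n_t + n_n)
}

#' Segment a learning curve into early / late / expert phases
#'
#' Progress for a session is `(d' - min d') / (max d' - min d')` over the
#' supplied block of sessions (compute per animal and per pre-/post-reversal
#' block). Sessions meeting the expert criteria (d' >= 1.5 and percent
#' correct >= 70) are labeled `expert` regardless of progress; otherwise
#' progress < 40% is `early` and the rest is `late`.
#'
#' @param dprime Per-session d' values (>= 2 sessions).
#' @param percent_correct Per-session percent correct.
#' @param expert_dprime,expert_pc Expert criteria (defaults 1.5 and 70).
#' @param progress_cut Early/late progress threshold (default 0.40).
#' @return Character vector of phase labels (`"early"`, `"late"`,
#'   `"expert"`), one per session.
#' @export
segment_learning_phases <- function(dprime, percent_correct,
                                    expert_dprime = 1.5, expert_pc = 70,
                                    progress_cut = 0.40) {
  stopifnot(length(dprime) >= 2, length(percent_correct) == length(dprime))
  rng <- range(dprime)
  if (rng[1] == rng[2]) stop("flat learning curve: unsegmentable")
  progress <- (dprime - rng[1]) / (rng[2] - rng[1])
  expert <- dprime >= expert_dprime & percent_correct >= expert_pc
  ifelse(expert, "expert", ifelse(progress < progress_cut, "early", "late"))
}

#' Learning-curve slope per phase
#'
#' Ordinary least-squares slope of d' against session index over all
#' sessions of a phase; for non-expert phases the first session of the next
#' occupied phase is appended before fitting, so the slope captures the
#' transition.
#'
#' @param dprime Per-session d'.
#' @param phases Phase labels from [segment_learning_phases()].
#' @return Named numeric vector of slopes (d' per session) for phases
#'   `early`, `late`, `expert`; `NA` where fewer than two points are
#'   available.
#' @export
phase_slopes <- function(dprime, phases) {
  stopifnot(length(dprime) == length(phases))
  idx <- seq_along(dprime)
  order_ph <- c("early", "late", "expert")
  out <- c(early = NA_real_, late = NA_real_, expert = NA_real_)
  for (p in seq_along(order_ph)) {
    ph <- order_ph[p]
    pts <- which(phases == ph)
    if (length(pts) == 0) next
    if (ph != "expert") {
      nxt <- integer(0)
      for (q in seq(p + 1, length(order_ph))) {
        cand <- which(phases == order_ph[q])
        if (length(cand)) { nxt <- min(cand); break }
      }
      pts <- c(pts, nxt)
    }
    if (length(pts) >= 2) {
      x <- idx[pts]; y <- dprime[pts]
      out[ph] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    }
  }
  out
}

#' Detect movement onset in a speed trace
#'
#' For each frame f with 100 frames of context on both sides, the forward -
#' backward speed difference is `mean(speed[f..f+99]) -
#' mean(speed[f-100..f-1])`. The onset is the first frame where this
#' difference exceeds the whole-trace mean of the difference plus two
#' standard deviations. With `rule = "lookahead"` the onset is instead the
#' first frame such that a crossing occurs within the following 100 frames.
#'
#' @param speed Per-frame speed sequence (> 300 frames).
#' @param frame_rate Frames per second (default 100).
#' @param rule `"first_crossing"` (default) or `"lookahead"`.
#' @return List with `onset_frame` (NA when no crossing), `peak_frame` (the
#'   frame maximizing the difference trace - for a clean speed step this
#'   pinpoints the step while the first crossing necessarily precedes it),
#'   `speed_before` and `speed_after` (mean speed in the 0.5-s windows
#'   before / from onset), and the `diff_trace` with its `threshold`.
#' @export
detect_movement_onset <- function(speed, frame_rate = 100,
                                  rule = c("first_crossing", "lookahead")) {
  rule <- match.arg(rule)
  n <- length(speed)
  if (n <= 300) stop("need > 300 frames")
  cs <- c(0, cumsum(speed))
  frames <- seq(101L, n - 99L)  # f..f+99 and f-100..f-1 both in range
  fwd <- (cs[frames + 100] - cs[frames]) / 100
  bwd <- (cs[frames] - cs[frames - 100]) / 100
  dtr <- fwd - bwd
  thr <- mean(dtr) + 2 * sd(dtr)
  cross <- which(dtr > thr)
  onset <- NA_integer_
  if (length(cross)) {
    onset <- if (rule == "first_crossing") frames[cross[1]] else {
      hit <- which(vapply(seq_along(frames), function(i) {
        any(cross >= i & cross < i + 100)
      }, logical(1)))
      frames[hit[1]]
    }
  }
  w <- round(0.5 * frame_rate)
  before <- after <- NA_real_
  if (!is.na(onset)) {
    before <- mean(speed[max(1, onset - w):(onset - 1)])
    after <- mean(speed[onset:min(n, onset + w - 1)])
  }
  list(onset_frame = onset, peak_frame = frames[which.max(dtr)],
       speed_before = before, speed_after = after,
       diff_trace = dtr, diff_frames = frames, threshold = thr)
}

#' Summarize a simulated or recorded learning curve
#'
#' Convenience wrapper: per-day d' and percent correct from trial tables,
#' phase labels, and phase slopes.
#'
#' @param sessions List of per-day trial data frames (columns `stimulus`,
#'   `outcome`).
#' @return Data frame with `day`, `dprime`, `percent_correct`, `phase`, plus
#'   a `"slopes"` attribute.
#' @export
learning_curve_summary <- function(sessions) {
  perf <- lapply(sessions, compute_dprime)
  d <- vapply(perf, `[[`, numeric(1), "dprime")
  pc <- vapply(perf, `[[`, numeric(1), "percent_correct")
  phase <- segment_learning_phases(d, pc)
  out <- data.frame(day = seq_along(sessions), dprime = d,
                    percent_correct = pc, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "slopes") <- phase_slopes(d, phase)
  out
}
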