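# Shared fixtures: everything is generated in code at test time.

# A small trial table with fixed onsets (no simulation), for oracle tests.
fixed_trials <- function(n = 20, iti = 5, p_target = 0.5, latency = 0.6) {
  onset <- iti * seq_len(n)
  stimulus <- rep(c("target", "nontarget"), length.out = n)
  go <- rep(c(TRUE, FALSE), length.out = n)
  data.frame(trial_id = seq_len(n), onset_s = onset, stimulus = stimulus,
             response_time_s = ifelse(go, onset + latency, NA_real_),
             outcome = ifelse(stimulus == "target",
                              ifelse(go, "hit", "miss"),
                              ifelse(go, "false_alarm", "correct_reject")),
             stringsAsFactors = FALSE)
}

# Place spikes deterministically: `times` are offsets relative to each onset.
spikes_at_offsets <- function(trials, offsets) {
  sort(as.vector(outer(trials$onset_s, offsets, `+`)))
}

# Quick single-unit session for decoder tests.
quick_session <- function(n_trials = 100, baseline = 5, stim_delta = 0,
                          shapes = c(0.6, 2.5), seed = 1L, n_units = 1,
                          gain_sd = 0) {
  us <- lapply(seq_len(n_units), function(i) {
    unit_gen_spec(paste0("u", i), baseline, stim_delta = stim_delta,
                  isi_shape_target = shapes[1],
                  isi_shape_nontarget = shapes[2],
                  true_label = if (stim_delta == 0) "NCR" else "CR")
  })
  ss <- session_gen_spec(n_units = n_units, n_trials = n_trials,
                         shared_gain_sd = gain_sd, seed = seed)
  simulate_session(ss, us)
}

# Brute-force sliding-window modulation oracle (independent of the package's
# vectorized path): plain loops over offsets and trials.
oracle_modulation <- function(spikes, trials, baseline = 0.150, width = 0.05,
                              range_s = 0.2, step = 0.01) {
  rbl <- mean(vapply(trials$onset_s, function(on) {
    sum(spikes >= on - baseline & spikes < on)
  }, numeric(1))) / baseline
  offsets <- seq(0, range_s - width, by = step)
  diffs <- vapply(offsets, function(o) {
    r <- mean(vapply(trials$onset_s, function(on) {
      sum(spikes >= on + o & spikes < on + o + width)
    }, numeric(1))) / width
    r - rbl
  }, numeric(1))
  j <- which.max(abs(diffs))
  list(evoked = diffs[j], modulation = max(abs(diffs)), rbl = rbl,
       offset = offsets[j])
}
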