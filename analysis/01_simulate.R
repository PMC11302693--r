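#!/usr/bin/env Rscript
# Stage 1 - generate the synthetic study data every later stage consumes:
# one multi-unit recording session with known CR/NCR ground truth, a
# multi-day behavioral learning curve, and a kinematic speed trace.
#
# Outputs under results/data/: session CSVs + ground-truth JSON, per-day
# behavioral trials, speed trace.

suppressPackageStartupMessages(library(isidecode))
set.seed(NULL)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## Recording session: 24 units (half CR, half timing-coded NCR), 200 trials,
## modest shared gain so population covariance is realistic.
specs <- population_gen_specs(24, p_ncr = 0.5, seed = 11)
session <- simulate_session(
  session_gen_spec(n_units = 24, n_trials = 200, shared_gain_sd = 0.25,
                   seed = 12),
  specs)
write_session(session, file.path(out_dir, "session01"))
message(sprintf("session01: %d units, %d trials (%d target)",
                length(session$spikes), nrow(session$trials),
                sum(session$trials$stimulus == "target")))

## Behavioral learning curve: 12 training days sweeping from chance to
## expert performance (hit rate rising 0.5 -> 0.95, false alarms falling
## 0.5 -> 0.08), 200 trials/day.
days <- 12
lc <- simulate_learning_curve(
  days,
  hit_traj = seq(0.50, 0.95, length.out = days),
  fa_traj = seq(0.50, 0.08, length.out = days),
  trials_per_day = 200, seed = 13)
for (d in seq_len(days)) {
  write.csv(lc$sessions[[d]],
            file.path(out_dir, sprintf("behavior_day%02d.csv", d)),
            row.names = FALSE)
}
write.csv(lc$summary, file.path(out_dir, "behavior_summary.csv"),
          row.names = FALSE)
message(sprintf("learning curve: %d days, hits day1 = %d, day%d = %d",
                days, lc$summary$hits[1], days, lc$summary$hits[days]))

## Kinematic speed trace: 100 frames/s, movement onset at frame 900.
speed <- simulate_speed_trace(3000, onset_frame = 900, pre_speed = 0.5,
                              post_speed = 3.0, noise_sd = 0.5, seed = 14)
write.csv(data.frame(frame = seq_along(speed), speed = speed),
          file.path(out_dir, "speed_trace.csv"), row.names = FALSE)
message("speed trace: 3000 frames, true onset at frame 900")
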