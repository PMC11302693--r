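#!/usr/bin/env Rscript
# Stage 2 - behavioral performance: per-day d' and percent correct,
# early/late/expert phase labels, phase slopes, and movement-onset
# detection on the kinematic trace.

suppressPackageStartupMessages(library(isidecode))

data_dir <- "results/data"
out_dir <- "results/behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

day_files <- sort(list.files(data_dir, pattern = "^behavior_day",
                             full.names = TRUE))
sessions <- lapply(day_files, read.csv, stringsAsFactors = FALSE)
curve <- learning_curve_summary(sessions)
slopes <- attr(curve, "slopes")

write.csv(curve, file.path(out_dir, "learning_curve.csv"), row.names = FALSE)
jsonlite::write_json(
  list(slopes = as.list(slopes),
       n_expert_days = sum(curve$phase == "expert"),
       final_dprime = curve$dprime[nrow(curve)]),
  file.path(out_dir, "behavior_summary.json"), auto_unbox = TRUE, digits = NA)

message("per-day d' and phase:")
print(curve, row.names = FALSE)
message(sprintf("phase slopes (d'/day): early %.2f, late %.2f, expert %.2f",
                slopes[["early"]], slopes[["late"]], slopes[["expert"]]))

speed <- read.csv(file.path(data_dir, "speed_trace.csv"))$speed
mo <- detect_movement_onset(speed, frame_rate = 100)
message(sprintf(
  "movement onset: first 2-SD crossing at frame %d (diff peak %d); speed %.2f -> %.2f",
  mo$onset_frame, mo$peak_frame, mo$speed_before, mo$speed_after))
jsonlite::write_json(
  list(onset_frame = mo$onset_frame, peak_frame = mo$peak_frame,
       speed_before = mo$speed_before, speed_after = mo$speed_after),
  file.path(out_dir, "movement_onset.json"), auto_unbox = TRUE, digits = NA)
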