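#!/usr/bin/env Rscript
# Stage 3 - responsiveness profiles and CR/NCR classification for the
# simulated session: spontaneous and evoked rates, tone selectivity,
# stimulus/choice modulation, subsampled-bootstrap labels, separating
# threshold, final labels scored against ground truth.

suppressPackageStartupMessages(library(isidecode))

session <- read_session("results/data/session01")
out_dir <- "results/responsiveness"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

keep <- vapply(session$spikes, function(sp) {
  unit_inclusion(sp)$included
}, logical(1))
message(sprintf("%d/%d units pass the 0.5 spikes/s inclusion rule",
                sum(keep), length(keep)))

cl <- classify_units(session$spikes[keep], session$trials,
                     period = "stimulus", seed = 21)
prof <- cl$profiles
truth <- vapply(session$ground_truth$unit_specs,
                `[[`, character(1), "true_label")[keep]
prof$true_label <- truth

write.csv(prof, file.path(out_dir, "unit_profiles.csv"), row.names = FALSE)
jsonlite::write_json(
  list(threshold_spikes_per_s = cl$threshold_fit$threshold,
       margin = cl$threshold_fit$margin,
       n_cr_train = cl$threshold_fit$n_cr,
       n_ncr_train = cl$threshold_fit$n_ncr),
  file.path(out_dir, "threshold_fit.json"), auto_unbox = TRUE, digits = NA)

message("bootstrap labels vs ground truth:")
print(table(truth, bootstrap = prof$bootstrap_label))
message(sprintf("separating threshold: %.2f spikes/s",
                cl$threshold_fit$threshold))
message("final labels vs ground truth:")
print(table(truth, final = prof$final_label))
message(sprintf("percent NCR (final): %.1f%%",
                100 * mean(prof$final_label == "NCR")))
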