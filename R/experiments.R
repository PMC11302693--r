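#' Chance-level decoding of synthetic controls
#'
#' Simulates a mixed population (half rate-coded CR units, half
#' timing-coded NCR units), builds each cell's resampled-ISI synthetic
#' control, and decodes the controls with the single-cell decoder under
#' flat priors. Since the surrogates destroy all condition-specific
#' structure while preserving trial length, control accuracy estimates the
#' decoder's chance level.
#'
#' @param n_cells Number of simulated cells (default 50).
#' @param n_trials Balanced trials per session (default 100).
#' @param k,iterations Cross-validation geometry (defaults 10 and 20).
#' @param seed Integer seed.
#' @return Data frame with one row per cell: `unit_id`, `true_label`,
#'   `control_accuracy`.
#' @export
experiment_control_chance <- function(n_cells = 50, n_trials = 100, k = 10,
                                      iterations = 20, seed = 1L) {
  seeds <- derive_seeds(seed, 2L + 2L * n_cells)
  specs <- population_gen_specs(n_cells, p_ncr = 0.5, seed = seeds[1])
  sess <- simulate_session(
    session_gen_spec(n_units = n_cells, n_trials = n_trials, seed = seeds[2]),
    specs)
  acc <- vapply(seq_len(n_cells), function(i) {
    isis <- trial_isis(sess$spikes[[i]], sess$trials)
    ctrl <- make_synthetic_control(isis, 2.5, seed = seeds[2 + i])
    crossval_decode(ctrl, sess$trials, "stimulus", k = k,
                    iterations = iterations,
                    seed = seeds[2 + n_cells + i])$mean_accuracy
  }, numeric(1))
  data.frame(unit_id = names(sess$spikes),
             true_label = vapply(specs, `[[`, character(1), "true_label"),
             control_accuracy = acc, stringsAsFactors = FALSE)
}

#' Ground-truth recovery of the CR/NCR classification pipeline
#'
#' Simulates a population of units with known labels (CR units with a fixed
#' stimulus rate change, NCR units rate-flat) and runs the full
#' classification pipeline - subsampled bootstrap, separating-threshold fit
#' on the bootstrap-labeled units, threshold classification of all units -
#' then scores final labels against ground truth.
#'
#' @param n_per_class Units per true class (default 100).
#' @param n_trials Trials (default 200).
#' @param stim_delta_cr True CR modulation in spikes/s (default 5).
#' @param seed Integer seed.
#' @return List with `recovery_cr`, `recovery_ncr` (fractions correct),
#'   `bootstrap_table` (true label x bootstrap label counts), `profiles`,
#'   and `threshold`.
#' @export
experiment_classifier_recovery <- function(n_per_class = 100, n_trials = 200,
                                           stim_delta_cr = 5, seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  specs <- population_gen_specs(2L * n_per_class, p_ncr = 0.5,
                                seed = seeds[1],
                                stim_delta_cr = stim_delta_cr,
                                ncr_shapes = c(1, 1))
  sess <- simulate_session(
    session_gen_spec(n_units = 2L * n_per_class, n_trials = n_trials,
                     seed = seeds[2]), specs)
  cl <- classify_units(sess$spikes, sess$trials, period = "stimulus",
                       seed = seeds[3])
  truth <- vapply(specs, `[[`, character(1), "true_label")
  prof <- cl$profiles
  list(recovery_cr = mean(prof$final_label[truth == "CR"] == "CR"),
       recovery_ncr = mean(prof$final_label[truth == "NCR"] == "NCR"),
       bootstrap_table = table(truth, prof$bootstrap_label),
       profiles = cbind(prof, true_label = truth),
       threshold = cl$threshold_fit$threshold)
}

#' Rate-matched timing-coded units versus their synthetic controls
#'
#' Each replicate simulates one NCR unit whose only condition dependence is
#' the gamma ISI shape (rates matched across conditions), decodes the real
#' trials and a resampled-ISI control, and tests real vs control accuracy
#' samples with a two-sided Mann-Whitney U test.
#'
#' @param n_replicates Number of replicate units (default 50).
#' @param n_trials,k,iterations Decoding geometry.
#' @param shapes Target/nontarget gamma shapes (default `c(0.6, 2.5)`).
#' @param seed Integer seed.
#' @return Data frame per replicate: `real_accuracy`, `control_accuracy`,
#'   `p_value`, `significant`.
#' @export
experiment_rate_matched <- function(n_replicates = 50, n_trials = 100,
                                    k = 10, iterations = 20,
                                    shapes = c(0.6, 2.5), seed = 1L) {
  seeds <- derive_seeds(seed, 4L * n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    s4 <- seeds[(4L * (r - 1L) + 1L):(4L * r)]
    spec <- unit_gen_spec("u", baseline_rate = 5, stim_delta = 0,
                          isi_shape_target = shapes[1],
                          isi_shape_nontarget = shapes[2], true_label = "NCR")
    sess <- simulate_session(
      session_gen_spec(n_units = 1, n_trials = n_trials, seed = s4[1]),
      list(spec))
    isis <- trial_isis(sess$spikes[[1]], sess$trials)
    dr <- crossval_decode(isis, sess$trials, "stimulus", k = k,
                          iterations = iterations, seed = s4[2])
    ctrl <- make_synthetic_control(isis, 2.5, seed = s4[3])
    dc <- crossval_decode(ctrl, sess$trials, "stimulus", k = k,
                          iterations = iterations, seed = s4[4])
    sg <- significance_vs_control(dr$accuracy_samples, dc$accuracy_samples)
    data.frame(real_accuracy = dr$mean_accuracy,
               control_accuracy = dc$mean_accuracy, p_value = sg$p_value,
               significant = sg$is_significant &
                 dr$mean_accuracy > dc$mean_accuracy)
  })
  do.call(rbind, rows)
}

#' Dimensionality versus shared-gain correlation
#'
#' For each shared-gain level, simulates replicate sessions of rate-flat
#' units, computes the activity covariance in the stimulus-aligned window,
#' and estimates the large-n dimensionality `D_inf` from its moments.
#' Stronger shared gain means stronger pairwise covariance and lower
#' dimensionality.
#'
#' @param gain_levels Shared-gain SDs (default `c(0, 0.25, 0.5)`).
#' @param n_replicates Sessions per level (default 50).
#' @param n_units,n_trials Session geometry.
#' @param seed Integer seed.
#' @return Data frame per (level, replicate): `gain_sd`, `d_inf`,
#'   `mean_abs_cov`.
#' @export
experiment_gain_dimensionality <- function(gain_levels = c(0, 0.25, 0.5),
                                           n_replicates = 50, n_units = 12,
                                           n_trials = 150, seed = 1L) {
  seeds <- derive_seeds(seed, length(gain_levels) * n_replicates)
  rows <- list()
  idx <- 0L
  for (g in gain_levels) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      specs <- lapply(seq_len(n_units), function(i) {
        unit_gen_spec(paste0("u", i), baseline_rate = 5, true_label = "NCR")
      })
      sess <- simulate_session(
        session_gen_spec(n_units = n_units, n_trials = n_trials,
                         shared_gain_sd = g, seed = seeds[idx]), specs)
      C <- cov(activity_matrix(sess$spikes, sess$trials))
      d <- dimensionality_decomposed(diag(C), C[upper.tri(C)])
      rows[[idx]] <- data.frame(gain_sd = g, d_inf = d$d_inf,
                                mean_abs_cov = d$mean_abs_cov)
    }
  }
  do.call(rbind, rows)
}
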