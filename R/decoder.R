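#' Extract interspike intervals from a trial window
#'
#' Successive differences of the spike times falling in the window; empty
#' when the window holds fewer than two spikes. The default window runs from
#' tone onset to the end of the 2.5-s response window.
#'
#' @param spikes Sorted spike times for one unit.
#' @param onset Trial tone-onset time (seconds).
#' @param window Window relative to onset, seconds (default `c(0, 2.5)`).
#' @return Numeric vector of positive ISIs (possibly empty).
#' @export
extract_isis <- function(spikes, onset, window = c(0, 2.5)) {
  s <- spikes[spikes >= onset + window[1] & spikes < onset + window[2]]
  if (length(s) < 2) return(numeric(0))
  diff(s)
}

# Per-trial ISI lists for a whole session.
trial_isis <- function(spikes, trials, window = c(0, 2.5)) {
  lapply(trials$onset_s, function(on) extract_isis(spikes, on, window))
}

#' Fit an ISI density by kernel density estimation
#'
#' Gaussian kernels on the log-ISI axis (ISIs are strictly positive and
#' heavy-tailed, so the log domain is the natural support). The bandwidth is
#' chosen by cross-validated maximum likelihood: held-out mean log-density
#' over a log-spaced bandwidth grid, with deterministic rank-interleaved
#' folds so the fit is a pure function of its inputs. Evaluated densities
#' are floored at `floor_eps` to keep out-of-support ISIs from contributing
#' -Inf log-likelihoods.
#'
#' @param isis Positive ISIs (seconds).
#' @param cv_folds Folds for bandwidth selection (default 5).
#' @param bandwidth_grid Candidate bandwidths on the log-ISI axis; default is
#'   a 13-point grid spanning Silverman's rule x 2^(-3..3).
#' @param min_isis Floor below which the widest grid bandwidth is used with
#'   a warning (default 10).
#' @param floor_eps Density floor (default 1e-12).
#' @param condition Optional condition label carried in the object.
#' @return An `isi_density` object: `log_centers`, `bandwidth`, `n`,
#'   `condition`, `floor_eps`, `cv_table`.
#' @export
fit_isi_density <- function(isis, cv_folds = 5, bandwidth_grid = NULL,
                            min_isis = 10, floor_eps = 1e-12,
                            condition = NA_character_) {
  stopifnot(all(isis > 0))
  x <- log(isis)
  n <- length(x)
  if (is.null(bandwidth_grid)) {
    s <- if (n > 1) sd(x) else 1
    if (!is.finite(s) || s <= 0) s <- 0.5
    silver <- 0.9 * s * max(n, 2)^(-1 / 5)
    bandwidth_grid <- silver * 2^seq(-3, 3, length.out = 13)
  }
  bandwidth_grid <- sort(bandwidth_grid)
  cv_table <- NULL
  if (n < min_isis) {
    warning("fewer than ", min_isis, " ISIs: using widest grid bandwidth")
    h <- max(bandwidth_grid)
  } else {
    k <- min(cv_folds, n)
    fold <- ((rank(x, ties.method = "first") - 1L) %% k) + 1L
    ll <- vapply(bandwidth_grid, function(h) {
      kde_cv_loglik_cpp(x, as.integer(fold), k, h, floor_eps)
    }, numeric(1))
    cv_table <- data.frame(bandwidth = bandwidth_grid, cv_loglik = ll)
    best <- which(ll >= max(ll) - 1e-12)
    h <- bandwidth_grid[max(best)]  # ties broken toward the wider bandwidth
  }
  structure(list(log_centers = x, bandwidth = h, n = n, condition = condition,
                 floor_eps = floor_eps, cv_table = cv_table),
            class = "isi_density")
}

#' Evaluate the log density of an `isi_density`
#'
#' @param density An [fit_isi_density()] object (or a bare list with
#'   `log_centers`, `bandwidth`, `floor_eps`).
#' @param isis Positive ISIs at which to evaluate.
#' @return Log density per ISI (on the log-ISI axis), floored at
#'   `floor_eps`.
#' @export
isi_log_density <- function(density, isis) {
  if (length(isis) == 0) return(numeric(0))
  kde_logdens_cpp(log(isis), density$log_centers, density$bandwidth,
                  density$floor_eps)
}

#' Posterior over task conditions for one trial
#'
#' Naive-Bayes posterior: the prior times the product of per-ISI likelihoods
#' under each condition's density, computed in log space and normalized. An
#' empty ISI set returns the prior unchanged.
#'
#' @param densities Named list of `isi_density` objects, one per condition.
#' @param isis The trial's ISIs.
#' @param priors Named prior probabilities summing to 1 (default flat).
#' @return Named posterior probabilities summing to 1.
#' @export
decode_trial <- function(densities, isis, priors = NULL) {
  conds <- names(densities)
  if (is.null(priors)) priors <- setNames(rep(1 / length(conds),
                                              length(conds)), conds)
  stopifnot(abs(sum(priors) - 1) < 1e-8, all(conds %in% names(priors)))
  lp <- log(priors[conds]) + vapply(conds, function(cn) {
    sum(isi_log_density(densities[[cn]], isis))
  }, numeric(1))
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

# Stratified fold assignment: within each condition, trials are permuted and
# dealt round-robin into k folds, so every training set holds both
# conditions.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cn in unique(labels)) {
    idx <- which(labels == cn)
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  fold
}

# Cross-validated naive-Bayes ISI decoding for an ensemble of >= 1 units.
#
# isis_by_unit: list (units) of lists (trials) of ISI vectors.
# labels: per-trial condition labels (2 conditions).
# Bandwidths are selected once per unit x condition on the full data
# (cv-ML); kernel centers are refit on the training folds of every split.
# Accuracy samples are per-fold fractions correct (k x iterations of them);
# a trial scores 1 when the true condition has the strictly largest
# posterior and 0.5 on an exact tie.
cv_decode_core <- function(isis_by_unit, labels, k = 10, iterations = 500,
                           seed = 1L, priors = NULL, floor_eps = 1e-12,
                           min_isis = 10) {
  labels <- as.character(labels)
  conds <- sort(unique(labels))
  stopifnot(length(conds) == 2)
  n_trials <- length(labels)
  if (min(table(labels)) < k) stop("need >= k trials per condition")
  if (is.null(priors)) priors <- setNames(rep(0.5, 2), conds)
  lpriors <- log(priors[conds])
  n_units <- length(isis_by_unit)

  # per unit x condition bandwidths from the full data
  bw <- matrix(NA_real_, n_units, 2, dimnames = list(NULL, conds))
  for (u in seq_len(n_units)) {
    for (ci in 1:2) {
      pooled <- unlist(isis_by_unit[[u]][labels == conds[ci]])
      bw[u, ci] <- if (length(pooled) >= 2) {
        suppressWarnings(
          fit_isi_density(pooled, min_isis = min_isis,
                          floor_eps = floor_eps)$bandwidth)
      } else 1
    }
  }

  log_isis <- lapply(isis_by_unit, function(tr) lapply(tr, log))
  lens <- lapply(log_isis, lengths)
  lfloor <- log(floor_eps)

  acc <- matrix(NA_real_, iterations, k)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      fold <- stratified_folds(labels, k)
      for (f in seq_len(k)) {
        test_idx <- which(fold == f)
        train_idx <- which(fold != f)
        loglik <- matrix(0, length(test_idx), 2)  # trials x conditions
        for (u in seq_len(n_units)) {
          q <- unlist(log_isis[[u]][test_idx])
          if (length(q) == 0) next
          grp <- rep(seq_along(test_idx), lens[[u]][test_idx])
          for (ci in 1:2) {
            centers <- unlist(
              log_isis[[u]][train_idx[labels[train_idx] == conds[ci]]])
            ld <- if (length(centers) == 0) rep(lfloor, length(q)) else {
              kde_logdens_cpp(q, centers, bw[u, ci], floor_eps)
            }
            sums <- rowsum(ld, grp)
            loglik[as.integer(rownames(sums)), ci] <-
              loglik[as.integer(rownames(sums)), ci] + sums[, 1]
          }
        }
        lp1 <- lpriors[1] + loglik[, 1]
        lp2 <- lpriors[2] + loglik[, 2]
        truth1 <- labels[test_idx] == conds[1]
        score <- ifelse(lp1 == lp2, 0.5, ifelse((lp1 > lp2) == truth1, 1, 0))
        acc[it, f] <- mean(score)
      }
    }
  })
  samples <- as.vector(t(acc))
  structure(list(level = if (n_units == 1) "single_cell" else "ensemble",
                 accuracy_samples = samples, mean_accuracy = mean(samples),
                 per_iteration = rowMeans(acc), k = k,
                 iterations = iterations, conditions = conds,
                 n_trials = n_trials, n_units = n_units,
                 control_mean_accuracy = NA_real_, p_vs_control = NA_real_,
                 is_significant = NA, is_task_encoder = NA),
            class = "decoding_result")
}

#' Cross-validated single-cell ISI decoding
#'
#' Decodes the stimulus (target vs nontarget) or choice (go vs no-go) of
#' each trial from the cell's ISI sequence with the naive-Bayes KDE decoder,
#' under stratified 10-fold cross-validation repeated `iterations` times.
#' Accuracy samples are per-fold fractions correct (the defaults yield
#' 10 x 500 = 5,000 samples).
#'
#' @param spikes Sorted spike times, or a pre-extracted list of per-trial
#'   ISI vectors.
#' @param trials Session trial table.
#' @param task `"stimulus"` or `"choice"`.
#' @param k,iterations Cross-validation geometry (defaults 10 and 500).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param window ISI extraction window relative to tone onset.
#' @param priors Prior probabilities (default flat).
#' @return A `decoding_result`.
#' @export
crossval_decode <- function(spikes, trials, task = c("stimulus", "choice"),
                            k = 10, iterations = 500, seed = 1L,
                            window = c(0, 2.5), priors = NULL) {
  task <- match.arg(task)
  isis <- if (is.list(spikes)) spikes else trial_isis(spikes, trials, window)
  cv_decode_core(list(isis), task_labels(trials, task), k = k,
                 iterations = iterations, seed = seed, priors = priors)
}

# Condition labels for a task: stimulus = target/nontarget; choice = go/no-go
# (go = response present).
task_labels <- function(trials, task = c("stimulus", "choice")) {
  task <- match.arg(task)
  if (task == "stimulus") trials$stimulus
  else ifelse(is.na(trials$response_time_s), "nogo", "go")
}

#' Build a synthetic (resampled-ISI) control
#'
#' For each real trial, ISIs are drawn i.i.d. with replacement from the
#' cell's pooled ISI set (all trials, any condition) and accumulated until
#' the next draw would exceed the trial's window length. Condition structure
#' is destroyed while trial length and the marginal ISI distribution are
#' preserved, so decoding surrogates should sit at chance.
#'
#' @param isis_by_trial List of per-trial ISI vectors (from real data).
#' @param window_length Trial window length in seconds (scalar or
#'   per-trial).
#' @param seed Integer seed.
#' @return List of surrogate per-trial ISI vectors (same length as input).
#' @export
make_synthetic_control <- function(isis_by_trial, window_length = 2.5,
                                   seed = 1L) {
  pooled <- unlist(isis_by_trial)
  if (length(pooled) < 2) stop("need >= 2 pooled ISIs")
  wl <- rep_len(window_length, length(isis_by_trial))
  mean_isi <- mean(pooled)
  with_seed(seed, {
    lapply(seq_along(isis_by_trial), function(t) {
      out <- numeric(0)
      total <- 0
      repeat {
        m <- max(8L, ceiling((wl[t] - total) / mean_isi * 1.5))
        draw <- sample(pooled, m, replace = TRUE)
        cum <- total + cumsum(draw)
        keep <- cum <= wl[t]
        out <- c(out, draw[keep])
        if (!all(keep)) break
        total <- cum[m]
      }
      out
    })
  })
}

#' Mann-Whitney significance of decoding vs its synthetic control
#'
#' Two-sided rank-sum test comparing the accuracy-sample distributions from
#' real and control decoding. Cells with p >= 0.05 are flagged
#' non-significant and excluded from decoding analyses.
#'
#' @param true_samples,control_samples Accuracy-sample vectors.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value`, `is_significant`.
#' @export
significance_vs_control <- function(true_samples, control_samples,
                                    alpha = 0.05) {
  stopifnot(length(true_samples) > 0, length(control_samples) > 0)
  p <- suppressWarnings(
    wilcox.test(true_samples, control_samples, exact = FALSE)$p.value)
  list(p_value = p, is_significant = is.finite(p) && p < alpha)
}

#' Task-encoder accuracy threshold
#'
#' Below-chance decoding accuracies estimate the sampling variability around
#' chance; the gap between their 5th percentile and chance, reflected above
#' chance, is the threshold for calling a cell a task encoder.
#'
#' @param mean_accuracies Per-cell mean decoding accuracies.
#' @param chance Chance level (default 0.5).
#' @param min_below Minimum number of at-or-below-chance cells required
#'   (default 20).
#' @return List with `threshold`, `p5`, `n_below`; threshold `NA` (flagged)
#'   when too few cells sit at or below chance.
#' @export
task_encoder_threshold <- function(mean_accuracies, chance = 0.5,
                                   min_below = 20) {
  below <- mean_accuracies[mean_accuracies <= chance]
  if (length(below) < min_below) {
    warning("fewer than ", min_below, " below-chance cells: threshold undefined")
    return(list(threshold = NA_real_, p5 = NA_real_, n_below = length(below)))
  }
  p5 <- unname(quantile(below, 0.05))
  list(threshold = chance + (chance - p5), p5 = p5, n_below = length(below))
}
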