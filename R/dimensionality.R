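#' Trial-by-unit activity matrix
#'
#' Per-trial spike counts for each unit in a stimulus-aligned window
#' (default the 200 ms from tone onset). Units whose counts have zero
#' variance are retained but flagged - they are degenerate for covariance.
#'
#' @param spikes_list Named list of sorted spike-time vectors.
#' @param trials Session trial table.
#' @param window Window relative to onset, seconds (default `c(0, 0.2)`).
#' @return Numeric matrix (trials x units) with a `zero_variance` attribute
#'   naming flagged units and a `window` attribute.
#' @export
activity_matrix <- function(spikes_list, trials, window = c(0, 0.2)) {
  stopifnot(nrow(trials) >= 2)
  on <- trials$onset_s
  m <- vapply(spikes_list, function(sp) {
    count_in_windows(sp, on + window[1], on + window[2])
  }, numeric(nrow(trials)))
  colnames(m) <- names(spikes_list)
  v <- apply(m, 2, var)
  structure(m, zero_variance = colnames(m)[v == 0], window = window)
}

#' Participation ratio of a covariance matrix
#'
#' D = (Tr C)^2 / Tr C^2, an effective count of independent activity modes:
#' n for the identity (all modes equal), 1 for a rank-one matrix.
#'
#' @param C Symmetric positive semi-definite covariance matrix.
#' @return Dimensionality D in \[1, n\].
#' @export
participation_ratio <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("covariance matrix must be symmetric")
  }
  tr2 <- sum(C * C)  # Tr C^2 for symmetric C
  if (tr2 == 0) stop("zero covariance matrix: participation ratio undefined")
  sum(diag(C))^2 / tr2
}

# Moment summaries used by the decomposed form: <Var_i^2>, <Var_i Var_j>
# over i != j, <Cov_ij^2> over i != j.
covariance_moments <- function(C) {
  v <- diag(C)
  n <- length(v)
  off <- C[upper.tri(C)]
  list(n = n,
       mean_var_sq = mean(v^2),
       mean_var_prod = if (n > 1) (sum(v)^2 - sum(v^2)) / (n * (n - 1)) else NA_real_,
       mean_cov_sq = if (n > 1) mean(off^2) else NA_real_,
       mean_abs_cov = if (n > 1) mean(abs(off)) else NA_real_)
}

#' Dimensionality from variance/covariance moments
#'
#' Finite-population form
#' `D = [1 + (n-1) <Var_i Var_j>/<Var_i^2>] / [1 + (n-1) <Cov_ij^2>/<Var_i^2>]`
#' and its large-n limit `D_inf = <Var_i Var_j> / <Cov_ij^2>`. On moments
#' taken from a complete covariance matrix the finite form reproduces
#' `(Tr C)^2 / Tr C^2` exactly.
#'
#' @param variances Per-unit activity variances.
#' @param covariances Pairwise covariances (each unordered pair once or
#'   both orders - the squared mean is the same).
#' @param n Unit count (default `length(variances)`).
#' @return List with `d_finite`, `d_inf` (`Inf`, flagged, when the mean
#'   squared covariance is 0), and the moments.
#' @export
dimensionality_decomposed <- function(variances, covariances,
                                      n = length(variances)) {
  stopifnot(n >= 2, length(variances) >= 1, length(covariances) >= 1)
  v <- variances
  mean_var_sq <- mean(v^2)
  if (mean_var_sq == 0) stop("all variances zero: dimensionality undefined")
  mean_var_prod <- if (length(v) > 1) {
    (sum(v)^2 - sum(v^2)) / (length(v) * (length(v) - 1))
  } else v^2
  mean_cov_sq <- mean(covariances^2)
  d_finite <- (1 + (n - 1) * mean_var_prod / mean_var_sq) /
    (1 + (n - 1) * mean_cov_sq / mean_var_sq)
  d_inf <- if (mean_cov_sq == 0) Inf else mean_var_prod / mean_cov_sq
  list(d_finite = d_finite, d_inf = d_inf, n = n,
       mean_var_sq = mean_var_sq, mean_var_prod = mean_var_prod,
       mean_cov_sq = mean_cov_sq, mean_abs_cov = mean(abs(covariances)))
}

#' Two-level bootstrap of population dimensionality
#'
#' The numerator moments (single-unit variances) are re-estimated by
#' resampling each animal's units with replacement at that animal's original
#' unit count; the denominator moments (pairwise covariances, which exist
#' only within a session) are re-estimated by resampling sessions with
#' replacement and pooling all within-session pairs of the sampled
#' sessions. One D_inf estimate is computed per replicate; the mean and
#' s.e.m. over `B` replicates are reported alongside the point estimate.
#'
#' @param unit_variances Data frame with columns `animal` and `variance`
#'   (one row per unit).
#' @param session_covs List of per-session covariance matrices (or
#'   activity matrices via [activity_matrix()] with `cov()` applied by the
#'   caller).
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List with `d_inf` (point estimate), `bootstrap_mean`,
#'   `bootstrap_sem`, `replicates`, `n_excluded` (replicates with all-zero
#'   covariances, flagged and dropped), and the point moments.
#' @export
bootstrap_dimensionality <- function(unit_variances, session_covs, B = 2000,
                                     seed = 1L) {
  stopifnot(is.data.frame(unit_variances),
            all(c("animal", "variance") %in% names(unit_variances)),
            length(session_covs) >= 1)
  by_animal <- split(unit_variances$variance, unit_variances$animal)
  if (!any(lengths(by_animal) >= 2)) stop("need >= 1 animal with >= 2 units")
  pair_covs <- lapply(session_covs, function(C) C[upper.tri(C)])
  if (!any(lengths(pair_covs) >= 1)) stop("need >= 1 session with >= 2 units")
  mvp <- function(v) (sum(v)^2 - sum(v^2)) / (length(v) * (length(v) - 1))
  point_num <- mvp(unit_variances$variance)
  point_den <- mean(unlist(pair_covs)^2)
  point <- if (point_den == 0) Inf else point_num / point_den
  ns <- length(pair_covs)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      v <- unlist(lapply(by_animal, function(vv) {
        vv[sample.int(length(vv), length(vv), replace = TRUE)]
      }))
      sess <- sample.int(ns, ns, replace = TRUE)
      cc <- unlist(pair_covs[sess])
      den <- mean(cc^2)
      if (!is.finite(den) || den == 0) return(NA_real_)
      mvp(v) / den
    }, numeric(1))
  })
  ok <- is.finite(reps)
  list(d_inf = point, bootstrap_mean = mean(reps[ok]),
       bootstrap_sem = sd(reps[ok]) / sqrt(sum(ok)),
       replicates = reps[ok], n_excluded = sum(!ok), B = B,
       mean_var_prod = point_num, mean_cov_sq = point_den)
}
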