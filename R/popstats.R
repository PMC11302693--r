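#' Per-animal bootstrap of a population statistic
#'
#' On each replicate every animal's units are resampled with replacement at
#' that animal's original unit count, and the statistic is recomputed over
#' the pooled resample. Used for population proportions such as percent
#' non-classically responsive.
#'
#' @param records Data frame with an `animal` column; remaining columns are
#'   per-unit values the statistic consumes.
#' @param statistic Function of a data frame (the pooled resample) returning
#'   one number.
#' @param B Replicates (default 2000).
#' @param seed Integer seed.
#' @return List with `estimate` (statistic on the original data),
#'   `bootstrap_mean`, `bootstrap_sem`, `replicates`, `n_excluded`
#'   (replicates where the statistic was undefined), `B`, `seed`.
#' @export
bootstrap_population_stat <- function(records, statistic, B = 2000,
                                      seed = 1L) {
  stopifnot(is.data.frame(records), "animal" %in% names(records),
            nrow(records) >= 1)
  idx_by_animal <- split(seq_len(nrow(records)), records$animal)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- unlist(lapply(idx_by_animal, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }))
      val <- statistic(records[take, , drop = FALSE])
      if (length(val) != 1 || !is.finite(val)) NA_real_ else val
    }, numeric(1))
  })
  ok <- is.finite(reps)
  list(estimate = statistic(records), bootstrap_mean = mean(reps[ok]),
       bootstrap_sem = sd(reps[ok]) / sqrt(sum(ok)), replicates = reps[ok],
       n_excluded = sum(!ok), B = B, seed = seed)
}

#' Permutation test for a difference between two groups
#'
#' The observed difference `statistic(A) - statistic(B)` is compared against
#' its distribution under `N` random relabelings that preserve group sizes.
#' The two-sided p-value uses the `max(count, 1) / N` convention, so the
#' minimum reportable p is `1/N` (4e-6 at the default N = 250,000). With
#' `exact = TRUE` (small groups only) all distinct assignments are
#' enumerated instead.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param statistic Function of a numeric vector (default [mean()]).
#' @param N Number of random relabelings (default 250000).
#' @param seed Integer seed.
#' @param exact Enumerate all assignments (requires `choose(nA+nB, nA)`
#'   manageable).
#' @return List with `observed`, `p_value`, `N` (resamples actually used),
#'   `min_p`, `direction`.
#' @export
permutation_test <- function(a, b, statistic = mean, N = 250000, seed = 1L,
                             exact = FALSE) {
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  observed <- statistic(a) - statistic(b)
  if (exact) {
    combs <- utils::combn(n, na)
    diffs <- apply(combs, 2, function(ii) {
      statistic(pooled[ii]) - statistic(pooled[-ii])
    })
    N_used <- ncol(combs)
    count <- sum(abs(diffs) >= abs(observed) - 1e-12)
    p <- count / N_used
  } else {
    diffs <- with_seed(seed, {
      vapply(seq_len(N), function(i) {
        ii <- sample.int(n, na)
        statistic(pooled[ii]) - statistic(pooled[-ii])
      }, numeric(1))
    })
    N_used <- N
    count <- sum(abs(diffs) >= abs(observed) - 1e-12)
    p <- max(count, 1) / N
  }
  if (all(abs(diffs - diffs[1]) < 1e-15) && abs(observed - diffs[1]) < 1e-15) {
    p <- 1  # statistic constant under relabeling: degenerate
  }
  list(observed = observed, p_value = min(p, 1), N = N_used,
       min_p = 1 / N_used,
       direction = if (observed >= 0) "A>B" else "A<B")
}

#' Benjamini-Hochberg correction
#'
#' Standard step-up false-discovery-rate control: adjusted p-values are
#' `min over j >= i of m * p_(j) / j`, capped at 1; hypotheses with adjusted
#' p at or below `q` are rejected.
#'
#' @param p P-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (same order as input) and `rejected`
#'   (logical); empty input gives empty output.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(adjusted = numeric(0), rejected = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines z-transformed sample skewness and kurtosis into the K^2 statistic
#' (chi-squared with 2 df under normality). Used only by the test-selection
#' dispatcher; population analyses default to the resampling tests.
#'
#' @param x Numeric vector (n >= 20 recommended).
#' @return List with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("need n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  stdb2 <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + stdb2 * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Parametric-vs-rank test dispatcher
#'
#' Chooses between t-tests and rank tests from pairedness and normality
#' (D'Agostino-Pearson on each sample at `alpha_norm`): normal data get a
#' (paired) t-test, non-normal data a Mann-Whitney U or Wilcoxon signed-rank
#' test. Provided for parity with conventional analysis pipelines; the
#' package's population comparisons default to [permutation_test()] and
#' [bootstrap_population_stat()].
#'
#' @param x,y Samples.
#' @param paired Paired comparison?
#' @param alpha_norm Normality alpha (default 0.05).
#' @return List with `test` (name), `p_value`, `normal` (per-sample flags).
#' @export
choose_test <- function(x, y, paired = FALSE, alpha_norm = 0.05) {
  nx <- dagostino_pearson(x)$p_value
  ny <- dagostino_pearson(y)$p_value
  normal <- c(x = nx >= alpha_norm, y = ny >= alpha_norm)
  if (all(normal)) {
    ht <- stats::t.test(x, y, paired = paired)
    name <- if (paired) "paired t-test" else "independent t-test"
  } else if (paired) {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    name <- "Wilcoxon signed-rank"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    name <- "Mann-Whitney U"
  }
  list(test = name, p_value = ht$p.value, normal = normal)
}
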