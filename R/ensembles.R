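#' Sample ensembles from a session
#'
#' Draws exactly n2 ensembles of size `n1` from a session with n2
#' simultaneously recorded units, each ensemble a uniform draw of distinct
#' units. Capping the number of sampled ensembles at n2 keeps high-yield
#' sessions from dominating pooled ensemble statistics while representing
#' every recorded unit equally.
#'
#' @param unit_ids Unit identifiers of one session (length n2).
#' @param n1 Ensemble size (<= n2).
#' @param seed Integer seed.
#' @return List of character vectors of member unit ids (length n2).
#' @export
sample_ensembles <- function(unit_ids, n1, seed = 1L) {
  n2 <- length(unit_ids)
  if (n1 > n2) stop("ensemble size n1 exceeds session unit count n2")
  with_seed(seed, {
    lapply(seq_len(n2), function(i) sample(unit_ids, n1))
  })
}

#' Categorize an ensemble by its CR/NCR composition
#'
#' Composition bands: ensembles with at most 30% non-classically responsive
#' members are CR ensembles (70-100% classically responsive); 50-70% NCR is
#' mixed; at least 80% NCR is an NCR ensemble. Fractions falling in the
#' uncovered gaps (30-50%, 70-80%) are uncategorized and dropped from
#' category contrasts.
#'
#' @param member_labels `"CR"`/`"NCR"` final labels of the members.
#' @return List with `category` (`"CR_ensemble"`, `"mixed"`,
#'   `"NCR_ensemble"`, `"uncategorized"`) and `fraction_ncr`.
#' @export
categorize_ensemble <- function(member_labels) {
  f <- mean(member_labels == "NCR")
  category <- if (f <= 0.30) "CR_ensemble"
  else if (f >= 0.50 && f <= 0.70) "mixed"
  else if (f >= 0.80) "NCR_ensemble"
  else "uncategorized"
  list(category = category, fraction_ncr = f)
}

#' Cross-validated ensemble ISI decoding
#'
#' Generalizes [crossval_decode()] to simultaneously recorded ensembles:
#' within each cross-validation split every member's per-condition ISI
#' density is fit on the training folds, and each member's ISI likelihoods
#' independently update the trial's log posterior (ISIs are assumed
#' independent across and within members given the condition). The same
#' fold partition is applied to all members, so an ensemble of size 1 is
#' identical - sample for sample - to single-cell decoding under the same
#' seed.
#'
#' @param spikes_list Named list of member spike-time vectors, or of
#'   per-trial ISI lists.
#' @param trials Shared session trial table.
#' @param task `"stimulus"` or `"choice"`.
#' @param k,iterations,seed,window,priors As in [crossval_decode()].
#' @return A `decoding_result` (level `"ensemble"` when > 1 member).
#' @export
decode_ensemble <- function(spikes_list, trials,
                            task = c("stimulus", "choice"), k = 10,
                            iterations = 500, seed = 1L, window = c(0, 2.5),
                            priors = NULL) {
  task <- match.arg(task)
  isis_by_unit <- lapply(spikes_list, function(sp) {
    if (is.list(sp)) sp else trial_isis(sp, trials, window)
  })
  cv_decode_core(isis_by_unit, task_labels(trials, task), k = k,
                 iterations = iterations, seed = seed, priors = priors)
}
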