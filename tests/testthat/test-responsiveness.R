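test_that("spontaneous rate matches a direct per-trial recount", {
  tr <- fixed_trials(20)
  # exactly 3 spikes in every 150-ms baseline window => 20 spikes/s
  sp <- spikes_at_offsets(tr, c(-0.14, -0.09, -0.01))
  expect_equal(spontaneous_rate(sp, tr), 20)
  expect_equal(spontaneous_rate(numeric(0), tr), 0)
  # random fixture vs brute-force recount
  set.seed(7)
  sp2 <- sort(runif(500, 0, max(tr$onset_s) + 3))
  oracle <- mean(vapply(tr$onset_s, function(on) {
    sum(sp2 >= on - 0.15 & sp2 < on)
  }, numeric(1))) / 0.15
  expect_equal(spontaneous_rate(sp2, tr), oracle)
})

test_that("evoked rate picks the extremal sliding window with its sign", {
  tr <- fixed_trials(20)
  base <- spikes_at_offsets(tr, seq(-0.149, -0.001, by = 0.05))  # 20 sp/s
  # a burst at 60-110 ms adds one window of elevated rate
  burst <- spikes_at_offsets(tr, c(0.062, 0.071, 0.083, 0.094))
  ev <- evoked_rate(sort(c(base, spikes_at_offsets(tr, seq(0.005, 0.195, by = 0.05)))), tr)
  expect_equal(ev$evoked, 0)  # rate identical to baseline in all windows
  # silenced unit: 0 spikes post-onset, baseline 20 => -20
  ev2 <- evoked_rate(base, tr)
  expect_equal(ev2$evoked, -20)
  expect_gt(evoked_rate(sort(c(base, burst)), tr)$evoked, 0)
})

test_that("modulation equals the exhaustive window-scan oracle on random fixtures", {
  tr <- fixed_trials(15)
  for (r in 1:12) {
    set.seed(100 + r)
    sp <- sort(runif(800, 0, max(tr$onset_s) + 3))
    o <- oracle_modulation(sp, tr)
    ev <- evoked_rate(sp, tr)
    sm <- stimulus_modulation(sp, tr)
    expect_equal(ev$evoked, o$evoked, tolerance = 1e-12)
    expect_equal(sm$modulation, o$modulation, tolerance = 1e-12)
    expect_equal(sm$modulation, abs(ev$evoked), tolerance = 1e-12)
    expect_equal(ev$window_offset, o$offset)
  }
})

test_that("tone selectivity is the normalized absolute-response contrast", {
  expect_equal(tone_selectivity(3, 3), 0)
  expect_equal(tone_selectivity(3, -3), 0)  # |RT| = |RNT|
  expect_equal(tone_selectivity(1, 0), 1)
  expect_equal(tone_selectivity(1, 3), -0.5)
  # antisymmetry
  expect_equal(tone_selectivity(2, 5), -tone_selectivity(5, 2))
  expect_warning(si <- tone_selectivity(0, 0), "undefined")
  expect_true(is.na(si))
  # bounded in [-1, 1]
  for (r in 1:20) {
    set.seed(r)
    v <- rnorm(2) * 10
    if (sum(abs(v)) == 0) next
    expect_lte(abs(tone_selectivity(v[1], v[2])), 1)
  }
})

test_that("choice modulation counts spikes in response-locked windows", {
  tr <- fixed_trials(20)
  # unit firing 5 extra spikes inside every 100-ms choice window, baseline 0
  ctr <- ifelse(is.na(tr$response_time_s),
                tr$onset_s + mean(tr$response_time_s - tr$onset_s, na.rm = TRUE),
                tr$response_time_s)
  sp <- sort(as.vector(outer(ctr, c(-0.04, -0.02, 0, 0.02, 0.04), `+`)))
  cm <- choice_modulation(sp, tr)
  expect_equal(cm$modulation, 50)
  # translation invariance: shifting spikes and responses together
  tr2 <- tr
  tr2$response_time_s <- tr2$response_time_s + 0.3
  ctr2 <- ifelse(is.na(tr2$response_time_s),
                 tr2$onset_s + mean(tr2$response_time_s - tr2$onset_s, na.rm = TRUE),
                 tr2$response_time_s)
  sp2 <- sort(as.vector(outer(ctr2, c(-0.04, -0.02, 0, 0.02, 0.04), `+`)))
  expect_equal(choice_modulation(sp2, tr2)$modulation, cm$modulation)
  # no go trials => error
  tr3 <- fixed_trials(10)
  tr3$response_time_s <- NA_real_
  expect_error(choice_modulation(sp, tr3), "go trials")
})

test_that("subsampled bootstrap labels strong modulation CR and exact nulls NCR", {
  tr <- fixed_trials(40)
  # all per-trial count changes exactly 0: every subsample mean is 0 => NCR
  sp <- spikes_at_offsets(tr, c(-0.03, 0.02))  # one spike in each 50-ms window
  bc <- bootstrap_classify(sp, tr, "stimulus", seed = 3)
  expect_equal(bc$label, "NCR")
  expect_equal(bc$frac_inside, 1)
  # large reliable change: 3 extra spikes in the tone window every trial
  sp2 <- sort(c(sp, spikes_at_offsets(tr, c(0.005, 0.015, 0.04))))
  bc2 <- bootstrap_classify(sp2, tr, "stimulus", seed = 3)
  expect_equal(bc2$label, "CR")
  expect_equal(bc2$frac_outside, 1)
  # below the trial floor: indeterminate with warning
  expect_warning(bc3 <- bootstrap_classify(sp, tr[1:10, ], "stimulus"),
                 "floor")
  expect_equal(bc3$label, "indeterminate")
  # seeded determinism
  s <- quick_session(n_trials = 60, stim_delta = 4, shapes = c(1, 1), seed = 5)
  b1 <- bootstrap_classify(s$spikes[[1]], s$trials, "stimulus", seed = 11)
  b2 <- bootstrap_classify(s$spikes[[1]], s$trials, "stimulus", seed = 11)
  expect_identical(b1, b2)
})

test_that("bootstrap classifier is calibrated on null units", {
  labs <- vapply(1:40, function(r) {
    s <- quick_session(n_trials = 200, baseline = 5, stim_delta = 0,
                       shapes = c(1, 1), seed = 4000 + r)
    bootstrap_classify(s$spikes[[1]], s$trials, "stimulus", n_boot = 2000,
                       seed = r)$label
  }, character(1))
  expect_lte(mean(labs == "CR"), 0.05)
  expect_gte(mean(labs %in% c("NCR", "indeterminate")), 0.95)
})

test_that("separating threshold is the max-margin midpoint, matching a scan oracle", {
  fit <- fit_separating_threshold(
    c(0.1, 0.2, 4.0, 5.0, 0.05, 0.15, 4.4, 4.9, 4.1, 4.6),
    c("NCR", "NCR", "CR", "CR", "NCR", "NCR", "CR", "CR", "CR", "CR"),
    min_per_class = 2)
  expect_equal(fit$threshold, 2.1)
  # adding a duplicate interior point does not move a separable boundary
  fit2 <- fit_separating_threshold(c(0.1, 0.2, 0.2, 4.0, 5.0, 0.05, 0.15, 4.4, 4.9, 4.1, 4.6),
                                   c("NCR", "NCR", "NCR", "CR", "CR", "NCR", "NCR", "CR", "CR", "CR", "CR"),
                                   min_per_class = 2)
  expect_equal(fit2$threshold, 2.1)
  expect_error(fit_separating_threshold(1:3, rep("CR", 3)), "empty")
  # hinge-loss equivalence with a brute-force 1-D grid scan on noisy inputs
  scan_loss <- function(th, x, lab) {
    cr <- x[lab == "CR"]; ncr <- x[lab == "NCR"]
    sum(pmax(0, th - cr[cr < th])) + sum(pmax(0, ncr[ncr >= th] - th))
  }
  for (r in 1:10) {
    set.seed(200 + r)
    x <- c(abs(rnorm(12, 1, 0.8)), abs(rnorm(12, 4, 1.5)))
    lab <- rep(c("NCR", "CR"), each = 12)
    fit <- suppressWarnings(fit_separating_threshold(x, lab))
    grid <- seq(0, max(x) + 0.5, by = 0.001)
    best <- min(vapply(grid, scan_loss, numeric(1), x = x, lab = lab))
    expect_lte(fit$loss, best + 1e-9)
  }
})

test_that("threshold classification applies the documented tie rule", {
  fit <- list(threshold = 2)
  expect_equal(classify_by_threshold(0, fit), "NCR")
  expect_equal(classify_by_threshold(2, fit), "CR")  # tie goes to CR
  expect_equal(classify_by_threshold(c(1.9, 2.1), fit), c("NCR", "CR"))
})

test_that("unit inclusion enforces the 0.5 spikes/s and refractory rules", {
  inc <- unit_inclusion(seq(0, 100, by = 1), span = 100)
  expect_true(inc$included)  # 1 spikes/s
  expect_false(unit_inclusion(c(1, 50), span = 200)$included)
  expect_true(unit_inclusion(c(1, 1.0005, 2), span = 2)$refractory_violation)
  expect_false(unit_inclusion(c(1, 1.1, 2), span = 2)$refractory_violation)
})

test_that("best frequency is the argmax of absolute evoked response", {
  freqs <- c(4, 8, 16, 32, 64)
  bf <- best_frequency(freqs, c(0, 0, 5, 0, 0))
  expect_equal(bf$best_frequency, 16)
  # suppressed responses count through the absolute value
  expect_equal(best_frequency(freqs, c(0, -8, 5, 0, 0))$best_frequency, 8)
  # argmax agrees with exhaustive comparison on random curves
  for (r in 1:10) {
    set.seed(r)
    ev <- rnorm(5) * 5
    expect_equal(best_frequency(freqs, ev)$best_index,
                 which(abs(ev) == max(abs(ev)))[1])
  }
  # symmetric tuning centers symmetrically
  ctr <- best_frequency(freqs, c(1, 3, 9, 3, 1))$centered
  expect_equal(ctr$offset, -2:2)
  expect_equal(ctr$evoked[ctr$offset == -1], ctr$evoked[ctr$offset == 1])
  expect_warning(bfz <- best_frequency(freqs, rep(0, 5)), "undefined")
  expect_true(is.na(bfz$best_frequency))
})
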