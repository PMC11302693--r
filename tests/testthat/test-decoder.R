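test_that("ISI extraction is the diff of in-window spikes", {
  sp <- c(0.10, 0.25, 0.45, 3.0, 3.2)
  expect_equal(extract_isis(sp, 0, c(0, 2.5)), c(0.15, 0.20))
  expect_equal(extract_isis(sp, 0, c(0.3, 2.5)), numeric(0))  # one spike
  expect_equal(extract_isis(numeric(0), 0), numeric(0))
  # recount oracle on random fixtures
  for (r in 1:10) {
    set.seed(r)
    sp2 <- sort(runif(100, 0, 10))
    on <- runif(1, 1, 5)
    sub <- sp2[sp2 >= on & sp2 < on + 2.5]
    expect_equal(extract_isis(sp2, on), if (length(sub) < 2) numeric(0)
                 else diff(sub))
  }
})

test_that("ISI KDE integrates to one and CV picks a sensible bandwidth", {
  set.seed(5)
  isis <- exp(rnorm(300, log(0.1), 0.7))
  d <- fit_isi_density(isis)
  # density over the log-ISI axis integrates to 1
  f <- function(z) exp(isi_log_density(d, exp(z)))
  expect_lt(abs(integrate(f, -12, 6, subdivisions = 500L)$value - 1), 1e-3)
  # chosen bandwidth beats the grid endpoints on held-out likelihood
  tab <- d$cv_table
  best <- tab$cv_loglik[tab$bandwidth == d$bandwidth]
  expect_gte(best, tab$cv_loglik[1])
  expect_gte(best, tab$cv_loglik[nrow(tab)])
  # duplicating the data does not increase the chosen bandwidth
  d2 <- fit_isi_density(c(isis, isis))
  expect_lte(d2$bandwidth, d$bandwidth)
  # deterministic: pure function of inputs
  expect_identical(fit_isi_density(isis)$bandwidth, d$bandwidth)
  expect_warning(dsmall <- fit_isi_density(rep(0.1, 3)), "widest")
  expect_true(dsmall$bandwidth > 0)
})

test_that("trial posteriors follow Bayes rule over per-ISI likelihoods", {
  set.seed(9)
  dens <- list(target = fit_isi_density(exp(rnorm(200, log(0.05), 0.5))),
               nontarget = fit_isi_density(exp(rnorm(200, log(0.3), 0.5))))
  # empty ISI set: prior passthrough
  expect_equal(decode_trial(dens, numeric(0)),
               c(target = 0.5, nontarget = 0.5))
  pri <- c(target = 0.7, nontarget = 0.3)
  expect_equal(decode_trial(dens, numeric(0), pri), pri)
  # single ISI, flat priors: posterior = likelihood ratio / (1 + ratio)
  isi <- 0.06
  l1 <- exp(isi_log_density(dens$target, isi))
  l2 <- exp(isi_log_density(dens$nontarget, isi))
  post <- decode_trial(dens, isi)
  expect_equal(unname(post["target"]), l1 / (l1 + l2), tolerance = 1e-12)
  # multi-ISI posterior equals the linear-space product oracle
  isis <- c(0.04, 0.09, 0.2)
  lin1 <- prod(exp(isi_log_density(dens$target, isis))) * 0.5
  lin2 <- prod(exp(isi_log_density(dens$nontarget, isis))) * 0.5
  post2 <- decode_trial(dens, isis)
  expect_equal(unname(post2["target"]), lin1 / (lin1 + lin2),
               tolerance = 1e-9)
  expect_equal(sum(post2), 1, tolerance = 1e-12)
})

test_that("cross-validated decoding separates ISI-coded conditions and is seeded", {
  sess <- quick_session(n_trials = 100, shapes = c(0.6, 2.5), seed = 21)
  dr <- crossval_decode(sess$spikes[[1]], sess$trials, "stimulus",
                        iterations = 10, seed = 31)
  expect_gt(dr$mean_accuracy, 0.8)
  expect_true(all(dr$accuracy_samples >= 0 & dr$accuracy_samples <= 1))
  expect_length(dr$accuracy_samples, 100)  # k x iterations
  dr2 <- crossval_decode(sess$spikes[[1]], sess$trials, "stimulus",
                         iterations = 10, seed = 31)
  expect_identical(dr$accuracy_samples, dr2$accuracy_samples)
  expect_error(crossval_decode(sess$spikes[[1]], sess$trials[1:12, ],
                               "stimulus"), ">= k")
})

test_that("label permutation drives accuracy to chance", {
  # an uninformative unit (equal ISI shapes, no rate change) under a label
  # shuffle: no structure for the decoder to find
  sess <- quick_session(n_trials = 100, shapes = c(1, 1), seed = 23)
  tr <- sess$trials
  set.seed(77)
  tr$stimulus <- sample(tr$stimulus)
  dr <- crossval_decode(sess$spikes[[1]], tr, "stimulus", iterations = 20,
                        seed = 5)
  expect_lt(abs(dr$mean_accuracy - 0.5), 0.02)
})

test_that("synthetic controls preserve trial length and the pooled ISI pool", {
  sess <- quick_session(n_trials = 200, shapes = c(1, 1), seed = 25)
  isis <- isidecode:::trial_isis(sess$spikes[[1]], sess$trials)
  ctrl <- make_synthetic_control(isis, 2.5, seed = 9)
  expect_length(ctrl, length(isis))
  # every surrogate trial fits its window
  expect_true(all(vapply(ctrl, sum, numeric(1)) <= 2.5))
  # per-trial ISI counts match the pooled ISI rate to first order:
  # E[count] ~ window / mean(pooled ISIs), minus an O(1) stopping overshoot
  mu <- mean(unlist(isis))
  expect_lt(abs(mean(lengths(ctrl)) - 2.5 / mu) / (2.5 / mu), 0.05)
  # counts track the real trials too, up to the window-boundary gaps the
  # surrogate fills but real spike trains spend on entry/exit intervals
  expect_lt(abs(mean(lengths(ctrl)) - mean(lengths(isis))) /
              mean(lengths(isis)), 0.25)
  # pooled surrogate ISI distribution tracks the empirical pool (the
  # stopping rule conditions kept draws on fitting the window, which tilts
  # quantiles slightly short)
  qr <- quantile(unlist(isis), c(0.25, 0.5, 0.75))
  qc <- quantile(unlist(ctrl), c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qr - qc) / qr), 0.2)
  # surrogate ISIs are draws from the pooled set
  expect_true(all(unlist(ctrl) %in% unlist(isis)))
  expect_error(make_synthetic_control(list(numeric(0)), 2.5), "pooled")
  expect_identical(make_synthetic_control(isis, 2.5, seed = 9), ctrl)
})

test_that("rate-matched ISI-coded units beat their synthetic controls", {
  sess <- quick_session(n_trials = 100, shapes = c(0.6, 2.5), seed = 27)
  isis <- isidecode:::trial_isis(sess$spikes[[1]], sess$trials)
  dr <- crossval_decode(isis, sess$trials, "stimulus", iterations = 10,
                        seed = 41)
  ctrl <- make_synthetic_control(isis, 2.5, seed = 43)
  dc <- crossval_decode(ctrl, sess$trials, "stimulus", iterations = 10,
                        seed = 41)
  # condition-wise mean rates are matched by construction
  cnt <- lengths(isis)
  expect_lt(abs(mean(cnt[sess$trials$stimulus == "target"]) -
                  mean(cnt[sess$trials$stimulus == "nontarget"])) /
              mean(cnt), 0.12)
  sig <- significance_vs_control(dr$accuracy_samples, dc$accuracy_samples)
  expect_lt(sig$p_value, 0.05)
  expect_true(sig$is_significant)
  expect_gt(dr$mean_accuracy, dc$mean_accuracy)
})

test_that("rank-sum significance matches a small-sample U oracle", {
  expect_gt(significance_vs_control(rep(c(0.5, 0.6), 50),
                                    rep(c(0.5, 0.6), 50))$p_value, 0.9)
  # fully separated 100 vs 100
  expect_lt(significance_vs_control(runif(100, 0.8, 0.9),
                                    runif(100, 0.1, 0.2))$p_value, 1e-10)
  # brute-force U on tiny inputs: U = #{(i,j): x_i > y_j} (+ 0.5 ties)
  set.seed(3)
  x <- round(runif(8), 2); y <- round(runif(7), 2)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  expect_equal(unname(w$statistic), u)
  expect_equal(significance_vs_control(x, y)$p_value, w$p.value)
})

test_that("task-encoder threshold reflects the below-chance 5th percentile", {
  # constructed so the below-chance 5th percentile is 0.44 => threshold 0.56
  below <- c(rep(0.44, 10), seq(0.45, 0.50, length.out = 90))
  accs <- c(below, runif(30, 0.55, 0.9))
  th <- task_encoder_threshold(accs)
  expect_equal(th$threshold, 0.56, tolerance = 1e-6)
  # degenerate at chance: zero gap
  expect_equal(task_encoder_threshold(rep(0.5, 25))$threshold, 0.5)
  # the threshold sits the same distance above chance as the 5th percentile
  # sits below it
  expect_equal(th$threshold - 0.5, 0.5 - th$p5, tolerance = 1e-12)
  expect_warning(tw <- task_encoder_threshold(c(0.4, 0.45, 0.7)), "undefined")
  expect_true(is.na(tw$threshold))
})
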