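test_that("generated spike trains hit the specified rates", {
  spec <- unit_gen_spec("u", baseline_rate = 5, stim_delta = 20,
                        true_label = "CR")
  ss <- session_gen_spec(n_units = 1, n_trials = 200, seed = 11)
  sess <- simulate_session(ss, list(spec))
  tr <- sess$trials
  sp <- sess$spikes[[1]]
  tone_rate <- mean(isidecode:::count_in_windows(
    sp, tr$onset_s, tr$onset_s + 0.1)) / 0.1
  expect_lt(abs(tone_rate - 25) / 25, 0.10)
  expect_lt(abs(spontaneous_rate(sp, tr) - 5) / 5, 0.20)
})

test_that("baseline rate is recovered within 5% over replicates", {
  rates <- vapply(1:40, function(r) {
    spec <- unit_gen_spec("u", baseline_rate = 6, true_label = "NCR")
    ss <- session_gen_spec(n_units = 1, n_trials = 200, seed = 5000 + r)
    sess <- simulate_session(ss, list(spec))
    spontaneous_rate(sess$spikes[[1]], sess$trials)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 6) / 6, 0.05)
})

test_that("generators are pure functions of seed and spec", {
  spec <- unit_gen_spec("u", 4, stim_delta = 3, true_label = "CR")
  tr <- fixed_trials(30)
  s1 <- simulate_unit(spec, tr, rep(1, 30), seed = 9)
  s2 <- simulate_unit(spec, tr, rep(1, 30), seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_unit(spec, tr, rep(1, 30), seed = 10)))
  lc1 <- simulate_learning_curve(4, c(0.3, 0.5, 0.8, 0.9), 0.2, 100, seed = 2)
  lc2 <- simulate_learning_curve(4, c(0.3, 0.5, 0.8, 0.9), 0.2, 100, seed = 2)
  expect_identical(lc1, lc2)
  expect_identical(simulate_speed_trace(500, 250, 1, 3, 0.5, seed = 3),
                   simulate_speed_trace(500, 250, 1, 3, 0.5, seed = 3))
})

test_that("spike trains respect the 1-ms refractory period and sorting", {
  spec <- unit_gen_spec("u", 15, isi_shape_target = 0.4,
                        isi_shape_nontarget = 0.4, true_label = "NCR")
  tr <- fixed_trials(50)
  sp <- simulate_unit(spec, tr, rep(1, 50), seed = 4)
  expect_true(all(diff(sp) >= 0.001))
})

test_that("invalid unit and session specs are rejected", {
  expect_error(unit_gen_spec("u", 2, stim_delta = -5), "negative")
  expect_error(unit_gen_spec("u", -1), "baseline_rate")
  expect_error(unit_gen_spec("u", 2, isi_shape_target = 0), "isi_shape")
  spec <- unit_gen_spec("u", 2)
  expect_error(simulate_unit(spec, fixed_trials(0), numeric(0), 1), "empty")
  expect_error(simulate_unit(spec, fixed_trials(5), rep(1, 3), 1), "gain")
  expect_error(session_gen_spec(1, 10, p_target = 1.2))
})

test_that("shared gain induces positive pairwise spike-count correlations", {
  mean_cor <- function(gain_sd, seed) {
    sess <- quick_session(n_trials = 120, n_units = 6, shapes = c(1, 1),
                          gain_sd = gain_sd, seed = seed)
    cm <- cor(activity_matrix(sess$spikes, sess$trials,
                              window = c(0, 2.5)))
    mean(cm[upper.tri(cm)])
  }
  c0 <- vapply(1:8, function(r) mean_cor(0, 300 + r), numeric(1))
  c1 <- vapply(1:8, function(r) mean_cor(0.5, 300 + r), numeric(1))
  expect_lt(abs(mean(c0)), 0.05)
  expect_gt(mean(c1), mean(c0) + 0.1)
})

test_that("session structure matches its spec and round-trips to disk", {
  sess <- quick_session(n_trials = 60, n_units = 3, seed = 17)
  expect_equal(length(sess$spikes), 3)
  expect_equal(nrow(sess$trials), 60)
  expect_equal(sum(sess$trials$stimulus == "target"), 30)
  # outcomes consistent with stimulus and response presence
  with(sess$trials, {
    expect_true(all(outcome[stimulus == "target"] %in% c("hit", "miss")))
    expect_true(all(outcome[stimulus == "nontarget"] %in%
                      c("false_alarm", "correct_reject")))
    expect_true(all(is.na(response_time_s[outcome %in%
                                            c("miss", "correct_reject")])))
    rt <- response_time_s[!is.na(response_time_s)]
    on <- onset_s[!is.na(response_time_s)]
    expect_true(all(rt - on > 0 & rt - on <= 2.5))
  })
  dir <- withr::local_tempdir()
  write_session(sess, dir)
  back <- read_session(dir)
  expect_equal(back$trials$onset_s, sess$trials$onset_s)
  expect_equal(back$spikes[["u2"]], sess$spikes[["u2"]], tolerance = 1e-12)
  # ground truth retrievable losslessly
  expect_equal(back$ground_truth$unit_specs[[1]]$baseline_rate,
               sess$ground_truth$unit_specs[[1]]$baseline_rate)
  expect_equal(back$ground_truth$session_spec$shared_gain_sd,
               sess$ground_truth$session_spec$shared_gain_sd)
})

test_that("simulated learning outcomes track their trajectories", {
  lc <- simulate_learning_curve(3, hit_traj = c(0.5, 0.9, 0.9),
                                fa_traj = c(0.5, 0.1, 0.1),
                                trials_per_day = 200, seed = 8)
  perf <- vapply(lc$sessions, function(s) compute_dprime(s)$dprime, numeric(1))
  expect_lt(abs(perf[1]), 0.35)          # H = FA => d' ~ 0
  # hit 0.9 / fa 0.1 => d' ~ qnorm(.9) - qnorm(.1) = 2.563
  expect_lt(abs(perf[2] - 2.563103), 0.45)
  expect_error(simulate_learning_curve(0, 0.5, 0.5, 10, 1), "empty")
})

test_that("speed traces step at the onset frame", {
  tr <- simulate_speed_trace(2000, 500, 1, 5, noise_sd = 0, seed = 1)
  expect_equal(tr[499], 1)
  expect_equal(tr[500], 5)
  d <- vapply(101:1900, function(f) {
    mean(tr[f:(f + 99)]) - mean(tr[(f - 100):(f - 1)])
  }, numeric(1))
  expect_equal(which.max(d) + 100, 500)  # forward-backward diff peaks at onset
  expect_error(simulate_speed_trace(0, 10, 1, 2), "zero-length")
  expect_error(simulate_speed_trace(500, 50, 1, 2), "edges")
})
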