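test_that("two-component dwell mixtures are recovered by histogram fit and MLE", {
  set.seed(61)
  d <- c(rexp(1000, 1 / 0.2), rexp(2000, 1 / 8))
  fit <- fit_dwell_distribution(d, "double")
  g <- glance(fit)
  expect_lt(abs(g$tau1_s - 0.2) / 0.2, 0.2)
  expect_lt(abs(g$tau2_s - 8) / 8, 0.2)
  expect_lt(abs(g$mle_tau1_s - 0.2) / 0.2, 0.15)
  expect_lt(abs(g$mle_tau2_s - 8) / 8, 0.15)
  expect_false(g$degenerate)
  expect_gt(g$r_square, 0.9)
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("single-exponential data collapses the double model and is flagged", {
  set.seed(62)
  d <- rexp(2000, 1 / 3)
  expect_warning(fit <- fit_dwell_distribution(d, "double"), "degenerate")
  expect_true(fit$degenerate)
  fs <- fit_dwell_distribution(d, "single")
  expect_lt(abs(fs$tau1_s - 3) / 3, 0.2)
  expect_error(fit_dwell_distribution(rexp(10)), "at least 30")
})

test_that("model comparison prefers the double model only for two-component data", {
  set.seed(63)
  d2 <- c(rexp(1500, 1 / 0.2), rexp(3000, 1 / 8))
  f_s <- fit_dwell_distribution(d2, "single")
  f_d <- fit_dwell_distribution(d2, "double")
  cmp <- compare_models(f_s, f_d)
  expect_equal(cmp$preferred, "double")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$reduced_r_square_double, cmp$reduced_r_square_single)
  # one-component data: the single model wins in most replicates
  wins <- replicate(20, {
    d1 <- rexp(1000, 1 / 3)
    s1 <- fit_dwell_distribution(d1, "single")
    d1f <- suppressWarnings(fit_dwell_distribution(d1, "double"))
    compare_models(s1, d1f)$preferred == "single"
  })
  expect_gte(mean(wins), 0.9)
  # mismatched fits are rejected
  other <- fit_dwell_distribution(rexp(500, 1 / 2), "single")
  expect_error(compare_models(other, f_d), "not nested")
  expect_error(compare_models(f_d, f_d), "single-model")
})

test_that("mode proportions partition to 100% and ignore ordering and scale", {
  ev <- tibble::tibble(
    mode = c(rep("ultrafast", 2), rep("fast", 5), rep("ultraslow", 3))
  )
  mp <- mode_proportions(ev)
  expect_equal(sum(mp$percent), 100)
  expect_equal(mp$percent[mp$mode == "fast"], 50)
  mp2 <- mode_proportions(ev[sample(nrow(ev)), , drop = FALSE])
  expect_equal(mp, mp2)
  # trivial cases
  expect_equal(mode_proportions(tibble::tibble(mode = "ultraslow"))$percent,
               c(0, 0, 100))
  expect_equal(
    mode_proportions(tibble::tibble(mode = "ultrafast"))$percent[1], 100
  )
  expect_error(mode_proportions(ev[0, , drop = FALSE]), "at least one")
})

test_that("retrieval versus dwell reports per-bin mean and SD, omitting empty bins", {
  ev <- tibble::tibble(
    dwell_s = c(0.05, 0.3, 0.7, 2, 7),
    retrieval_fraction = 1,
    detected = TRUE, multivesicular = FALSE
  )
  tab <- retrieval_vs_dwell(ev)
  expect_equal(tab$mean_fraction, rep(1, 5))
  expect_equal(tab$sd_fraction[tab$n > 1], numeric(0)) # all singleton bins
  expect_false("(10,20]" %in% tab$dwell_bin) # empty bin absent, not zero
  # dispersion grows with dwell when endpoint noise scales with dwell
  set.seed(64)
  d <- runif(4000, 0, 20)
  ev2 <- tibble::tibble(
    dwell_s = d,
    retrieval_fraction = 1 + rnorm(4000, 0, 0.05 + 0.04 * d)
  )
  tab2 <- retrieval_vs_dwell(ev2)
  expect_true(all(diff(tab2$sd_fraction) > 0))
})

test_that("onset-aligned averages expose the two decay phases", {
  cfg <- sim_config(
    duration_s = 420, p_release = 0.9, noise_sd = 0.5,
    multivesicular_prob = 0, mode_weights = c(0.5, 0.5, 0),
    tau_ultrafast_s = 0.2, tau_fast_s = 6, tau_reacidification_s = 0.4,
    retrieval_fraction_dist = list(
      prob = c(partial = 0, quantal = 1, excess = 0),
      partial_mean = 0.55, partial_sd = 0.15, quantal_sd = 0.02,
      excess_mean = 1.35, excess_sd = 0.12, dwell_dispersion_per_s = 0
    ),
    seed = 65
  )
  ds <- simulate_experiment(cfg, 40)
  corr <- correct_photobleaching(ds$traces, stimulus_times_s = ds$stimulus_times_s)
  den <- ck_filter(corr)
  ev <- detect_events(den, ds$stimulus_times_s, detect_config(), raw = corr)
  avg <- average_event_trace(corr, ev)
  expect_true(all(c("time_rel_s", "mean", "sd", "n") %in% names(avg)))
  fit <- fit_two_phase_decay(avg)
  # with rapid re-acidification the averaged decay mirrors the dwell
  # survival: a fast phase near tau_ultrafast and a slow one near tau_fast
  expect_false(fit$degenerate)
  expect_lt(fit$tau1_s, 1)
  expect_equal(fit$tau2_s, 6, tolerance = 6 * 0.35)
  expect_error(average_event_trace(corr, ev[0, , drop = FALSE]), "at least 20")
})

test_that("a single-phase composition collapses the two-phase average fit", {
  cfg <- sim_config(
    duration_s = 420, p_release = 0.9, noise_sd = 0.3,
    multivesicular_prob = 0, mode_weights = c(1, 0, 0),
    tau_reacidification_s = 0.4,
    seed = 66
  )
  ds <- simulate_experiment(cfg, 30)
  corr <- correct_photobleaching(ds$traces, stimulus_times_s = ds$stimulus_times_s)
  ev <- detect_events(ck_filter(corr), ds$stimulus_times_s, detect_config(),
                      raw = corr)
  avg <- average_event_trace(corr, ev, post_s = 10)
  fit <- fit_two_phase_decay(avg)
  expect_true(fit$degenerate)
})

test_that("train responses recover amplitude, slope and decay constant", {
  cfg <- sim_config(sampling_rate_hz = 10, duration_s = 120, noise_sd = 0,
                    bleach_amplitude = 0, stimulus_times_s = numeric(0))
  tr <- simulate_train_trace(cfg, endo_tau_s = 4, train_start_s = 20)
  truth <- attr(tr, "train_truth")
  fit <- analyze_train_response(tr, 20, 25)
  expect_true(fit$fit_ok)
  expect_equal(fit$amplitude, truth$amplitude, tolerance = 1e-6)
  expect_equal(fit$rise_slope, truth$rise_slope, tolerance = 1e-6)
  expect_equal(fit$decay_tau_s, 4, tolerance = 1e-4)
  # flat trace: amplitude ~ 0 and the fit is flagged
  flat <- tibble::tibble(time_s = tr$time_s, bouton_id = "f",
                         intensity = 20 + rnorm(nrow(tr), 0, 0.5))
  ff <- analyze_train_response(flat, 20, 25)
  expect_false(ff$fit_ok)
  expect_error(analyze_train_response(tr, 115, 125), "within")
})

test_that("a 2.5-fold change in endocytic speed is recovered from noisy trains", {
  cfg <- sim_config(sampling_rate_hz = 10, duration_s = 160, noise_sd = 1,
                    bleach_amplitude = 5, stimulus_times_s = numeric(0), seed = 67)
  f1 <- analyze_train_response(
    simulate_train_trace(cfg, endo_tau_s = 10, train_start_s = 20), 20, 25
  )
  cfg$seed <- 68
  f2 <- analyze_train_response(
    simulate_train_trace(cfg, endo_tau_s = 4, train_start_s = 20), 20, 25
  )
  expect_equal(f1$decay_tau_s / f2$decay_tau_s, 2.5, tolerance = 0.25)
})
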