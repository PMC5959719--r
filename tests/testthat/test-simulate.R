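test_that("same seed reproduces a dataset bit for bit, different seeds do not", {
  cfg <- quick_config(seed = 11)
  a <- simulate_experiment(cfg, 2)
  b <- simulate_experiment(cfg, 2)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  cfg2 <- quick_config(seed = 12)
  c <- simulate_experiment(cfg2, 2)
  expect_false(identical(a$traces$intensity, c$traces$intensity))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(p_release = 1.2), "p_release")
  expect_error(sim_config(stimulus_times_s = c(10, 5)), "increasing")
  expect_error(sim_config(stimulus_times_s = c(10, 500)), "within")
  expect_error(sim_config(mode_weights = c(0.5, 0.5, 0.5)), "mode_weights")
  expect_error(sim_config(tau_fast_s = -1), "positive")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(simulate_experiment(quick_config(), 0), "n_boutons")
})

test_that("fusion outcomes follow the configured release probability", {
  cfg <- quick_config(p_release = 0.15, seed = 21)
  ds <- simulate_experiment(cfg, 400) # 2400 Bernoulli draws
  n <- nrow(ds$truth)
  k <- sum(ds$truth$fused)
  ci <- qbinom(c(0.005, 0.995), n, 0.15) / n # independent binomial oracle
  expect_gte(k / n, ci[1])
  expect_lte(k / n, ci[2])
})

test_that("true kinetic modes follow the configured weights", {
  cfg <- quick_config(p_release = 0.6, seed = 22,
                      mode_weights = c(0.2, 0.4, 0.4))
  ds <- simulate_experiment(cfg, 400)
  modes <- ds$truth$true_mode[ds$truth$fused]
  n <- length(modes)
  for (i in seq_along(cfg$mode_weights)) {
    p <- cfg$mode_weights[i]
    k <- sum(modes == names(cfg$mode_weights)[i])
    ci <- qbinom(c(0.005, 0.995), n, p) / n
    expect_gte(k / n, ci[1])
    expect_lte(k / n, ci[2])
  }
})

test_that("noiseless traces are exactly reconstructible from ground truth", {
  cfg <- quick_config(noise_sd = 0, p_release = 0.8, seed = 23)
  ds <- simulate_experiment(cfg, 3)
  for (b in unique(ds$traces$bouton_id)) {
    y <- ds$traces$intensity[ds$traces$bouton_id == b]
    y_hat <- reconstruct_from_truth(ds$truth[ds$truth$bouton_id == b, ], cfg)
    expect_equal(y, y_hat, tolerance = 1e-12)
  }
})

test_that("dwell times follow the truncated exponential class distributions", {
  cfg <- sim_config(duration_s = 1010, p_release = 1,
                    stimulus_times_s = seq(10, 990, 20), seed = 24)
  ds <- simulate_experiment(cfg, 60) # ~3000 events
  tr <- ds$truth[ds$truth$fused, ]
  ptrunc <- function(q, tau, lo, hi) {
    (pexp(pmin(pmax(q, lo), hi), 1 / tau) - pexp(lo, 1 / tau)) /
      (pexp(hi, 1 / tau) - pexp(lo, 1 / tau))
  }
  uf <- tr$true_dwell_s[tr$true_mode == "ultrafast"]
  fa <- tr$true_dwell_s[tr$true_mode == "fast"]
  expect_gt(length(uf), 400)
  expect_gt(
    suppressWarnings(ks.test(uf, ptrunc, tau = cfg$tau_ultrafast_s,
                             lo = 0, hi = 1))$p.value, 0.01
  )
  expect_gt(
    suppressWarnings(ks.test(fa, ptrunc, tau = cfg$tau_fast_s,
                             lo = 1, hi = cfg$ultraslow_boundary_s))$p.value, 0.01
  )
  # censoring and mode labels are consistent
  expect_true(all(is.na(tr$true_dwell_s) == tr$true_censored))
  expect_true(all((tr$true_mode == "ultraslow") == tr$true_censored))
})

test_that("negative controls have no fused events and Gaussian-tail exceedances", {
  cfg <- quick_config(seed = 25)
  ds <- simulate_negative_control(cfg, 60)
  expect_false(any(ds$truth$fused))
  # raw per-frame 3-sigma exceedance of the noise matches the Gaussian tail
  trend <- cfg$background_level +
    cfg$bleach_amplitude * exp(-unique(ds$traces$time_s) / cfg$bleach_tau_s)
  z <- (ds$traces$intensity - rep(trend, 60)) / cfg$noise_sd
  p_hat <- mean(z > 3)
  p_theory <- pnorm(3, lower.tail = FALSE) # independent Gaussian-tail oracle
  n <- length(z)
  expect_lt(abs(p_hat - p_theory), 3 * sqrt(p_theory * (1 - p_theory) / n) + 1e-4)
})

test_that("train traces have the constructed rise and decay", {
  cfg <- sim_config(duration_s = 120, stimulus_times_s = numeric(0),
                    noise_sd = 0, bleach_amplitude = 0, seed = 26)
  tr <- simulate_train_trace(cfg, endo_tau_s = 10, train_start_s = 20)
  truth <- attr(tr, "train_truth")
  post <- tr$time_s > 25
  expected <- cfg$background_level +
    truth$amplitude * exp(-(tr$time_s[post] - 25) / 10)
  expect_equal(tr$intensity[post], expected, tolerance = 1e-12)
  # zero quantal amplitude: flat trace
  cfg0 <- sim_config(duration_s = 120, stimulus_times_s = numeric(0),
                     quantal_amplitude = 0, noise_sd = 0, bleach_amplitude = 0)
  tr0 <- simulate_train_trace(cfg0, endo_tau_s = 10, train_start_s = 20)
  expect_equal(unique(tr0$intensity), cfg0$background_level)
  expect_error(simulate_train_trace(cfg, endo_tau_s = -1), "endo_tau")
  expect_error(simulate_train_trace(cfg, train_start_s = 118), "within")
})

test_that("retrieval fractions fall in the configured classes", {
  cfg <- quick_config(p_release = 1, seed = 27)
  ds <- simulate_experiment(cfg, 300)
  r <- ds$truth$true_retrieval_fraction
  r <- r[!is.na(r)]
  expect_true(all(r > 0 & r <= 2))
  cls <- cut(r, c(0, 0.8, 1.2, Inf), labels = c("partial", "quantal", "excess"))
  p_hat <- as.numeric(table(cls) / length(r))
  # dwell-dependent jitter moves a few events across class bounds
  expect_true(all(abs(p_hat - c(0.35, 0.5, 0.15)) < 0.06))
})
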