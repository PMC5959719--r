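test_that("a flat noisy trace is essentially unchanged by bleach correction", {
  set.seed(41)
  t <- seq(0, 99.9, 0.1)
  tr <- tibble::tibble(time_s = t, bouton_id = "b1",
                       intensity = 20 + rnorm(length(t)))
  out <- correct_photobleaching(tr)
  expect_lt(mean(abs(out$intensity - tr$intensity)), 0.5)
  f <- bleach_fits(out)
  expect_lt(f$bleach_amplitude * (1 - exp(-100 / f$bleach_tau_s)), 1)
})

test_that("an additive exponential bleach trend is flattened", {
  set.seed(42)
  t <- seq(0, 419.9, 0.1)
  y <- 20 + 10 * exp(-t / 100) + rnorm(length(t))
  tr <- tibble::tibble(time_s = t, bouton_id = "b1", intensity = y)
  pre_slope <- coef(lm(y ~ t))[[2]]
  out <- correct_photobleaching(tr)
  post_slope <- coef(lm(out$intensity ~ t))[[2]]
  expect_lt(abs(post_slope), 0.01 * abs(pre_slope))
  # residuals of the corrected negative control remain Gaussian
  expect_true(noise_gaussianity(out$intensity - mean(out$intensity))$gaussian)
})

test_that("stimulus-aware correction recovers bleach under a staircase of
           non-retrieved events", {
  cfg <- quick_config(p_release = 0.5, seed = 43,
                      mode_weights = c(0, 0, 1)) # every event is ultraslow
  ds <- simulate_experiment(cfg, 4)
  out <- correct_photobleaching(ds$traces, stimulus_times_s = ds$stimulus_times_s)
  # corrected trace must not have invented a strong within-trace trend:
  # compare against the bleach-free construction
  for (b in unique(out$bouton_id)) {
    y <- out$intensity[out$bouton_id == b]
    tr0 <- reconstruct_from_truth(ds$truth[ds$truth$bouton_id == b, ],
                                  modifyList(unclass(cfg), list(bleach_amplitude = 0)))
    resid <- y - tr0
    sm <- stats::filter(resid, rep(1 / 50, 50), sides = 2)
    drift <- diff(range(sm, na.rm = TRUE))
    expect_lt(drift, 5)
  }
})

test_that("the event-free mask precondition is enforced", {
  tr <- step_trace()
  mask <- stimulus_mask(tr, 10, before_s = 0.5, after_s = 20)
  expect_length(mask, nrow(tr))
  expect_true(mean(mask) > 0.1)
  expect_error(correct_photobleaching(tr, rep(FALSE, nrow(tr))), "mask")
  expect_error(correct_photobleaching(tr, c(TRUE, FALSE)), "one element")
})

test_that("background subtraction handles scalars, vectors and traces", {
  tr <- step_trace(noise_sd = 0)
  expect_equal(subtract_background(tr, 0)$intensity, tr$intensity)
  expect_equal(subtract_background(tr, 5)$intensity, tr$intensity - 5)
  nt <- length(unique(tr$time_s))
  bgv <- rep(2, nt)
  expect_equal(subtract_background(tr, bgv)$intensity, tr$intensity - 2)
  bg_tr <- tibble::tibble(time_s = unique(tr$time_s), intensity = 3)
  expect_equal(subtract_background(tr, bg_tr)$intensity, tr$intensity - 3)
  expect_error(subtract_background(tr, c(1, 2, 3)), "matches neither")
})

test_that("cell-free background subtraction recovers a zero-mean baseline", {
  set.seed(44)
  t <- seq(0, 59.9, 0.1)
  bg <- 15 + rnorm(length(t), 0, 0.1)
  tr <- tibble::tibble(time_s = t, bouton_id = "b1",
                       intensity = 15 + rnorm(length(t)))
  out <- subtract_background(tr, tibble::tibble(time_s = t, intensity = bg))
  expect_lt(abs(mean(out$intensity)), 0.1)
})

test_that("bleach-then-background commutes with background-then-bleach", {
  set.seed(45)
  t <- seq(0, 199.9, 0.1)
  y <- 30 + 8 * exp(-t / 80) + rnorm(length(t))
  tr <- tibble::tibble(time_s = t, bouton_id = "b1", intensity = y)
  a <- subtract_background(correct_photobleaching(tr), 10)
  b <- correct_photobleaching(subtract_background(tr, 10))
  expect_lt(mean(abs(a$intensity - b$intensity)), 0.2)
})
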