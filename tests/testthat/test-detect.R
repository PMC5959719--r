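test_that("quantal bounds follow the mean-plus-half-gap rule", {
  set.seed(51)
  # tight, well-separated modes: the rule reduces to simple arithmetic
  a <- c(rnorm(200, 1, 0.02), rnorm(60, 2, 0.03))
  qb <- estimate_quantal_bounds(a)
  expect_equal(qb$upper_limit, 1.5, tolerance = 0.03)
  qb2 <- estimate_quantal_bounds(c(rnorm(200, 10, 0.2), rnorm(60, 20, 0.3)))
  expect_equal(qb2$upper_limit, 15, tolerance = 0.3)
  # realistic overlap: the first mode is still located within 5%
  a3 <- c(rnorm(900, 1, 0.15), rnorm(100, 2, 0.2))
  qb3 <- estimate_quantal_bounds(a3)
  expect_equal(qb3$mean_single_quantum, 1, tolerance = 0.05)
  # unimodal fallback
  expect_warning(qb4 <- estimate_quantal_bounds(rnorm(200, 1, 0.1)), "unimodal")
  expect_equal(qb4$upper_limit, 1.5 * qb4$mean_single_quantum)
  expect_error(estimate_quantal_bounds(rnorm(10)), "at least 50")
})

test_that("a single constructed event is detected at its stimulus, and only there", {
  set.seed(52)
  stim <- seq(10, 110, 20)
  tr <- step_trace(duration = 130, stim = stim[3], amp = 5, dwell = 2,
                   noise_sd = 1)
  den <- ck_filter(tr)
  ev <- detect_events(den, stim, detect_config(), raw = tr)
  expect_equal(sum(ev$detected), 1)
  expect_equal(ev$stimulus_index[ev$detected], 3)
  expect_equal(ev$amplitude[ev$detected], 5, tolerance = 0.25)
})

test_that("events below the 3-sigma threshold are not called", {
  set.seed(53)
  hits <- replicate(20, {
    tr <- step_trace(duration = 40, stim = 10, amp = 2.5, dwell = 2, noise_sd = 1)
    den <- ck_filter(tr)
    ev <- detect_events(den, 10, detect_config(), raw = tr)
    sum(ev$detected)
  })
  expect_lt(mean(hits), 0.5)
})

test_that("noiseless dwell times are recovered within one frame at 10 and 40 Hz", {
  for (fs in c(10, 40)) {
    for (dwell in c(1.5, 2.6, 7.3)) {
      tr <- step_trace(fs = fs, duration = 60, stim = 10, dwell = dwell)
      den <- ck_filter(tr)
      ev <- detect_events(den, 10, detect_config(), raw = tr)
      expect_true(ev$detected)
      expect_false(ev$censored)
      expect_lt(abs(ev$dwell_s - dwell), 1 / fs + 1e-9)
    }
  }
  # an immediate decay yields a dwell of at most one frame
  tr0 <- step_trace(fs = 40, duration = 60, stim = 10, dwell = 0)
  ev0 <- detect_events(ck_filter(tr0), 10, detect_config(), raw = tr0)
  expect_lte(ev0$dwell_s, 1 / 40 + 1e-9)
})

test_that("censoring triggers exactly at the 20 s limit", {
  for (dwell in c(19.5, 20.5, 30)) {
    tr <- step_trace(fs = 10, duration = 120, stim = 10, dwell = dwell)
    ev <- detect_events(ck_filter(tr), 10, detect_config(), raw = tr)
    if (dwell <= 20) {
      expect_false(ev$censored)
      expect_equal(ev$dwell_s, dwell, tolerance = 0.1 + 1e-9)
      expect_equal(ev$mode, "fast")
    } else {
      expect_true(ev$censored)
      expect_true(is.na(ev$dwell_s))
      expect_equal(ev$mode, "ultraslow")
    }
  }
})

test_that("fraction of retrieval and its classes follow the definition", {
  cases <- list(
    list(r = 1.0, class = "quantal"),
    list(r = 0.5, class = "partial"),
    list(r = 1.3, class = "excess")
  )
  for (cs in cases) {
    tr <- step_trace(fs = 10, duration = 60, stim = 10, dwell = 1.5,
                     tau = 2, retrieval = cs$r)
    ev <- detect_events(ck_filter(tr), 10, detect_config(), raw = tr)
    expect_equal(ev$retrieval_fraction, cs$r, tolerance = 0.02)
    expect_equal(ev$retrieval_class, cs$class)
  }
})

test_that("mode classification uses the 1 s and 20 s dwell boundaries", {
  cfg <- detect_config()
  expect_equal(classify_mode(0.25, FALSE, cfg), "ultrafast")
  expect_equal(classify_mode(1.0, FALSE, cfg), "ultrafast")
  expect_equal(classify_mode(5, FALSE, cfg), "fast")
  expect_equal(classify_mode(NA, TRUE, cfg), "ultraslow")
  expect_equal(classify_mode(c(0.5, 3, NA), c(FALSE, FALSE, TRUE), cfg),
               c("ultrafast", "fast", "ultraslow"))
})

test_that("release probability is events over stimuli with mean and SEM", {
  ev <- tibble::tibble(
    bouton_id = rep(c("a", "b"), each = 20),
    status = "x",
    detected = c(rep(c(TRUE, FALSE), c(3, 17)), rep(FALSE, 20))
  )
  rp <- release_probability(ev)
  expect_equal(sort(rp$p_release), c(0, 0.15))
  g <- glance(rp)
  expect_equal(g$mean_p, 0.075)
  expect_equal(g$n_stimuli, 40)
  # skipped stimuli are excluded from the denominator
  ev$status[1] <- "skipped"
  expect_equal(release_probability(ev)$n_stimuli[1], 19)
})

test_that("stimuli without a full baseline window are skipped and flagged", {
  tr <- step_trace(duration = 40, stim = 1)
  ev <- detect_events(ck_filter(tr), c(1, 25), detect_config(), raw = tr)
  expect_equal(ev$status[1], "skipped")
  expect_false(ev$detected[1])
})

test_that("multivesicular candidates are excluded from kinetics but logged", {
  tr <- step_trace(duration = 60, stim = 10, amp = 10, dwell = 2, noise_sd = 0)
  ev <- detect_events(ck_filter(tr), 10, detect_config(), upper_limit = 7.5,
                      raw = tr)
  expect_true(ev$detected)
  expect_true(ev$multivesicular)
  expect_equal(ev$status, "multivesicular")
  expect_true(is.na(ev$dwell_s))
})

test_that("pure-noise traces yield no detections", {
  set.seed(54)
  cfg <- quick_config(seed = 54)
  ds <- simulate_negative_control(cfg, 20)
  corr <- correct_photobleaching(ds$traces, stimulus_times_s = ds$stimulus_times_s)
  ev <- detect_events(ck_filter(corr), ds$stimulus_times_s, detect_config(),
                      raw = corr)
  expect_lte(mean(ev$detected), 0.03)
})

test_that("measure_dwell and fraction_of_retrieval work at the vector level", {
  tr <- step_trace(fs = 10, duration = 60, stim = 10, dwell = 3, retrieval = 1)
  y <- ck_filter(tr$intensity)
  pk <- which(tr$time_s >= 10)[1]
  md <- measure_dwell(y, tr$time_s, pk, baseline_mean = 20)
  expect_false(md$censored)
  expect_equal(md$dwell_s, 3, tolerance = 0.1 + 1e-9)
  fr <- fraction_of_retrieval(y, tr$time_s, pk, baseline_mean = 20)
  expect_equal(fr$retrieval_fraction, 1, tolerance = 0.02)
  expect_equal(fr$retrieval_class, "quantal")
})
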