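# Shared fixtures: all synthetic, built in code at test time.

# minimal quiet config for fast simulations
quick_config <- function(...) {
  sim_config(
    duration_s = 120,
    stimulus_times_s = seq(10, 110, by = 20),
    ...
  )
}

# a single-bouton trace tibble holding an ideal step event: baseline, a
# one-frame rise of `amp`, a plateau of `dwell` seconds, then exponential
# decay towards baseline + (1 - retrieval) * amp
step_trace <- function(fs = 10, duration = 60, stim = 10, amp = 5,
                       dwell = 0.5, tau = 4, retrieval = 1, baseline = 20,
                       noise_sd = 0, bouton_id = "b1") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  y <- rep(baseline, length(t))
  on <- t >= stim
  td <- t[on] - stim
  y[on] <- baseline + amp * ifelse(
    td < dwell, 1, (1 - retrieval) + retrieval * exp(-(td - dwell) / tau)
  )
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_s = t, bouton_id = bouton_id, intensity = y)
}

# closed-form reconstruction of a noiseless simulated bouton from its truth
# records; the independent oracle for the generator
reconstruct_from_truth <- function(truth, config) {
  fs <- config$sampling_rate_hz
  t <- (seq_len(round(config$duration_s * fs)) - 1) / fs
  y <- config$background_level + config$bleach_amplitude * exp(-t / config$bleach_tau_s)
  ev <- truth[truth$fused, ]
  for (i in seq_len(nrow(ev))) {
    ts <- ev$stimulus_time_s[i]
    on <- t >= ts
    if (isTRUE(ev$true_censored[i])) {
      y[on] <- y[on] + ev$true_amplitude[i]
    } else {
      td <- t[on] - ts
      d <- ev$true_dwell_s[i]
      r <- ev$true_retrieval_fraction[i]
      y[on] <- y[on] + ev$true_amplitude[i] * ifelse(
        td < d, 1, (1 - r) + r * exp(-(td - d) / config$tau_reacidification_s)
      )
    }
  }
  y
}
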