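# Synthetic single-vesicle fluorescence data with full ground truth.
#
# The generator reproduces the statistical structure the analysis assumes:
# Bernoulli fusion per stimulus, quantal step amplitudes (with occasional
# two-quantum events), a single-frame rise, a plateau whose duration is drawn
# from the kinetic-class mixture, single-exponential re-acidification decay
# towards a variable retrieval endpoint, additive exponential photobleaching
# drift, and additive Gaussian noise.

# truncated normal via inverse-CDF (lo/hi may be -Inf/Inf)
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# exponential truncated to (lo, hi]
rtrunc_exp <- function(n, tau, lo = 0, hi = Inf) {
  flo <- 1 - exp(-lo / tau)
  fhi <- if (is.finite(hi)) 1 - exp(-hi / tau) else 1
  -tau * log(1 - runif(n, flo, fhi))
}

draw_retrieval_fraction <- function(n, dist, dwell_s) {
  cls <- sample(names(dist$prob), n, replace = TRUE, prob = dist$prob)
  r <- numeric(n)
  r[cls == "partial"] <- rtrunc_norm(sum(cls == "partial"),
                                     dist$partial_mean, dist$partial_sd, 0.05, 0.8)
  r[cls == "quantal"] <- rtrunc_norm(sum(cls == "quantal"), 1, dist$quantal_sd, 0.8, 1.2)
  r[cls == "excess"] <- rtrunc_norm(sum(cls == "excess"),
                                    dist$excess_mean, dist$excess_sd, 1.2, 2)
  disp <- dist$dwell_dispersion_per_s %||% 0
  if (disp > 0) {
    r <- r + rnorm(n, 0, disp * dwell_s)
    r <- pmin(pmax(r, 0.02), 2)
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic piecewise event waveform added to a trace:
# step at the first frame >= ts, plateau for `dwell`, then exponential decay
# towards (1 - r) * amp; censored events never decay.
event_waveform <- function(t, ts, amp, dwell, r, tau_reacid, censored) {
  out <- numeric(length(t))
  on <- t >= ts
  if (!any(on)) return(out)
  if (censored) {
    out[on] <- amp
  } else {
    td <- t[on] - ts
    out[on] <- amp * ifelse(td < dwell, 1, (1 - r) + r * exp(-(td - dwell) / tau_reacid))
  }
  out
}

simulate_one_bouton <- function(config, bouton_id) {
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  signal <- config$background_level +
    config$bleach_amplitude * exp(-t / config$bleach_tau_s)

  stim <- config$stimulus_times_s
  ns <- length(stim)
  fused <- if (ns > 0) runif(ns) < config$p_release else logical(0)
  rows <- vector("list", ns)
  for (k in seq_len(ns)) {
    if (!fused[k]) {
      rows[[k]] <- tibble(
        bouton_id = bouton_id, stimulus_index = k, stimulus_time_s = stim[k],
        fused = FALSE, n_quanta = NA_integer_, true_amplitude = NA_real_,
        true_dwell_s = NA_real_, true_censored = NA,
        true_mode = NA_character_, true_retrieval_fraction = NA_real_
      )
      next
    }
    nq <- 1L + stats::rbinom(1, 1, config$multivesicular_prob)
    amp <- sum(rtrunc_norm(nq, config$quantal_amplitude,
                           config$quantal_cv * config$quantal_amplitude,
                           lo = 0.1 * config$quantal_amplitude))
    mode <- sample(names(config$mode_weights), 1, prob = config$mode_weights)
    ub <- config$ultraslow_boundary_s
    if (mode == "ultrafast") {
      dwell <- rtrunc_exp(1, config$tau_ultrafast_s, 0, 1)
    } else if (mode == "fast") {
      dwell <- rtrunc_exp(1, config$tau_fast_s, 1, ub)
    } else {
      dwell <- NA_real_
    }
    censored <- mode == "ultraslow"
    # plateau running off the end of the trace cannot be observed to decay
    if (!censored && stim[k] + dwell > t[n]) {
      censored <- TRUE
      mode <- "ultraslow"
      dwell <- NA_real_
    }
    r <- if (censored) NA_real_ else {
      draw_retrieval_fraction(1, config$retrieval_fraction_dist, dwell)
    }
    signal <- signal + event_waveform(t, stim[k], amp, dwell, r,
                                      config$tau_reacidification_s, censored)
    rows[[k]] <- tibble(
      bouton_id = bouton_id, stimulus_index = k, stimulus_time_s = stim[k],
      fused = TRUE, n_quanta = nq, true_amplitude = amp,
      true_dwell_s = dwell, true_censored = censored,
      true_mode = mode, true_retrieval_fraction = r
    )
  }
  if (config$noise_sd > 0) signal <- signal + rnorm(n, 0, config$noise_sd)
  list(
    trace = tibble(time_s = t, bouton_id = bouton_id, intensity = signal),
    truth = if (ns > 0) bind_rows(rows) else tibble()
  )
}

#' Simulate a synthetic single-vesicle experiment
#'
#' Generates `n_boutons` independent bouton traces under a [sim_config()]
#' together with a ground-truth table holding one row per stimulus per bouton
#' (fusion outcome, quanta, amplitude, dwell time or censoring flag, kinetic
#' mode and retrieval fraction).
#'
#' @param config A [sim_config()].
#' @param n_boutons Number of independent boutons (>= 1).
#'
#' @return A list of class `sv_dataset` with elements `traces` (tibble:
#'   `time_s`, `bouton_id`, `intensity`), `truth` (ground-truth tibble),
#'   `stimulus_times_s` and `config`.
#' @export
#' @examples
#' ds <- simulate_experiment(sim_config(duration_s = 60,
#'   stimulus_times_s = c(10, 30), seed = 1), n_boutons = 2)
#' dplyr::count(ds$truth, fused)
simulate_experiment <- function(config, n_boutons) {
  config <- validate_sim_config(unclass(config))
  if (!is.numeric(n_boutons) || n_boutons < 1) {
    abort("n_boutons must be >= 1")
  }
  n_boutons <- as.integer(n_boutons)
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("b%04d", seq_len(n_boutons))
  parts <- map(ids, function(id) simulate_one_bouton(config, id))
  structure(
    list(
      traces = bind_rows(map(parts, "trace")),
      truth = bind_rows(map(parts, "truth")),
      stimulus_times_s = config$stimulus_times_s,
      config = config
    ),
    class = "sv_dataset"
  )
}

#' Simulate a single bouton trace with ground truth
#'
#' Convenience wrapper around [simulate_experiment()] for one bouton.
#'
#' @inheritParams simulate_experiment
#' @param bouton_id Identifier used in the output tables.
#' @return A list with `trace` and `truth` tibbles.
#' @export
simulate_single_trace <- function(config, bouton_id = "b0001") {
  config <- validate_sim_config(unclass(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_one_bouton(config, bouton_id)
}

#' Simulate negative-control boutons (no fusion)
#'
#' Identical pipeline to [simulate_experiment()] with fusion disabled
#' (`p_release` forced to 0): traces contain only background, photobleaching
#' drift and Gaussian noise, while the stimulus timestamps are retained so
#' detection can be scored per stimulus. This emulates imaging in TTX /
#' zero-calcium conditions and is the substrate of the false-positive bound.
#'
#' @inheritParams simulate_experiment
#' @return An `sv_dataset`; its `truth` table has no fused events.
#' @export
simulate_negative_control <- function(config, n_boutons) {
  config <- unclass(config)
  config$p_release <- 0
  simulate_experiment(validate_sim_config(config), n_boutons)
}

#' Simulate a 40 Hz train response
#'
#' Builds a bulk-stimulation trace: fluorescence rises approximately linearly
#' during the train (slope = train rate x release probability x quantal
#' amplitude), then decays mono-exponentially back to baseline with the
#' endocytosis time constant `endo_tau_s`. Photobleaching drift and Gaussian
#' noise are added as configured.
#'
#' @param config A [sim_config()]; `p_release`, `quantal_amplitude`,
#'   bleaching, background and noise are used.
#' @param train_rate_hz Stimulation frequency during the train.
#' @param train_duration_s Train length in seconds.
#' @param endo_tau_s Decay time constant (s) of the post-train return.
#' @param train_start_s Train onset time (s).
#' @param bouton_id Identifier for the output trace.
#'
#' @return A tibble trace (`time_s`, `bouton_id`, `intensity`) with the true
#'   rise slope, amplitude and decay constant in attribute `"train_truth"`.
#' @export
simulate_train_trace <- function(config, train_rate_hz = 40,
                                 train_duration_s = 5, endo_tau_s = 10,
                                 train_start_s = 10, bouton_id = "train") {
  config <- validate_sim_config(unclass(config))
  if (endo_tau_s <= 0) abort("endo_tau_s must be positive")
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  t_end <- train_start_s + train_duration_s
  if (t_end >= config$duration_s) abort("train must end within the trace")
  slope <- train_rate_hz * config$p_release * config$quantal_amplitude
  resp <- numeric(n)
  during <- t >= train_start_s & t < t_end
  resp[during] <- slope * (t[during] - train_start_s)
  after <- t >= t_end
  amp <- slope * train_duration_s
  resp[after] <- amp * exp(-(t[after] - t_end) / endo_tau_s)
  y <- config$background_level +
    config$bleach_amplitude * exp(-t / config$bleach_tau_s) + resp
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$noise_sd > 0) y <- y + rnorm(n, 0, config$noise_sd)
  out <- tibble(time_s = t, bouton_id = bouton_id, intensity = y)
  attr(out, "train_truth") <- list(
    rise_slope = slope, amplitude = amp, endo_tau_s = endo_tau_s,
    train_start_s = train_start_s, train_end_s = t_end
  )
  out
}

#' Simulate an acid-quench / NH4Cl pool-assay trace
#'
#' Three-epoch trace for the surface/internal pool assay: resting Tyrode
#' fluorescence, acid quench of the surface pool (pH ~5.5), and NH4Cl
#' alkalinisation revealing the total pool. Solution switches are smoothed
#' with a short exponential transition to emulate perfusion mixing.
#'
#' @param surface_fraction Fraction of probe on the plasma membrane.
#' @param total_fluorescence Total (surface + internal) probe fluorescence in
#'   NH4Cl units (a.u.).
#' @param epoch_duration_s Length of each epoch (s).
#' @param transition_tau_s Time constant of the solution-switch transient.
#' @param background_level,noise_sd,sampling_rate_hz,seed As in [sim_config()].
#'
#' @return A list with `trace` (tibble) and `epochs` (tibble of `label`,
#'   `start_s`, `end_s` with labels `rest`, `acid`, `nh4`).
#' @export
simulate_pool_trace <- function(surface_fraction = 0.6,
                                total_fluorescence = 100,
                                epoch_duration_s = 30,
                                transition_tau_s = 0.5,
                                background_level = 20,
                                noise_sd = 1,
                                sampling_rate_hz = 10,
                                seed = NULL) {
  if (surface_fraction < 0 || surface_fraction > 1) {
    abort("surface_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate_hz
  dur <- 3 * epoch_duration_s
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  # pHluorin visible: surface pool at rest, nothing in acid, everything in NH4Cl
  f_rest <- background_level + surface_fraction * total_fluorescence
  f_acid <- background_level
  f_nh4 <- background_level + total_fluorescence
  lv <- c(f_rest, f_acid, f_nh4)
  epoch <- pmin(floor(t / epoch_duration_s) + 1, 3)
  y <- lv[epoch]
  # exponential relaxation at each switch
  for (k in 2:3) {
    sw <- (k - 1) * epoch_duration_s
    seg <- t >= sw
    y[seg] <- lv[k] + (lv[k - 1] - lv[k]) * exp(-(t[seg] - sw) / transition_tau_s)
  }
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  list(
    trace = tibble(time_s = t, bouton_id = "pool", intensity = y),
    epochs = tibble(
      label = c("rest", "acid", "nh4"),
      start_s = c(0, epoch_duration_s, 2 * epoch_duration_s),
      end_s = c(epoch_duration_s, 2 * epoch_duration_s, dur)
    )
  )
}
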