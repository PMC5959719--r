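#' Simulation configuration for synthetic bouton traces
#'
#' Collects the generative parameters of the synthetic single-vesicle
#' experiment: the stimulation protocol, quantal fluorescence amplitudes,
#' the kinetic composition of retrieval (ultrafast / fast / ultraslow),
#' re-acidification, the retrieval-endpoint mixture, photobleaching drift
#' and Gaussian noise. Defaults emulate sparse 0.05 Hz single-AP stimulation
#' imaged at 10 Hz, with release probability 0.15, an ultrafast component of
#' ~200 ms, a fast component of ~8 s, and 40% of events never retrieved
#' within the 20 s observation window.
#'
#' @param sampling_rate_hz Frames per second (10 or 40 are typical).
#' @param duration_s Total trace duration in seconds.
#' @param stimulus_times_s Strictly increasing stimulus times (s), all within
#'   the trace.
#' @param p_release Probability that a stimulus triggers a fusion event.
#' @param quantal_amplitude Mean fluorescence step of a single vesicle (a.u.).
#' @param quantal_cv Coefficient of variation of the single-quantum amplitude.
#' @param multivesicular_prob Probability that a fusion event releases two
#'   quanta (such events exceed the quantal upper limit and are excluded from
#'   kinetic analysis downstream).
#' @param mode_weights Named or unnamed length-3 nonnegative weights
#'   (ultrafast, fast, ultraslow) summing to 1. Dwell times are drawn from
#'   exponential distributions truncated to the class band (0--1 s for
#'   ultrafast, 1--20 s for fast), so these weights are exactly the true mode
#'   proportions; ultraslow events never decay within the trace.
#' @param tau_ultrafast_s,tau_fast_s Exponential time constants (s) of the
#'   ultrafast and fast dwell-time components.
#' @param ultraslow_boundary_s Dwell band boundaries used by the generator:
#'   events beyond this limit are modelled as non-retrieving (censored).
#' @param tau_reacidification_s Single-exponential re-acidification time
#'   constant (s) governing the fluorescence decay after the dwell.
#' @param retrieval_fraction_dist List describing the mixture of retrieval
#'   endpoints: `prob` (named probabilities for partial / quantal / excess),
#'   class location/scale parameters, and `dwell_dispersion_per_s`, the extra
#'   endpoint SD added per second of dwell (emulating the increase of
#'   retrieval dispersion with dwell time).
#' @param bleach_tau_s,bleach_amplitude Additive single-exponential
#'   photobleaching drift: `bleach_amplitude * exp(-t / bleach_tau_s)`.
#' @param background_level Constant background fluorescence (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.). The default
#'   signal-to-noise ratio (quantal amplitude five times the noise SD)
#'   is a free, configurable choice.
#' @param seed Integer seed; `simulate_*` functions set it before drawing.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(noise_sd = 0, p_release = 1)
#' cfg$p_release
sim_config <- function(sampling_rate_hz = 10,
                       duration_s = 420,
                       stimulus_times_s = seq(10, by = 20, length.out = 20),
                       p_release = 0.15,
                       quantal_amplitude = 5,
                       quantal_cv = 0.15,
                       multivesicular_prob = 0.1,
                       mode_weights = c(ultrafast = 0.2, fast = 0.4, ultraslow = 0.4),
                       tau_ultrafast_s = 0.2,
                       tau_fast_s = 8,
                       ultraslow_boundary_s = 20,
                       tau_reacidification_s = 4,
                       retrieval_fraction_dist = list(
                         prob = c(partial = 0.35, quantal = 0.5, excess = 0.15),
                         partial_mean = 0.55, partial_sd = 0.15,
                         quantal_sd = 0.08,
                         excess_mean = 1.35, excess_sd = 0.12,
                         dwell_dispersion_per_s = 0.02
                       ),
                       bleach_tau_s = 100,
                       bleach_amplitude = 10,
                       background_level = 20,
                       noise_sd = 1,
                       seed = NULL) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    stimulus_times_s = stimulus_times_s, p_release = p_release,
    quantal_amplitude = quantal_amplitude, quantal_cv = quantal_cv,
    multivesicular_prob = multivesicular_prob,
    mode_weights = mode_weights,
    tau_ultrafast_s = tau_ultrafast_s, tau_fast_s = tau_fast_s,
    ultraslow_boundary_s = ultraslow_boundary_s,
    tau_reacidification_s = tau_reacidification_s,
    retrieval_fraction_dist = retrieval_fraction_dist,
    bleach_tau_s = bleach_tau_s, bleach_amplitude = bleach_amplitude,
    background_level = background_level, noise_sd = noise_sd, seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
      abort("sampling_rate_hz must be positive")
    }
    if (duration_s <= 0) abort("duration_s must be positive")
    if (length(stimulus_times_s) > 0) {
      if (any(diff(stimulus_times_s) <= 0)) {
        abort("stimulus_times_s must be strictly increasing")
      }
      if (min(stimulus_times_s) < 0 || max(stimulus_times_s) >= duration_s) {
        abort("stimulus_times_s must lie within [0, duration_s)")
      }
    }
    if (p_release < 0 || p_release > 1) abort("p_release must be in [0, 1]")
    if (quantal_amplitude < 0) abort("quantal_amplitude must be nonnegative")
    if (quantal_cv < 0) abort("quantal_cv must be nonnegative")
    if (multivesicular_prob < 0 || multivesicular_prob > 1) {
      abort("multivesicular_prob must be in [0, 1]")
    }
    if (length(mode_weights) != 3 || any(mode_weights < 0) ||
        abs(sum(mode_weights) - 1) > 1e-8) {
      abort("mode_weights must be 3 nonnegative values summing to 1")
    }
    taus <- c(tau_ultrafast_s, tau_fast_s, tau_reacidification_s, bleach_tau_s)
    if (any(taus <= 0)) abort("all time constants must be positive")
    if (noise_sd < 0) abort("noise_sd must be nonnegative")
    if (ultraslow_boundary_s <= 1) abort("ultraslow_boundary_s must exceed 1 s")
  })
  mw <- cfg$mode_weights
  names(mw) <- c("ultrafast", "fast", "ultraslow")
  cfg$mode_weights <- mw
  structure(cfg, class = "sim_config")
}

#' Chung-Kennedy filter configuration
#'
#' Window lengths of the forward/backward moving-average predictor bank, the
#' length of the running prediction-error comparison window, the weighting
#' exponent, the regulariser that keeps weights defined on noiseless data,
#' and optional per-predictor prior weights.
#'
#' @param predictor_windows Strictly increasing positive integer window
#'   lengths (samples) of the moving-average predictors.
#' @param comparison_window_M Number of most recent one-sided residuals summed
#'   into each predictor's error.
#' @param weighting_exponent_p Positive exponent: weights are proportional to
#'   `(error + epsilon)^(-p)`.
#' @param regularizer_epsilon Small positive constant guarding against zero
#'   prediction error; it vanishes in the noisy regime.
#' @param prior_weights Nonnegative prior weight per predictor window
#'   (recycled to forward and backward sides); default all 1.
#'
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(predictor_windows = c(2L, 4L, 8L, 16L),
                           comparison_window_M = 8L,
                           weighting_exponent_p = 2,
                           regularizer_epsilon = 1e-12,
                           prior_weights = NULL) {
  if (any(predictor_windows < 1) || any(diff(predictor_windows) <= 0)) {
    abort("predictor_windows must be strictly increasing positive integers")
  }
  if (comparison_window_M < 1) abort("comparison_window_M must be >= 1")
  if (weighting_exponent_p <= 0) abort("weighting_exponent_p must be positive")
  if (regularizer_epsilon <= 0) abort("regularizer_epsilon must be positive")
  if (is.null(prior_weights)) prior_weights <- rep(1, length(predictor_windows))
  if (length(prior_weights) != length(predictor_windows) || any(prior_weights < 0)) {
    abort("prior_weights must be nonnegative, one per predictor window")
  }
  structure(
    list(
      predictor_windows = as.integer(predictor_windows),
      comparison_window_M = as.integer(comparison_window_M),
      weighting_exponent_p = weighting_exponent_p,
      regularizer_epsilon = regularizer_epsilon,
      prior_weights = prior_weights
    ),
    class = "denoise_config"
  )
}

#' Event detection configuration
#'
#' Parameters of stimulus-locked fusion event detection: baseline statistics
#' window, the 3x-SD amplitude threshold, the stimulus coincidence window,
#' the censoring limit defining ultraslow retrieval, the dwell-time band
#' boundaries of the three kinetic modes, the fraction-of-retrieval class
#' bounds, and the noise guard on decay-onset calls.
#'
#' @param baseline_window_s Length (s) of the pre-stimulus baseline window.
#' @param threshold_sd_multiple Detection threshold in baseline SD units.
#' @param coincidence_window_frames Frames after the stimulus within which the
#'   threshold crossing must occur.
#' @param censor_limit_s Dwell times beyond this limit are censored
#'   (ultraslow retrieval).
#' @param mode_boundaries_s Dwell boundaries (s) separating ultrafast / fast /
#'   ultraslow retrieval.
#' @param retrieval_class_bounds Fraction-of-retrieval bounds separating
#'   partial / quantal / excess retrieval.
#' @param decay_onset_persistence_frames Consecutive frames of negative first
#'   derivative required to call a decay onset.
#' @param decay_confirm_near_factor Fraction of the confirmation guard the
#'   near window (the first `decay_confirm_s` after a candidate) must drop
#'   by, tying the onset call to the start of the decline.
#' @param decay_confirm_s Time scale (s) of decay-onset confirmation: a
#'   candidate onset is checked against the mean of the de-noised trace over
#'   `[1, 3] * decay_confirm_s` after it. Prevents smoothed noise wiggles on
#'   long plateaus from being mistaken for re-acidification.
#' @param decay_confirm_sd_multiple Minimum confirmed drop below the running
#'   plateau mean, in units of the raw baseline SD, for a candidate decay
#'   onset to be accepted. The confirmation averages the de-noised trace over
#'   `[1, 3] * decay_confirm_s` after the candidate, where window means of
#'   filtered noise fluctuate by ~0.1 raw-SD while even a partially retrieved
#'   event has dropped by well over one raw-SD; the guard vanishes on
#'   noiseless data. Calibrated, like the filter parameters, on simulated
#'   traces with known ground truth.
#' @param min_decay_step_frac Smallest per-frame decline, as a fraction of
#'   the event amplitude, that counts towards a decay onset. A numerical
#'   guard against the microscopic plateau declines the nonlinear filter can
#'   produce on noiseless data; far below any genuine re-acidification step.
#' @param baseline_sd_on Trace used for the baseline SD entering the
#'   detection threshold: `"raw"` (the corrected, un-denoised trace; default)
#'   or `"denoised"`. The short baseline window holds few, strongly
#'   autocorrelated de-noised samples, so the raw-trace SD is the better
#'   calibrated choice.
#'
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(baseline_window_s = 2,
                          threshold_sd_multiple = 3,
                          coincidence_window_frames = 3L,
                          censor_limit_s = 20,
                          mode_boundaries_s = c(1, 20),
                          retrieval_class_bounds = c(0.8, 1.2),
                          decay_onset_persistence_frames = 2L,
                          decay_confirm_s = 1,
                          decay_confirm_sd_multiple = 0.8,
                          decay_confirm_near_factor = 0.6,
                          min_decay_step_frac = 1e-3,
                          baseline_sd_on = c("raw", "denoised")) {
  baseline_sd_on <- match.arg(baseline_sd_on)
  vals <- c(baseline_window_s, threshold_sd_multiple, coincidence_window_frames,
            censor_limit_s, mode_boundaries_s, decay_onset_persistence_frames,
            decay_confirm_s)
  if (any(vals <= 0)) abort("all detection parameters must be positive")
  if (diff(mode_boundaries_s) <= 0) abort("mode_boundaries_s must be increasing")
  b <- retrieval_class_bounds
  if (!(b[1] > 0 && b[1] < 1 && b[2] > 1)) {
    abort("retrieval_class_bounds must satisfy 0 < lower < 1 < upper")
  }
  structure(
    list(
      baseline_window_s = baseline_window_s,
      threshold_sd_multiple = threshold_sd_multiple,
      coincidence_window_frames = as.integer(coincidence_window_frames),
      censor_limit_s = censor_limit_s,
      mode_boundaries_s = mode_boundaries_s,
      retrieval_class_bounds = retrieval_class_bounds,
      decay_onset_persistence_frames = as.integer(decay_onset_persistence_frames),
      decay_confirm_s = decay_confirm_s,
      decay_confirm_sd_multiple = decay_confirm_sd_multiple,
      decay_confirm_near_factor = decay_confirm_near_factor,
      min_decay_step_frac = min_decay_step_frac,
      baseline_sd_on = baseline_sd_on
    ),
    class = "detect_config"
  )
}
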