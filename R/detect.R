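# Stimulus-locked detection of single-vesicle fusion events on de-noised
# traces: threshold crossing against pre-stimulus baseline statistics,
# quantal upper limit against multivesicular events, dwell-time measurement
# with censoring, fraction of retrieval, and kinetic mode classification.

#' Estimate single-quantum amplitude and the multivesicular upper limit
#'
#' Fits a two-component Gaussian location mixture to the event amplitude
#' distribution. The first mode is the single-quantum amplitude q1, the
#' second the two-quantum peak q2; the upper limit used to exclude
#' multivesicular events is `q1 + 0.5 * (q2 - q1)`. If the distribution is
#' effectively unimodal (one-component model preferred, or modes closer than
#' 25%), the limit falls back to `1.5 * q1` with a warning.
#'
#' @param amplitudes Numeric vector of detected event amplitudes (>= 50).
#' @return A one-row tibble: `mean_single_quantum`, `mean_second_peak`,
#'   `upper_limit`, `n_components`, `unimodal_fallback`.
#' @export
#' @examples
#' set.seed(1)
#' a <- c(rnorm(180, 1, 0.15), rnorm(20, 2, 0.2))
#' estimate_quantal_bounds(a)
estimate_quantal_bounds <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 50) {
    abort("need at least 50 amplitudes to estimate quantal bounds")
  }
  fit <- tryCatch(
    mclust::Mclust(amplitudes, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL
  )
  fallback <- TRUE
  q1 <- mean(amplitudes)
  q2 <- NA_real_
  g <- 1L
  if (!is.null(fit) && fit$G == 2) {
    m <- unname(sort(fit$parameters$mean))
    if (m[2] / m[1] > 1.25) {
      q1 <- m[1]
      q2 <- m[2]
      g <- 2L
      fallback <- FALSE
    }
  }
  if (fallback) {
    warn("amplitude distribution looks unimodal; upper limit set to 1.5 * q1")
    upper <- 1.5 * q1
  } else {
    upper <- q1 + 0.5 * (q2 - q1)
  }
  tibble(
    mean_single_quantum = q1, mean_second_peak = q2, upper_limit = upper,
    n_components = g, unimodal_fallback = fallback
  )
}

# decay onset on a de-noised segment. Candidates are runs of >= persistence
# consecutive negative first differences after the peak (each step larger
# than a small fraction of the event amplitude, so microscopic declines of
# the filtered plateau do not qualify). A candidate is accepted when the
# decline both starts at it (near window) and is sustained (far window),
# each judged against the running plateau median with an SD-scaled guard.
# Returns the sample index of the last plateau sample, or NA (censored).
find_decay_onset <- function(y, peak_idx, end_idx, fs, config, sd_confirm, amplitude) {
  if (end_idx <= peak_idx + 1) return(NA_integer_)
  seg <- y[peak_idx:end_idx]
  len <- length(seg)
  d <- diff(seg)
  floor_step <- config$min_decay_step_frac * max(amplitude, 0)
  neg <- d < -floor_step
  pers <- config$decay_onset_persistence_frames
  if (length(neg) < pers) return(NA_integer_)
  # run starts: positions where `pers` consecutive qualifying diffs begin
  runs <- neg
  if (pers > 1) {
    for (j in seq_len(pers - 1)) {
      runs <- runs & c(neg[-seq_len(j)], rep(FALSE, j))
    }
  }
  starts <- which(runs)
  if (length(starts) == 0) return(NA_integer_)
  cw <- max(1L, round(config$decay_confirm_s * fs))
  guard <- config$decay_confirm_sd_multiple * sd_confirm
  for (s in starts) {
    dwell_s <- (s - 1L) / fs
    if (dwell_s > config$censor_limit_s) return(NA_integer_) # censored
    n_lo <- min(s + max(1L, cw %/% 4L), len)
    n_hi <- min(s + cw, len)
    w_lo <- min(s + cw, len)
    w_hi <- min(s + 3L * cw, len)
    if (w_hi <= w_lo || n_hi <= n_lo) next # no room to confirm
    # plateau reference: running median from the peak over at least 3
    # samples, robust to the noise-selected peak sample itself
    ref_n <- max(s, min(3L, len))
    ref <- stats::median(seg[1:ref_n])
    # the decline must have started at the candidate (near window) and be
    # sustained (far window); a far drop alone would back-date onsets of
    # slow decays into the plateau
    if (mean(seg[n_lo:n_hi]) < ref - config$decay_confirm_near_factor * guard &&
        mean(seg[w_lo:w_hi]) < ref - guard) {
      return(peak_idx + s - 1L)
    }
  }
  NA_integer_
}

detect_one_bouton <- function(tb, yraw, stim, config, upper_limit) {
  y <- tb$intensity
  t <- tb$time_s
  n <- length(y)
  fs <- infer_sampling_rate(t)
  nb <- round(config$baseline_window_s * fs)
  cw <- config$coincidence_window_frames
  rows <- vector("list", length(stim))
  for (k in seq_along(stim)) {
    ts <- stim[k]
    i0 <- which(t >= ts)[1]
    base <- tibble(
      bouton_id = tb$bouton_id[1], stimulus_index = k, stimulus_time_s = ts,
      status = "failure", detected = FALSE, onset_time_s = NA_real_,
      peak_time_s = NA_real_, amplitude = NA_real_,
      baseline_mean = NA_real_, baseline_sd = NA_real_,
      multivesicular = FALSE, dwell_s = NA_real_, censored = NA,
      censored_at_edge = FALSE, decay_onset_time_s = NA_real_,
      retrieval_fraction = NA_real_, retrieval_class = NA_character_,
      mode = NA_character_
    )
    if (is.na(i0) || i0 - nb < 1) {
      base$status <- "skipped" # no room for a full baseline window
      rows[[k]] <- base
      next
    }
    bidx <- (i0 - nb):(i0 - 1)
    bmean <- mean(y[bidx])
    bsd_raw <- sd(yraw[bidx])
    bsd <- if (config$baseline_sd_on == "raw") bsd_raw else sd(y[bidx])
    base$baseline_mean <- bmean
    base$baseline_sd <- bsd
    thr <- bmean + config$threshold_sd_multiple * bsd
    win <- i0:min(i0 + cw - 1L, n)
    # event time must coincide with the stimulus: the fluorescence step must
    # clear the threshold within the coincidence window. The raw trace shows
    # the step without the 1-3 frame rise smear the nonlinear filter adds,
    # so the crossing may register on either trace.
    cross <- win[which(y[win] > thr | yraw[win] > thr)[1]]
    if (is.na(cross)) {
      rows[[k]] <- base
      next
    }
    # peak attainment: first sample of the rise window reaching the window
    # maximum (within tolerance: the filter smears the one-frame step over a
    # few frames, and an exactly flat plateau carries sub-nanoscale wiggles
    # from the predictor weighting)
    jmax <- min(n, i0 + cw - 1L + max(2L, round(0.3 * fs)))
    rise <- y[cross:jmax]
    tol <- max(0.25 * sd(y[bidx]), 1e-8 * abs(max(rise)))
    peak_idx <- cross - 1L + which(rise >= max(rise) - tol)[1]
    peak_val <- y[peak_idx]
    amp <- peak_val - bmean
    # the event peak amplitude itself must exceed the detection threshold
    if (amp <= config$threshold_sd_multiple * bsd) {
      rows[[k]] <- base
      next
    }
    base$status <- "detected"
    base$detected <- TRUE
    base$onset_time_s <- t[cross]
    base$peak_time_s <- t[peak_idx]
    base$amplitude <- amp
    base$multivesicular <- amp > upper_limit
    if (base$multivesicular) {
      # excluded from kinetic analysis; still a release for failure analysis
      base$status <- "multivesicular"
      rows[[k]] <- base
      next
    }
    # search for the decay onset up to the next stimulus (or trace end)
    end_idx <- if (k < length(stim)) {
      nxt <- which(t >= stim[k + 1])[1]
      if (is.na(nxt)) n else nxt - 1L
    } else n
    onset <- find_decay_onset(y, peak_idx, end_idx, fs, config, bsd_raw, amp)
    if (is.na(onset)) {
      base$censored <- TRUE
      base$mode <- "ultraslow"
      # the observation window may simply have ended too early
      base$censored_at_edge <- (end_idx - peak_idx) / fs < config$censor_limit_s
    } else {
      base$censored <- FALSE
      base$dwell_s <- t[onset] - t[peak_idx]
      base$decay_onset_time_s <- t[onset]
      base$mode <- classify_mode(base$dwell_s, FALSE, config)
      # endpoint: mean over the final settled second of the interval
      eidx <- max(onset + 1L, end_idx - round(fs) + 1L):end_idx
      endpoint <- mean(y[eidx])
      frac <- (peak_val - endpoint) / (peak_val - bmean)
      base$retrieval_fraction <- frac
      b <- config$retrieval_class_bounds
      base$retrieval_class <- if (frac < b[1]) "partial" else if (frac > b[2]) "excess" else "quantal"
    }
    rows[[k]] <- base
  }
  bind_rows(rows)
}

#' Detect stimulus-locked single-vesicle fusion events
#'
#' For each stimulus, an event is called iff the de-noised trace rises above
#' `baseline mean + threshold_sd_multiple * baseline SD` within the
#' coincidence window after the stimulus (baseline statistics from the
#' window of `baseline_window_s` before the stimulus). Detected events whose
#' amplitude exceeds the quantal `upper_limit` are flagged multivesicular and
#' excluded from kinetic measurements. For the remaining events the dwell
#' time (time at peak amplitude until the first persistent negative
#' derivative of the de-noised trace), censoring beyond `censor_limit_s`,
#' the fraction of retrieval relative to the fusion amplitude, its class
#' (partial / quantal / excess) and the kinetic mode (ultrafast / fast /
#' ultraslow) are measured. Stimuli without a full baseline window are
#' skipped and flagged.
#'
#' @param denoised De-noised, bleach/background-corrected trace tibble.
#' @param stimulus_times_s Stimulus times (s).
#' @param config A [detect_config()].
#' @param upper_limit Quantal upper amplitude limit (a.u.); `Inf` disables
#'   multivesicular exclusion (e.g. for the first pass feeding
#'   [estimate_quantal_bounds()]).
#' @param raw Corrected but not de-noised trace tibble, required when
#'   `config$baseline_sd_on == "raw"` (the default).
#'
#' @return A tibble with one row per stimulus per bouton (failures included):
#'   identifiers, detection status, baseline statistics, amplitude,
#'   multivesicular flag, dwell time or censoring, retrieval fraction/class
#'   and mode.
#' @export
detect_events <- function(denoised, stimulus_times_s, config = detect_config(),
                          upper_limit = Inf, raw = NULL) {
  check_trace_df(denoised, "denoised")
  if (length(stimulus_times_s) == 0) abort("no stimulus times supplied")
  if (config$baseline_sd_on == "raw") {
    if (is.null(raw)) {
      abort(paste("baseline_sd_on = \"raw\" needs the corrected raw trace;",
                  "pass `raw` or use detect_config(baseline_sd_on = \"denoised\")"))
    }
    check_trace_df(raw, "raw")
  }
  parts <- denoised |> group_by(.data$bouton_id) |> dplyr::group_split()
  map_dfr(parts, function(tb) {
    yraw <- if (is.null(raw)) tb$intensity else {
      raw$intensity[raw$bouton_id == tb$bouton_id[1]]
    }
    if (length(yraw) != nrow(tb)) {
      abort("`raw` and `denoised` traces are not aligned")
    }
    detect_one_bouton(tb, yraw, stimulus_times_s, config, upper_limit)
  })
}

#' Classify the kinetic mode of retrieval
#'
#' Dwell times up to the first mode boundary (1 s) are ultrafast, up to the
#' censoring limit (20 s) fast; censored events are ultraslow.
#'
#' @param dwell_s Numeric dwell times (s); `NA` for censored events.
#' @param censored Logical, recycled.
#' @param config A [detect_config()] providing `mode_boundaries_s`.
#' @return Character vector of `"ultrafast"`, `"fast"`, `"ultraslow"`.
#' @export
classify_mode <- function(dwell_s, censored = is.na(dwell_s),
                          config = detect_config()) {
  b <- config$mode_boundaries_s
  out <- ifelse(censored, "ultraslow",
                ifelse(dwell_s <= b[1], "ultrafast", "fast"))
  as.character(out)
}

#' Release probability by failure analysis
#'
#' Per bouton, the release probability estimate is the number of detected
#' events (multivesicular releases included) divided by the number of
#' scoreable stimuli. Skipped stimuli are excluded from the denominator.
#'
#' @param events Event table from [detect_events()].
#' @return An object of class `release_probability`: a per-bouton tibble
#'   (`bouton_id`, `n_events`, `n_stimuli`, `p_release`) with the
#'   mean +/- SEM summary available via [glance()].
#' @export
release_probability <- function(events) {
  per <- events |>
    filter(.data$status != "skipped") |>
    group_by(.data$bouton_id) |>
    summarise(
      n_events = sum(.data$detected),
      n_stimuli = n(),
      p_release = .data$n_events / .data$n_stimuli,
      .groups = "drop"
    )
  structure(per, class = c("release_probability", class(per)))
}

#' @method glance release_probability
#' @export
glance.release_probability <- function(x, ...) {
  tibble(
    mean_p = mean(x$p_release),
    sem_p = sd(x$p_release) / sqrt(nrow(x)),
    n_boutons = nrow(x),
    n_stimuli = sum(x$n_stimuli),
    n_events = sum(x$n_events)
  )
}

#' @method tidy release_probability
#' @export
tidy.release_probability <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
print.release_probability <- function(x, ...) {
  g <- glance.release_probability(x)
  cat(sprintf(
    "Release probability (failure analysis): %.3f +/- %.3f (mean +/- SEM, %d boutons, %d stimuli)\n",
    g$mean_p, g$sem_p, g$n_boutons, g$n_stimuli
  ))
  print(as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Measure the dwell time of a detected event on a de-noised trace
#'
#' Vector-level access to the dwell estimator used by [detect_events()]:
#' time from peak attainment to the first persistent negative first
#' derivative of the de-noised trace, with censoring beyond the limit.
#'
#' @param y De-noised intensity vector.
#' @param t Time stamps (s), same length as `y`.
#' @param peak_index Sample index of peak attainment.
#' @param baseline_mean Pre-event baseline level (sets the event amplitude
#'   entering the minimal-decay-step guard).
#' @param baseline_sd Baseline SD of the corrected raw trace (sets the
#'   decay-confirmation scale; 0 for noiseless data).
#' @param config A [detect_config()].
#' @param end_index Last sample of the search interval (default: trace end).
#' @return A one-row tibble: `dwell_s`, `censored`, `decay_onset_time_s`.
#' @export
measure_dwell <- function(y, t, peak_index, baseline_mean = y[1],
                          baseline_sd = 0, config = detect_config(),
                          end_index = length(y)) {
  fs <- infer_sampling_rate(t)
  onset <- find_decay_onset(y, peak_index, end_index, fs, config,
                            baseline_sd, y[peak_index] - baseline_mean)
  if (is.na(onset)) {
    tibble(dwell_s = NA_real_, censored = TRUE, decay_onset_time_s = NA_real_)
  } else {
    tibble(dwell_s = t[onset] - t[peak_index], censored = FALSE,
           decay_onset_time_s = t[onset])
  }
}

#' Fraction of retrieval of a decaying event
#'
#' `(peak - endpoint) / (peak - baseline)`, with the endpoint averaged over
#' the final settled second of the inter-stimulus interval. 1 means the
#' fluorescence returned exactly to baseline (quantal retrieval).
#'
#' @inheritParams measure_dwell
#' @param baseline_mean Pre-stimulus baseline mean of the de-noised trace.
#' @param config A [detect_config()] providing the class bounds.
#' @return A one-row tibble: `retrieval_fraction`, `retrieval_class`.
#' @export
fraction_of_retrieval <- function(y, t, peak_index, baseline_mean,
                                  config = detect_config(),
                                  end_index = length(y)) {
  fs <- infer_sampling_rate(t)
  eidx <- max(peak_index + 1L, end_index - round(fs) + 1L):end_index
  frac <- (y[peak_index] - mean(y[eidx])) / (y[peak_index] - baseline_mean)
  b <- config$retrieval_class_bounds
  cls <- if (frac < b[1]) "partial" else if (frac > b[2]) "excess" else "quantal"
  tibble(retrieval_fraction = frac, retrieval_class = cls)
}
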