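# End-to-end orchestration: simulate (or load) -> photobleaching correction
# -> Chung-Kennedy de-noising -> event detection with quantal bounds ->
# dwell-time kinetics and summaries.

#' Run the full single-vesicle analysis pipeline
#'
#' Orchestrates the standard analysis on a dataset: photobleaching
#' correction (per-ROI single-exponential fit), Chung-Kennedy de-noising,
#' two-pass event detection (a first pass without an amplitude ceiling feeds
#' the quantal-bound estimate, the second applies the multivesicular upper
#' limit), then release probability, mode proportions, retrieval versus
#' dwell, and single/double exponential dwell-distribution fits with model
#' comparison. Deterministic given the simulation seed.
#'
#' @param data An `sv_dataset` from [simulate_experiment()], or a list with
#'   elements `traces` (trace tibble) and `stimulus_times_s`.
#' @param detect_cfg A [detect_config()].
#' @param denoise_cfg A [denoise_config()].
#' @param min_events_for_fit Minimum uncensored dwells for the distribution
#'   fits (fits are skipped below it).
#' @param out_dir Optional directory; when given, corrected traces, the
#'   event table and a JSON summary report are written there.
#'
#' @return A list of class `sv_results`: `events`, `release`,
#'   `mode_proportions`, `retrieval_vs_dwell`, `quantal_bounds`,
#'   `dwell_fit_single`, `dwell_fit_double`, `model_comparison`,
#'   `traces_corrected`, `traces_denoised`, and `provenance`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(duration_s = 120, stimulus_times_s = seq(10, 110, 20),
#'                   p_release = 0.5, seed = 7)
#' res <- run_pipeline(simulate_experiment(cfg, 30))
#' res$mode_proportions
#' }
run_pipeline <- function(data,
                         detect_cfg = detect_config(),
                         denoise_cfg = denoise_config(),
                         min_events_for_fit = 30,
                         out_dir = NULL) {
  if (!is.list(data) || is.null(data$traces) || is.null(data$stimulus_times_s)) {
    abort("`data` must contain `traces` and `stimulus_times_s`")
  }
  traces <- data$traces
  stim <- data$stimulus_times_s
  corrected <- correct_photobleaching(traces, stimulus_times_s = stim)
  denoised <- ck_filter(corrected, denoise_cfg)
  # pass 1: no amplitude ceiling, to collect the amplitude distribution
  ev1 <- detect_events(denoised, stim, detect_cfg, upper_limit = Inf,
                       raw = corrected)
  amps <- ev1$amplitude[ev1$detected]
  qb <- if (sum(is.finite(amps)) >= 50) {
    suppressWarnings(estimate_quantal_bounds(amps))
  } else {
    tibble(mean_single_quantum = NA_real_, mean_second_peak = NA_real_,
           upper_limit = Inf, n_components = NA_integer_,
           unimodal_fallback = NA)
  }
  events <- detect_events(denoised, stim, detect_cfg,
                          upper_limit = qb$upper_limit, raw = corrected)
  release <- release_probability(events)
  kept <- events |> filter(.data$detected, !.data$multivesicular)
  modes <- if (nrow(kept) > 0) mode_proportions(kept) else NULL
  rvd <- if (any(!is.na(kept$retrieval_fraction))) retrieval_vs_dwell(kept) else NULL
  dwells <- kept$dwell_s[!is.na(kept$dwell_s)]
  n_cens <- sum(kept$censored, na.rm = TRUE)
  if (length(dwells) >= min_events_for_fit) {
    fit_s <- fit_dwell_distribution(dwells, "single", n_censored = n_cens)
    fit_d <- tryCatch(
      suppressWarnings(fit_dwell_distribution(dwells, "double",
                                              n_censored = n_cens)),
      error = function(e) NULL
    )
    cmp <- if (!is.null(fit_d)) compare_models(fit_s, fit_d) else NULL
  } else {
    fit_s <- NULL
    fit_d <- NULL
    cmp <- NULL
  }
  res <- structure(
    list(
      events = events, release = release, mode_proportions = modes,
      retrieval_vs_dwell = rvd, quantal_bounds = qb,
      dwell_fit_single = fit_s, dwell_fit_double = fit_d,
      model_comparison = cmp,
      traces_corrected = corrected, traces_denoised = denoised,
      provenance = list(
        seed = if (!is.null(data$config)) data$config$seed else NULL,
        n_boutons = length(unique(traces$bouton_id)),
        n_stimuli = length(stim),
        sampling_rate_hz = infer_sampling_rate(traces$time_s),
        package_version = as.character(utils::packageVersion("vesitrace")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "sv_results"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_traces(corrected, file.path(out_dir, "traces_corrected.tsv"))
    write_events(events, file.path(out_dir, "events.csv"))
    report <- list(
      provenance = res$provenance,
      release_probability = as.list(glance(release)),
      mode_proportions = modes,
      quantal_bounds = as.list(qb),
      dwell_fit_double = if (!is.null(fit_d)) as.list(glance(fit_d)) else NULL,
      model_comparison = if (!is.null(cmp)) as.list(cmp) else NULL
    )
    write_report(report, file.path(out_dir, "report.json"))
  }
  res
}

#' @export
print.sv_results <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Single-vesicle analysis: %d boutons x %d stimuli at %g Hz\n",
              p$n_boutons, p$n_stimuli, p$sampling_rate_hz))
  g <- glance(x$release)
  cat(sprintf("  release probability %.3f +/- %.3f (mean +/- SEM)\n",
              g$mean_p, g$sem_p))
  if (!is.null(x$mode_proportions)) {
    m <- x$mode_proportions
    cat(sprintf("  modes: %s\n",
                paste(sprintf("%s %.1f%%", m$mode, m$percent), collapse = ", ")))
  }
  if (!is.null(x$dwell_fit_double)) {
    cat("  ")
    print(x$dwell_fit_double)
  }
  invisible(x)
}
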