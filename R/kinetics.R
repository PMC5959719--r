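# Dwell-time distribution fitting, averaged-event two-phase decay, mode
# proportions, retrieval dispersion versus dwell, and 40 Hz train kinetics.

default_dwell_breaks <- function(dwells) {
  # 0.1 s bins below 1 s to resolve the ultrafast peak, 1 s bins above
  hi <- max(2, ceiling(max(dwells)))
  c(seq(0, 1, by = 0.1), seq(2, hi, by = 1))
}

dwell_histogram <- function(dwells, breaks) {
  h <- graphics::hist(dwells, breaks = breaks, plot = FALSE)
  tibble(
    mid_s = h$mids, density = h$density,
    count = h$counts, width_s = diff(breaks)
  )
}

# EM for a K-component exponential mixture on raw dwell times
exp_mixture_mle <- function(x, K = 2, max_iter = 500, tol = 1e-10) {
  stopifnot(all(x > 0))
  q <- stats::quantile(x, probs = seq(0.2, 0.8, length.out = K))
  tau <- sort(as.numeric(q))
  tau[tau <= 0] <- min(x[x > 0])
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] / tau[k] * exp(-x / tau[k]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    resp <- dens / tot
    w <- colMeans(resp)
    tau <- colSums(resp * x) / colSums(resp)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(tau)
  list(tau = tau[ord], weight = w[ord], loglik = ll, iterations = it)
}

#' Fit a dwell-time distribution with exponential decay models
#'
#' Histograms the uncensored dwell times (density-normalised, 0.1 s bins
#' below 1 s and 1 s bins above by default) and fits
#' `A * exp(-t / tau)` (single) or `A1 * exp(-t / tau1) + A2 * exp(-t / tau2)`
#' (double) by nonlinear least squares, with no constant offset. A
#' maximum-likelihood exponential-mixture fit on the raw dwell times is
#' returned alongside as an independent cross-check of the histogram route.
#' Censored events must be excluded before calling; pass their count in
#' `n_censored` for bookkeeping.
#'
#' @param dwells Uncensored dwell times in seconds (>= 30).
#' @param model `"double"` (default) or `"single"`.
#' @param breaks Histogram breaks in seconds; default as described above.
#' @param n_censored Number of censored (ultraslow) events excluded upstream.
#' @return An object of class `dwell_fit`: model, `tau1_s`/`tau2_s`
#'   (`tau1 < tau2`), amplitudes `A1`/`A2`, `r_square`,
#'   `residual_sum_squares`, event counts, the binned histogram, the raw
#'   Levenberg-Marquardt fit, the MLE mixture cross-check (`$mle`), and a degeneracy
#'   flag for collapsed double fits.
#' @export
#' @examples
#' set.seed(1)
#' d <- c(rexp(300, 1 / 0.2), rexp(600, 1 / 8))
#' fit <- fit_dwell_distribution(d)
#' tidy(fit)
fit_dwell_distribution <- function(dwells, model = c("double", "single"),
                                   breaks = NULL, n_censored = 0) {
  model <- match.arg(model)
  dwells <- dwells[is.finite(dwells) & dwells >= 0]
  if (length(dwells) < 30) abort("need at least 30 uncensored dwell times")
  dwells <- pmax(dwells, 1e-6)
  if (is.null(breaks)) breaks <- default_dwell_breaks(dwells)
  hist_tb <- dwell_histogram(dwells, breaks)
  m <- hist_tb$mid_s
  d <- hist_tb$density
  tss <- sum((d - mean(d))^2)

  short <- dwells[dwells < 1]
  long <- dwells[dwells >= 1]
  # raw Levenberg-Marquardt: a collapsed double fit has a singular Jacobian,
  # which must be reported as degeneracy, not as a fitting error
  lm_fit <- function(fn, start, lower) {
    minpack.lm::nls.lm(par = start, lower = lower,
                       fn = function(p) d - fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 1000))
  }
  if (model == "single") {
    fn <- function(p) p[1] * exp(-m / p[2])
    fit <- lm_fit(fn, c(A = max(d), tau = mean(dwells)), c(0, 1e-4))
    cf <- fit$par
    tau1 <- cf[[2]]; tau2 <- NA_real_
    A1 <- cf[[1]]; A2 <- NA_real_
    mle <- list(tau = mean(dwells), weight = 1,
                loglik = sum(stats::dexp(dwells, 1 / mean(dwells), log = TRUE)))
    degenerate <- FALSE
    rss <- sum((d - fn(cf))^2)
  } else {
    t1_0 <- if (length(short) >= 5) mean(short) else 0.2
    t2_0 <- if (length(long) >= 5) mean(long) else max(2, mean(dwells))
    fn <- function(p) p[1] * exp(-m / p[2]) + p[3] * exp(-m / p[4])
    fit <- lm_fit(fn, c(A1 = max(d), tau1 = t1_0,
                        A2 = max(d[m >= 1], 0.05 * max(d)), tau2 = t2_0),
                  c(0, 1e-4, 0, 1e-4))
    cf <- fit$par
    ord <- order(c(cf[[2]], cf[[4]]))
    taus <- c(cf[[2]], cf[[4]])[ord]
    amps <- c(cf[[1]], cf[[3]])[ord]
    tau1 <- taus[1]; tau2 <- taus[2]
    A1 <- amps[1]; A2 <- amps[2]
    mle <- exp_mixture_mle(dwells, K = 2)
    # collapse: time constants indistinguishable or one amplitude vanishes
    degenerate <- (tau2 / tau1 < 1.5) || (min(A1, A2) < 1e-3 * max(A1, A2))
    if (degenerate) {
      warn("double-exponential fit is degenerate (components collapsed)")
    }
    rss <- sum((d - fn(cf))^2)
  }
  structure(
    list(
      model = model, tau1_s = tau1, tau2_s = tau2, A1 = A1, A2 = A2,
      r_square = 1 - rss / tss, residual_sum_squares = rss,
      n_events = length(dwells), n_censored = n_censored,
      breaks_s = breaks, histogram = hist_tb, fit = fit, mle = mle,
      degenerate = degenerate
    ),
    class = "dwell_fit"
  )
}

#' @method tidy dwell_fit
#' @export
tidy.dwell_fit <- function(x, ...) {
  if (x$model == "single") {
    tibble(term = c("A", "tau_s"), estimate = c(x$A1, x$tau1_s))
  } else {
    tibble(
      term = c("A1", "tau1_s", "A2", "tau2_s"),
      estimate = c(x$A1, x$tau1_s, x$A2, x$tau2_s)
    )
  }
}

#' @method glance dwell_fit
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble(
    model = x$model, tau1_s = x$tau1_s, tau2_s = x$tau2_s,
    r_square = x$r_square, residual_sum_squares = x$residual_sum_squares,
    n_events = x$n_events, n_censored = x$n_censored,
    mle_tau1_s = x$mle$tau[1],
    mle_tau2_s = if (length(x$mle$tau) > 1) x$mle$tau[2] else NA_real_,
    degenerate = x$degenerate
  )
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("%s-exponential dwell-time fit (%d events, %d censored excluded)\n",
              x$model, x$n_events, x$n_censored))
  if (x$model == "single") {
    cat(sprintf("  tau = %.3g s, R-square = %.3f, RSS = %.4g\n",
                x$tau1_s, x$r_square, x$residual_sum_squares))
  } else {
    cat(sprintf("  tau1 = %.3g s, tau2 = %.3g s, R-square = %.3f, RSS = %.4g\n",
                x$tau1_s, x$tau2_s, x$r_square, x$residual_sum_squares))
    cat(sprintf("  MLE cross-check: tau1 = %.3g s, tau2 = %.3g s (weight %.2f / %.2f)\n",
                x$mle$tau[1], x$mle$tau[2], x$mle$weight[1], x$mle$weight[2]))
  }
  invisible(x)
}

#' Compare single- and double-exponential dwell-time fits
#'
#' Extra-sum-of-squares F test between nested histogram fits, plus a
#' reduced (adjusted) R-square comparison; both fits must come from the same
#' histogram.
#'
#' @param single_fit,double_fit `dwell_fit` objects from
#'   [fit_dwell_distribution()] on the same dwell sample and breaks.
#' @param alpha Significance level of the verdict.
#' @return A one-row tibble: `f_statistic`, `df1`, `df2`, `p_value`, the two
#'   reduced R-squares, and `preferred` (`"single"` or `"double"`).
#' @export
compare_models <- function(single_fit, double_fit, alpha = 0.05) {
  if (!inherits(single_fit, "dwell_fit") || !inherits(double_fit, "dwell_fit")) {
    abort("both arguments must be dwell_fit objects")
  }
  if (single_fit$model != "single" || double_fit$model != "double") {
    abort("pass the single-model fit first and the double-model fit second")
  }
  if (!isTRUE(all.equal(single_fit$breaks_s, double_fit$breaks_s)) ||
      single_fit$n_events != double_fit$n_events) {
    abort("fits are not nested: different data or histogram breaks")
  }
  nb <- nrow(single_fit$histogram)
  p1 <- 2
  p2 <- 4
  df1 <- p2 - p1
  df2 <- nb - p2
  if (df2 <= 0) abort("too few histogram bins for the F test")
  rss1 <- single_fit$residual_sum_squares
  rss2 <- double_fit$residual_sum_squares
  f <- max(0, (rss1 - rss2) / df1) / (rss2 / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  tss <- rss1 / (1 - single_fit$r_square)
  red_r2 <- function(rss, p_) 1 - (rss / (nb - p_)) / (tss / (nb - 1))
  tibble(
    f_statistic = f, df1 = df1, df2 = df2, p_value = p,
    reduced_r_square_single = red_r2(rss1, p1),
    reduced_r_square_double = red_r2(rss2, p2),
    preferred = if (p < alpha) "double" else "single"
  )
}

#' Onset-aligned average of raw event traces
#'
#' Averages non-de-noised trace segments aligned at each detected event's
#' onset, the unbiased view of the post-fusion fluorescence time course.
#'
#' @param traces Raw (corrected, not de-noised) trace tibble.
#' @param events Event table from [detect_events()]; only detected,
#'   non-multivesicular events are used (>= 20 required).
#' @param pre_s,post_s Segment extent around the onset (s).
#' @param align Column of `events` giving the alignment time
#'   (default `"onset_time_s"`).
#' @return A tibble `time_rel_s`, `mean`, `sd`, `n`, baseline-subtracted per
#'   event before averaging.
#' @export
average_event_trace <- function(traces, events, pre_s = 1, post_s = 20,
                                align = "onset_time_s") {
  check_trace_df(traces)
  ev <- events |> filter(.data$detected, !.data$multivesicular)
  if (nrow(ev) < 20) abort("need at least 20 detected events to average")
  fs <- infer_sampling_rate(traces$time_s)
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  rel <- (-npre:npost) / fs
  segs <- matrix(NA_real_, nrow(ev), length(rel))
  by_b <- split(traces, traces$bouton_id)
  for (i in seq_len(nrow(ev))) {
    tb <- by_b[[ev$bouton_id[i]]]
    i0 <- which(tb$time_s >= ev[[align]][i])[1]
    idx <- (i0 - npre):(i0 + npost)
    ok <- idx >= 1 & idx <= nrow(tb)
    segs[i, ok] <- tb$intensity[idx[ok]] - ev$baseline_mean[i]
  }
  tibble(
    time_rel_s = rel,
    mean = apply(segs, 2, mean, na.rm = TRUE),
    sd = apply(segs, 2, sd, na.rm = TRUE),
    n = apply(segs, 2, function(z) sum(!is.na(z)))
  )
}

#' Two-phase exponential decay fit of an averaged event trace
#'
#' Fits `A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + c` to the post-peak
#' portion of an onset-aligned averaged trace. The constant accounts for the
#' non-retrieving (ultraslow) fraction; a collapsed fit (components merging
#' or an amplitude vanishing) is flagged, as seen when only one kinetic
#' phase is present.
#'
#' @param avg Averaged trace from [average_event_trace()].
#' @return A list of class `two_phase_fit`: `tau1_s < tau2_s`, amplitudes,
#'   offset, `r_square`, `degenerate` flag and the raw fit object.
#' @export
fit_two_phase_decay <- function(avg) {
  pk <- which.max(avg$mean)
  seg <- avg[pk:nrow(avg), ]
  t <- seg$time_rel_s - seg$time_rel_s[1]
  y <- seg$mean
  a0 <- max(y)
  fn <- function(p) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) + p[5]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A1 = a0 / 2, tau1 = 0.3, A2 = a0 / 4, tau2 = 5, c = min(y)),
      lower = c(0, 1e-3, 0, 1e-3, -Inf),
      fn = function(p) y - fn(p),
      control = minpack.lm::nls.lm.control(maxiter = 1000)
    ),
    error = function(e) abort(paste("two-phase decay fit failed:", conditionMessage(e)))
  )
  cf <- fit$par
  ord <- order(c(cf[[2]], cf[[4]]))
  taus <- c(cf[[2]], cf[[4]])[ord]
  amps <- c(cf[[1]], cf[[3]])[ord]
  rss <- sum((y - fn(cf))^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      tau1_s = taus[1], tau2_s = taus[2], A1 = amps[1], A2 = amps[2],
      offset = cf[[5]], r_square = 1 - rss / tss,
      degenerate = taus[2] / taus[1] < 1.5 || min(amps) < 0.02 * max(amps),
      fit = fit
    ),
    class = "two_phase_fit"
  )
}

#' @method tidy two_phase_fit
#' @export
tidy.two_phase_fit <- function(x, ...) {
  tibble(
    term = c("tau1_s", "tau2_s", "A1", "A2", "offset"),
    estimate = c(x$tau1_s, x$tau2_s, x$A1, x$A2, x$offset)
  )
}

#' Proportions of the three retrieval modes
#'
#' Percentage of detected (non-multivesicular) events in each kinetic mode;
#' the three percentages sum to 100. Invariant to event ordering and to any
#' rescaling of the underlying traces.
#'
#' @param events Event table (or any tibble with a `mode` column).
#' @return A tibble `mode`, `n`, `percent` covering all three modes.
#' @export
mode_proportions <- function(events) {
  ev <- events
  if ("detected" %in% names(ev)) {
    ev <- filter(ev, .data$detected, !.data$multivesicular)
  }
  if (nrow(ev) < 1) abort("need at least one event")
  lev <- c("ultrafast", "fast", "ultraslow")
  tb <- ev |>
    dplyr::count(mode = factor(.data$mode, levels = lev), .drop = FALSE) |>
    mutate(percent = 100 * .data$n / sum(.data$n), mode = as.character(mode))
  tb
}

#' Retrieval fraction as a function of dwell time
#'
#' Mean and SD of the fraction of retrieval in dwell-time bins, the summary
#' used to show that retrieval dispersion grows with dwell time. Empty bins
#' are absent from the output rather than reported as zero.
#'
#' @param events Event table; only rows with an observed decay (uncensored,
#'   with a retrieval fraction) are used.
#' @param dwell_breaks_s Bin edges in seconds.
#' @return Tibble `dwell_bin`, `n`, `mean_fraction`, `sd_fraction`.
#' @export
retrieval_vs_dwell <- function(events,
                               dwell_breaks_s = c(0, 0.1, 0.5, 1, 5, 10, 20)) {
  ev <- events |>
    filter(!is.na(.data$retrieval_fraction), !is.na(.data$dwell_s))
  if (nrow(ev) == 0) abort("no events with an observed decay")
  ev |>
    mutate(dwell_bin = cut(.data$dwell_s, breaks = dwell_breaks_s,
                           include.lowest = TRUE)) |>
    filter(!is.na(.data$dwell_bin)) |>
    group_by(.data$dwell_bin) |>
    summarise(
      n = n(),
      mean_fraction = mean(.data$retrieval_fraction),
      sd_fraction = sd(.data$retrieval_fraction),
      .groups = "drop"
    ) |>
    mutate(dwell_bin = as.character(.data$dwell_bin))
}

#' Amplitude, decay constant and rise slope of a 40 Hz train response
#'
#' Measures the bulk response to a stimulus train: amplitude as the peak
#' fluorescence change over the pre-train baseline, the decay time constant
#' from a single-exponential fit of the post-train return, and the rise
#' slope from linear regression of the fluorescence change against time
#' during the train.
#'
#' @param trace Trace tibble of a single bouton (or averaged response).
#' @param train_start_s,train_end_s Train onset and offset times (s).
#' @param baseline_window_s Pre-train window for the baseline mean (s).
#' @return An object of class `train_fit`: `amplitude`, `decay_tau_s`,
#'   `rise_slope`, fit diagnostics (`decay_r_square`, `rise_r_square`), and
#'   a `fit_ok` flag (FALSE when the response is flat or a fit failed).
#' @export
analyze_train_response <- function(trace, train_start_s, train_end_s,
                                   baseline_window_s = 5) {
  check_trace_df(trace)
  if (length(unique(trace$bouton_id)) != 1) {
    abort("analyze_train_response expects a single bouton trace")
  }
  t <- trace$time_s
  y <- trace$intensity
  if (train_start_s <= min(t) || train_end_s >= max(t) ||
      train_end_s <= train_start_s) {
    abort("train must lie strictly within the trace")
  }
  base_idx <- t >= train_start_s - baseline_window_s & t < train_start_s
  if (!any(base_idx)) abort("no samples in the pre-train baseline window")
  b <- mean(y[base_idx])
  dy <- y - b
  rise_idx <- t >= train_start_s & t <= train_end_s
  peak_idx <- which(t >= train_start_s & t <= train_end_s + 1)
  amplitude <- max(dy[peak_idx])
  flat <- amplitude <= 3 * sd(y[base_idx]) + 1e-12
  rise_fit <- lm(dy[rise_idx] ~ I(t[rise_idx] - train_start_s))
  rise_slope <- coef(rise_fit)[[2]]
  rise_r2 <- suppressWarnings(summary(rise_fit)$r.squared)
  post_idx <- t > train_end_s
  td <- t[post_idx] - train_end_s
  yd <- dy[post_idx]
  decay <- tryCatch(
    minpack.lm::nlsLM(
      yd ~ A * exp(-td / tau),
      start = list(A = max(amplitude, 1e-6), tau = max(td) / 3),
      lower = c(A = 0, tau = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (flat || is.null(decay)) {
    decay_tau <- NA_real_
    decay_r2 <- NA_real_
    ok <- FALSE
  } else {
    decay_tau <- coef(decay)[["tau"]]
    rssd <- sum(resid(decay)^2)
    decay_r2 <- 1 - rssd / sum((yd - mean(yd))^2)
    ok <- TRUE
  }
  structure(
    list(
      amplitude = amplitude, decay_tau_s = decay_tau, rise_slope = rise_slope,
      decay_r_square = decay_r2, rise_r_square = rise_r2,
      baseline = b, fit_ok = ok,
      train_start_s = train_start_s, train_end_s = train_end_s
    ),
    class = "train_fit"
  )
}

#' @method glance train_fit
#' @export
glance.train_fit <- function(x, ...) {
  tibble(
    amplitude = x$amplitude, decay_tau_s = x$decay_tau_s,
    rise_slope = x$rise_slope, decay_r_square = x$decay_r_square,
    rise_r_square = x$rise_r_square, fit_ok = x$fit_ok
  )
}

#' @method tidy train_fit
#' @export
tidy.train_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "decay_tau_s", "rise_slope"),
    estimate = c(x$amplitude, x$decay_tau_s, x$rise_slope)
  )
}

#' @export
print.train_fit <- function(x, ...) {
  cat(sprintf(
    "Train response: amplitude %.3g a.u., decay tau %.3g s (R2 %.3f), rise slope %.3g a.u./s (R2 %.3f)%s\n",
    x$amplitude, x$decay_tau_s, x$decay_r_square, x$rise_slope,
    x$rise_r_square, if (x$fit_ok) "" else " [fit flagged]"
  ))
  invisible(x)
}
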