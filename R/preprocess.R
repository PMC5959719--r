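# Photobleaching and background correction of raw traces.

#' Build an event-free sample mask around stimuli
#'
#' Marks samples outside `[-before_s, +after_s]` windows around each stimulus
#' as event-free. Note that under sparse 0.05 Hz stimulation a +20 s window
#' covers the whole trace; use a shorter window, or fit the bleach trend on
#' the full trace (the pipeline default), for that protocol.
#'
#' @param traces Trace tibble (`time_s`, `bouton_id`, `intensity`).
#' @param stimulus_times_s Stimulus times (s).
#' @param before_s,after_s Exclusion window around each stimulus (s).
#' @return Logical vector, one element per row of `traces`.
#' @export
stimulus_mask <- function(traces, stimulus_times_s, before_s = 0.5, after_s = 20) {
  check_trace_df(traces)
  keep <- rep(TRUE, nrow(traces))
  for (s in stimulus_times_s) {
    keep <- keep & !(traces$time_s >= s - before_s & traces$time_s <= s + after_s)
  }
  keep
}

# bleach + staircase model for stimulus-locked protocols. Fusion events that
# are never retrieved permanently elevate the trace, so the model is an
# exponential bleach trend plus a nonnegative persistent step at each
# stimulus time. The within-interval curvature that identifies (a, tau)
# comes from intervals with no apparent event (the trace never leaves its
# baseline band); event-containing intervals contribute only their
# end-of-interval baseline block. Steps only increase while the bleach term
# only decreases, and among near-equivalent fits the one with the least
# total bleach drift is preferred, which keeps the degenerate all-event
# case from inventing a trend. Linear in everything but tau, so tau is
# profiled over a log grid and the rest solved by weighted least squares
# with nonnegativity enforced by an active-set clamp.
fit_bleach_steps <- function(t, y, stim, baseline_window_s = 2,
                             robust_iterations = 3) {
  span <- max(t) - min(t)
  sig <- stats::mad(diff(y)) / sqrt(2)
  K <- length(stim)
  edges <- c(stim, max(t) + 1e-9)
  sel <- t < stim[1] # pre-protocol stretch: always event-free
  for (k in seq_len(K)) {
    iv <- t >= edges[k] & t < edges[k + 1]
    bl <- t >= edges[k] - baseline_window_s & t < edges[k]
    ref <- if (any(bl)) stats::median(y[bl]) else stats::median(y[iv])
    clean <- sig > 0 && any(iv) && max(y[iv]) - ref < 3.5 * sig
    if (clean) {
      sel <- sel | iv
    } else if (k < K) {
      # keep only the next stimulus' baseline block of a dirty interval
      sel <- sel | (t >= edges[k + 1] - baseline_window_s & t < edges[k + 1])
    }
  }
  ts <- t[sel]
  ys <- y[sel]
  X0 <- cbind(1, vapply(stim, function(s) as.numeric(ts >= s), numeric(length(ts))))
  taus <- exp(seq(log(span / 50), log(2 * span), length.out = 15))
  solve_tau <- function(tau, w) {
    X <- cbind(exp(-ts / tau), X0)
    co <- stats::lm.wfit(X, ys, w)$coefficients
    co[is.na(co)] <- 0
    # clamp the bleach amplitude and step sizes at zero
    for (pass in 1:3) {
      negs <- which(c(co[1] < 0, FALSE, co[-(1:2)] < 0))
      if (length(negs) == 0) break
      keep_c <- setdiff(seq_len(ncol(X)), negs)
      co[] <- 0
      sub <- stats::lm.wfit(X[, keep_c, drop = FALSE], ys, w)$coefficients
      sub[is.na(sub)] <- 0
      co[keep_c] <- sub
    }
    r <- ys - drop(X %*% co)
    list(tau = tau, co = co, r = r, rss = sum(w * r^2))
  }
  w <- rep(1, length(ys))
  best <- NULL
  for (it in seq_len(robust_iterations)) {
    fits <- lapply(taus, solve_tau, w = w)
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    drift <- vapply(fits, function(f) f$co[1] * (1 - exp(-span / f$tau)),
                    numeric(1))
    ok <- rss <= 1.02 * min(rss)
    best <- fits[ok][[which.min(drift[ok])]]
    if (!is.finite(sig) || sig <= 0) break
    # down-weight samples elevated by an unfinished event decay
    w_new <- ifelse(best$r > 2.5 * sig, 0.005, 1)
    if (all(w_new == w)) break
    w <- w_new
  }
  list(method = "exponential+steps", a = best$co[1], tau_s = best$tau,
       asymptote = best$co[2], trend = best$co[1] * exp(-t / best$tau))
}

fit_bleach_one <- function(t, y, robust_iterations = 5) {
  span <- max(t) - min(t)
  n <- length(y)
  head_m <- mean(y[seq_len(max(3, n %/% 10))])
  tail_m <- mean(y[seq(n - max(3, n %/% 10) + 1, n)])
  w <- rep(1, n)
  par <- NULL
  # drift- and event-insensitive noise scale from first differences
  sig <- stats::mad(diff(y)) / sqrt(2)
  a0 <- max(head_m - tail_m, sig, 1e-2 * max(abs(y), 1))
  start <- c(a = a0, tau = span / 3, c = tail_m)
  model <- function(p) p[1] * exp(-t / p[2]) + p[3]
  # iteratively reweighted asymmetric fit: fusion events and persistently
  # elevated (non-retrieved) stretches sit above the baseline, so positive
  # excursions are down-weighted and the fit tracks the baseline envelope
  for (it in seq_len(robust_iterations)) {
    lmfit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = c(0, span / 1e4, -Inf), upper = c(Inf, Inf, Inf),
        fn = function(p) sqrt(w) * (y - model(p)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(lmfit)) break # keep the previous successful fit
    par <- lmfit$par
    if (!is.finite(sig) || sig <= 0) break # noiseless: plain fit suffices
    r <- y - model(par)
    q_lo <- stats::quantile(r, 0.1, names = FALSE) # lower-envelope reference
    w_new <- ifelse(r - q_lo > 2.5 * sig, 0.005, 1)
    if (all(w_new == w)) break
    w <- w_new
    start <- par
    start[2] <- max(start[2], span / 5e3)
  }
  if (!is.null(par)) {
    list(method = "exponential", a = par[[1]], tau_s = par[[2]],
         asymptote = par[[3]], trend = par[[1]] * exp(-t / par[[2]]))
  } else {
    # fallback: linear detrend, flagged
    lf <- lm(y ~ t)
    sl <- coef(lf)[[2]]
    list(method = "linear", a = NA_real_, tau_s = NA_real_,
         asymptote = coef(lf)[[1]] + sl * max(t), trend = sl * (t - max(t)))
  }
}

#' Correct photobleaching with a single-exponential fit
#'
#' Fits `a * exp(-t / tau) + c` to the event-free samples of each bouton and
#' subtracts the fitted trend minus its asymptote, flattening the baseline
#' without changing the amplitude scale. On fit failure the bouton falls back
#' to a linear detrend and is flagged.
#'
#' @param traces Trace tibble.
#' @param event_free_mask Optional logical vector (one per row of `traces`)
#'   marking samples to use in the fit, e.g. from [stimulus_mask()]. `NULL`
#'   uses every sample. Must cover at least `min_mask_frac` of each bouton.
#' @param stimulus_times_s Optional stimulus times (s). When given, the model
#'   adds a nonnegative persistent step at each stimulus, so fusion events
#'   that never retrieve (whose fluorescence stays up) are not confounded
#'   with the bleach trend; only the exponential term is subtracted.
#' @param min_mask_frac Minimum fraction of samples the mask must retain.
#' @return The corrected trace tibble, with the per-bouton fits in attribute
#'   `"bleach_fits"` (see [bleach_fits()]).
#' @export
correct_photobleaching <- function(traces, event_free_mask = NULL,
                                   stimulus_times_s = NULL,
                                   min_mask_frac = 0.1) {
  check_trace_df(traces)
  if (is.null(event_free_mask)) event_free_mask <- rep(TRUE, nrow(traces))
  if (length(event_free_mask) != nrow(traces)) {
    abort("event_free_mask must have one element per row of `traces`")
  }
  traces$..mask <- event_free_mask
  parts <- traces |>
    group_by(.data$bouton_id) |>
    dplyr::group_split()
  fits <- vector("list", length(parts))
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- parts[[i]]
    if (mean(d$..mask) < min_mask_frac) {
      abort(sprintf(
        "event-free mask covers %.1f%% of bouton %s; need >= %.0f%%",
        100 * mean(d$..mask), d$bouton_id[1], 100 * min_mask_frac
      ))
    }
    f <- if (is.null(stimulus_times_s)) {
      fit_bleach_one(d$time_s[d$..mask], d$intensity[d$..mask])
    } else {
      fit_bleach_steps(d$time_s[d$..mask], d$intensity[d$..mask],
                       stimulus_times_s)
    }
    trend_all <- if (f$method != "linear") {
      f$a * exp(-d$time_s / f$tau_s)
    } else {
      stats::approx(d$time_s[d$..mask], f$trend, xout = d$time_s, rule = 2)$y
    }
    # re-anchored at the trace end so the corrected level is preserved
    d$intensity <- d$intensity - (trend_all - trend_all[length(trend_all)])
    d$..mask <- NULL
    out[[i]] <- d
    fits[[i]] <- tibble(
      bouton_id = d$bouton_id[1], method = f$method,
      bleach_amplitude = f$a, bleach_tau_s = f$tau_s, asymptote = f$asymptote
    )
  }
  res <- bind_rows(out)
  attr(res, "bleach_fits") <- bind_rows(fits)
  res
}

#' Per-bouton photobleaching fit parameters
#'
#' @param traces The tibble returned by [correct_photobleaching()].
#' @return Tibble of per-bouton fit parameters and method flags.
#' @export
bleach_fits <- function(traces) {
  f <- attr(traces, "bleach_fits")
  if (is.null(f)) abort("no bleach fits attached; run correct_photobleaching() first")
  f
}

#' Subtract background fluorescence
#'
#' Elementwise subtraction of a scalar background level, a background trace
#' sampled on the same time base (e.g. a cell-free region), or a per-bouton
#' table of scalars.
#'
#' @param traces Trace tibble.
#' @param background A scalar, a numeric vector with one value per time point
#'   (recycled across boutons), or a tibble with columns `time_s` and
#'   `intensity`.
#' @return Corrected trace tibble; attribute `"background_source"` records
#'   what was subtracted.
#' @export
subtract_background <- function(traces, background) {
  check_trace_df(traces)
  nt <- length(unique(traces$time_s))
  if (is.data.frame(background)) {
    if (!all(c("time_s", "intensity") %in% names(background))) {
      abort("background trace needs columns time_s and intensity")
    }
    bg <- stats::approx(background$time_s, background$intensity,
                        xout = traces$time_s, rule = 2)$y
    src <- "trace"
  } else if (length(background) == 1) {
    bg <- background
    src <- "scalar"
  } else if (length(background) == nt) {
    bg <- background[match(traces$time_s, sort(unique(traces$time_s)))]
    src <- "per-timepoint vector"
  } else {
    abort(sprintf(
      "background length %d matches neither 1 nor the %d time points",
      length(background), nt
    ))
  }
  traces$intensity <- traces$intensity - bg
  attr(traces, "background_source") <- src
  traces
}
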