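# Chung-Kennedy forward-backward nonlinear de-noising and the FFT low-pass
# comparator. The CK filter runs a bank of forward and backward
# moving-average predictors of several window lengths; at every sample each
# predictor is weighted by the inverse of its recent one-sided squared
# prediction error, so predictors whose window straddles a step are
# suppressed and step edges survive where linear smoothing would blur them.

ck_filter_core <- function(x, config) {
  n <- length(x)
  if (!all(is.finite(x))) abort("trace contains non-finite samples")
  windows <- config$predictor_windows
  M <- config$comparison_window_M
  if (n <= max(windows) + M) {
    abort(sprintf("trace too short for filtering: need > %d samples, got %d",
                  max(windows) + M, n))
  }
  p <- config$weighting_exponent_p
  eps <- config$regularizer_epsilon
  prior <- config$prior_weights
  k <- seq_len(n)
  cs <- c(0, cumsum(x))
  num <- numeric(n)
  den <- numeric(n)
  for (i in seq_along(windows)) {
    w <- windows[i]
    # forward predictor: mean of the preceding min(w, k-1) samples
    wf <- pmin(w, k - 1L)
    pf <- rep(NA_real_, n)
    has_f <- wf > 0
    pf[has_f] <- (cs[k[has_f]] - cs[k[has_f] - wf[has_f]]) / wf[has_f]
    # backward predictor: mean of the following min(w, n-k) samples
    wb <- pmin(w, n - k)
    pb <- rep(NA_real_, n)
    has_b <- wb > 0
    pb[has_b] <- (cs[k[has_b] + wb[has_b] + 1L] - cs[k[has_b] + 1L]) / wb[has_b]
    # one-sided running error: sum of the M most recent squared residuals on
    # the predictor's own side (past for forward, future for backward),
    # truncated at the trace boundaries
    rf2 <- ifelse(has_f, (x - pf)^2, 0)
    rb2 <- ifelse(has_b, (x - pb)^2, 0)
    cf <- c(0, cumsum(rf2))
    cb <- c(0, cumsum(rb2))
    ef <- cf[k + 1L] - cf[pmax(k - M, 0L) + 1L]
    eb <- cb[pmin(k + M - 1L, n) + 1L] - cb[k]
    wtf <- prior[i] * (ef + eps)^(-p)
    wtb <- prior[i] * (eb + eps)^(-p)
    wtf[!has_f] <- 0
    wtb[!has_b] <- 0
    pf[!has_f] <- 0
    pb[!has_b] <- 0
    num <- num + wtf * pf + wtb * pb
    den <- den + wtf + wtb
  }
  num / den
}

#' Chung-Kennedy forward-backward nonlinear filter
#'
#' De-noises a fluorescence trace with a bank of forward and backward
#' moving-average predictors combined by inverse recent prediction error.
#' The filter preserves step edges and plateau amplitudes, is the identity on
#' constant traces, and is equivariant under affine transforms of the input.
#' Boundary samples use truncated windows; predictors with an empty window
#' receive zero weight.
#'
#' @param x A numeric trace, or a trace tibble with columns `time_s`,
#'   `bouton_id`, `intensity` (each bouton filtered independently).
#' @param config A [denoise_config()].
#' @param ... Passed to methods.
#'
#' @return Same shape as the input: a numeric vector, or the tibble with
#'   `intensity` replaced by the de-noised signal.
#' @export
#' @examples
#' x <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.1)
#' xf <- ck_filter(x)
ck_filter <- function(x, config = denoise_config(), ...) {
  UseMethod("ck_filter")
}

#' @rdname ck_filter
#' @export
ck_filter.numeric <- function(x, config = denoise_config(), ...) {
  ck_filter_core(x, config)
}

#' @rdname ck_filter
#' @export
ck_filter.data.frame <- function(x, config = denoise_config(), ...) {
  check_trace_df(x)
  x |>
    group_by(.data$bouton_id) |>
    mutate(intensity = ck_filter_core(.data$intensity, config)) |>
    ungroup()
}

fft_lowpass_core <- function(x, cutoff_hz, sampling_rate_hz) {
  if (!all(is.finite(x))) abort("trace contains non-finite samples")
  nyquist <- sampling_rate_hz / 2
  if (cutoff_hz >= nyquist) {
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  cutoff_hz, nyquist))
  }
  n <- length(x)
  freq <- (seq_len(n) - 1) / n * sampling_rate_hz
  freq <- pmin(freq, sampling_rate_hz - freq) # two-sided spectrum
  X <- fft(x)
  X[freq > cutoff_hz] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' FFT low-pass filter
#'
#' Zeroes all frequency components above `cutoff_hz` and inverse-transforms.
#' Used as the comparator to the Chung-Kennedy filter: it attenuates the
#' amplitude of plateaus shorter than roughly `1 / cutoff` while the CK
#' filter preserves them.
#'
#' @param x A numeric trace or trace tibble (see [ck_filter()]).
#' @param cutoff_hz Low-pass cutoff in Hz (must be below Nyquist).
#' @param sampling_rate_hz Sampling rate; inferred from `time_s` for tibbles.
#' @param ... Passed to methods.
#' @return Filtered trace, same shape as the input.
#' @export
fft_lowpass <- function(x, cutoff_hz = 2, sampling_rate_hz = NULL, ...) {
  UseMethod("fft_lowpass")
}

#' @rdname fft_lowpass
#' @export
fft_lowpass.numeric <- function(x, cutoff_hz = 2, sampling_rate_hz = NULL, ...) {
  if (is.null(sampling_rate_hz)) {
    abort("sampling_rate_hz is required for a bare numeric trace")
  }
  fft_lowpass_core(x, cutoff_hz, sampling_rate_hz)
}

#' @rdname fft_lowpass
#' @export
fft_lowpass.data.frame <- function(x, cutoff_hz = 2, sampling_rate_hz = NULL, ...) {
  check_trace_df(x)
  if (is.null(sampling_rate_hz)) sampling_rate_hz <- infer_sampling_rate(x$time_s)
  x |>
    group_by(.data$bouton_id) |>
    mutate(intensity = fft_lowpass_core(.data$intensity, cutoff_hz, sampling_rate_hz)) |>
    ungroup()
}

#' Normality check of trace residuals
#'
#' Tests whether residuals (raw minus de-noised baseline segments) are
#' consistent with Gaussian noise, using the Lilliefors
#' (Kolmogorov-Smirnov) test for normality with estimated parameters.
#' The de-noising filter assumes Gaussian noise, so this is the standing
#' sanity check on real or simulated data.
#'
#' @param residuals Numeric vector of at least 20 residuals.
#' @param alpha Significance level of the pass/fail decision.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `n`, `alpha`,
#'   `gaussian` (logical: not rejected at `alpha`).
#' @export
noise_gaussianity <- function(residuals, alpha = 0.01) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 20) abort("need at least 20 residuals")
  if (sd(residuals) == 0) {
    abort("residuals are constant; normality test is degenerate")
  }
  ht <- nortest::lillie.test(residuals)
  tibble(
    test = "Lilliefors (Kolmogorov-Smirnov) normality test",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = length(residuals),
    alpha = alpha,
    gaussian = ht$p.value >= alpha
  )
}
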