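#' Design the spike-band Butterworth filter
#'
#' Butterworth band-pass used to isolate the extracellular spike band
#' before threshold detection. Defaults: 200-3000 Hz pass band, order 3.
#' The single-pass magnitude response is -3 dB at both design cutoffs;
#' [bandpass_filter()] applies it forward-backward (zero phase).
#'
#' @param rate_hz Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (Hz); must satisfy
#'   `0 < low < high < rate_hz / 2`.
#' @param order Butterworth order of the low-pass prototype.
#' @return A `signal::Arma` filter object with attributes `rate_hz`,
#'   `low_hz`, `high_hz`.
#' @export
spike_band_filter <- function(rate_hz, low_hz = 200, high_hz = 3000, order = 3) {
  check_positive_scalar(rate_hz, "rate_hz")
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < rate_hz / 2)) {
    stop_invalid("band edges must satisfy 0 < low < high < rate/2")
  }
  filt <- signal::butter(order, c(low_hz, high_hz) / (rate_hz / 2), type = "pass")
  attr(filt, "rate_hz") <- rate_hz
  attr(filt, "low_hz") <- low_hz
  attr(filt, "high_hz") <- high_hz
  filt
}

#' Band-pass filter an MEA recording
#'
#' Applies the spike-band Butterworth filter per electrode with
#' `signal::filtfilt` (forward-backward, zero phase distortion).
#'
#' @param rec An `mea_recording`, a voltage matrix (electrodes x samples),
#'   or a numeric vector (one electrode).
#' @param rate_hz Sampling rate; taken from `rec` when it is an
#'   `mea_recording`.
#' @inheritParams spike_band_filter
#' @return Same shape as the input, filtered.
#' @export
bandpass_filter <- function(rec, low_hz = 200, high_hz = 3000, order = 3,
                            rate_hz = NULL) {
  if (inherits(rec, "mea_recording")) {
    filt <- spike_band_filter(rec$rate_hz, low_hz, high_hz, order)
    rec$voltage <- t(apply(rec$voltage, 1L, function(v) signal::filtfilt(filt, v)))
    rec$filtered <- TRUE
    return(rec)
  }
  if (is.null(rate_hz)) stop_invalid("`rate_hz` is required for matrix/vector input")
  filt <- spike_band_filter(rate_hz, low_hz, high_hz, order)
  if (is.matrix(rec)) {
    t(apply(rec, 1L, function(v) signal::filtfilt(filt, v)))
  } else {
    signal::filtfilt(filt, as.numeric(rec))
  }
}

#' Magnitude response of a designed filter
#'
#' Evaluates the single-pass magnitude response |H(f)| of a digital filter
#' at the requested frequencies.
#'
#' @param filt Filter from [spike_band_filter()].
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param rate_hz Sampling rate; defaults to the rate stored on `filt`.
#' @return Numeric vector of magnitudes (1 = unity gain).
#' @export
filter_response <- function(filt, freq_hz, rate_hz = attr(filt, "rate_hz")) {
  w <- 2 * pi * freq_hz / rate_hz
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1L)), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1L)), complex(1))
  Mod(num / den)
}

#' Locate the -3 dB band edges of a filter
#'
#' Finds, by bisection on the magnitude response, the lower and upper
#' frequencies at which attenuation reaches 3 dB (|H| = 1/sqrt(2)).
#'
#' @inheritParams filter_response
#' @return Named numeric vector `c(low_hz =, high_hz =)`.
#' @export
filter_band_edges <- function(filt, rate_hz = attr(filt, "rate_hz")) {
  resp <- function(f) filter_response(filt, f, rate_hz) - 1 / sqrt(2)
  centre_lo <- attr(filt, "low_hz") %||% 200
  centre_hi <- attr(filt, "high_hz") %||% rate_hz / 4
  low <- stats::uniroot(resp, c(1, sqrt(centre_lo * centre_hi)), tol = 1e-6)$root
  high <- stats::uniroot(resp, c(sqrt(centre_lo * centre_hi), rate_hz / 2 - 1),
    tol = 1e-6
  )$root
  c(low_hz = low, high_hz = high)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise gain of the zero-phase spike-band filter
#'
#' Ratio between the SD of white Gaussian noise after forward-backward
#' filtering and before it, computed from the zero-phase impulse response.
#' Used to translate a raw-noise SD into the detector-domain (post-filter)
#' noise SD when calibrating simulated spike amplitudes.
#'
#' @inheritParams filter_response
#' @param n Impulse length used for the computation.
#' @return Scalar gain (< 1 for a band-pass narrower than the Nyquist band).
#' @export
filter_noise_gain <- function(filt, n = 8192L) {
  imp <- c(rep(0, n %/% 2), 1, rep(0, n %/% 2))
  h <- signal::filtfilt(filt, imp)
  sqrt(sum(h^2))
}

#' Estimate per-electrode baseline noise SD
#'
#' Default method is the robust median estimator
#' `sigma = median(|v|) / 0.6745`, which is insensitive to the small
#' fraction of samples occupied by spikes. Alternatively, a plain SD over
#' a caller-designated spike-free interval.
#'
#' @param filtered Band-passed voltage: `mea_recording`, matrix
#'   (electrodes x samples) or numeric vector.
#' @param method `"mad"` (robust default) or `"sd"`.
#' @param baseline Optional index vector (samples) restricting the
#'   estimate to a spike-free interval; required context for `method =
#'   "sd"` to be meaningful when spikes are present.
#' @return Tibble with `electrode` and `sigma` (uV). All-constant traces
#'   yield `sigma = 0` with a warning.
#' @export
estimate_noise_sd <- function(filtered, method = c("mad", "sd"), baseline = NULL) {
  method <- match.arg(method)
  v <- if (inherits(filtered, "mea_recording")) filtered$voltage else filtered
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  if (!is.null(baseline)) v <- v[, baseline, drop = FALSE]
  sigma <- apply(v, 1L, function(x) {
    switch(method,
      mad = median(abs(x)) / 0.6745,
      sd = sd(x)
    )
  })
  if (any(sigma == 0)) {
    rlang::warn("constant trace(s): estimated noise SD is 0")
  }
  tibble(electrode = seq_len(nrow(v)), sigma = as.numeric(sigma))
}
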