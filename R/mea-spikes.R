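#' Threshold spike detection on filtered voltage
#'
#' Detects a spike at each positive excursion whose peak strictly exceeds
#' `threshold_sd` times the per-electrode baseline noise SD (default 6.0).
#' After each detection, further threshold crossings are suppressed for
#' `dead_time_ms` (default 1 ms) so one waveform is never counted twice.
#' Spike time is the peak sample divided by the sampling rate.
#'
#' @param filtered Band-passed voltage: `mea_recording`, matrix
#'   (electrodes x samples), or numeric vector.
#' @param rate_hz Sampling rate (Hz); taken from an `mea_recording` input.
#' @param sigma Per-electrode noise SD: a numeric vector, a tibble from
#'   [estimate_noise_sd()], or `NULL` to estimate with the robust default.
#' @param threshold_sd Detection threshold in multiples of the noise SD.
#' @param dead_time_ms Refractory window after each detection (ms).
#' @param polarity `"positive"` (default, literal reading of a `+k x SD`
#'   threshold) or `"both"` to also detect negative deflections.
#' @return Tibble with columns `electrode`, `time` (s), `amplitude` (uV,
#'   signed peak value), sorted by electrode then time.
#' @export
detect_spikes <- function(filtered, rate_hz = NULL, sigma = NULL,
                          threshold_sd = 6, dead_time_ms = 1,
                          polarity = c("positive", "both")) {
  polarity <- match.arg(polarity)
  if (inherits(filtered, "mea_recording")) {
    rate_hz <- filtered$rate_hz
    v <- filtered$voltage
  } else {
    v <- filtered
  }
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  if (is.null(rate_hz)) stop_invalid("`rate_hz` is required")
  if (ncol(v) == 0L) {
    return(tibble(electrode = integer(), time = numeric(), amplitude = numeric()))
  }
  if (is.null(sigma)) sigma <- estimate_noise_sd(v)
  if (is.data.frame(sigma)) sigma <- sigma$sigma[order(sigma$electrode)]
  sigma <- rep_len(as.numeric(sigma), nrow(v))

  dead_samples <- max(1L, round(dead_time_ms / 1000 * rate_hz))
  out <- purrr::map(seq_len(nrow(v)), function(el) {
    x <- v[el, ]
    thr <- threshold_sd * sigma[el]
    peaks <- find_excursion_peaks(x, thr)
    if (polarity == "both") {
      peaks <- sort(c(peaks, find_excursion_peaks(-x, thr)))
    }
    peaks <- apply_dead_time(peaks, dead_samples)
    tibble(
      electrode = el,
      time = (peaks - 1) / rate_hz,
      amplitude = x[peaks]
    )
  })
  bind_rows(out) %>% arrange(.data$electrode, .data$time)
}

# Peak index of every contiguous run of samples strictly above `thr`.
find_excursion_peaks <- function(x, thr) {
  above <- x > thr
  if (!any(above)) {
    return(integer(0))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  vapply(
    seq_along(starts),
    function(i) starts[i] + which.max(x[starts[i]:ends[i]]) - 1L,
    integer(1)
  )
}

# Keep peaks separated by at least `dead` samples (first-come wins).
apply_dead_time <- function(peaks, dead) {
  if (length(peaks) < 2L) {
    return(peaks)
  }
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= dead) {
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  peaks[keep]
}

#' Classify active electrodes
#'
#' An electrode is active when its average firing rate strictly exceeds
#' `min_rate_per_min` spikes per minute (default 5) over the whole
#' recording.
#'
#' @param spikes Spike tibble with columns `electrode`, `time`.
#' @param duration_s Recording duration (s).
#' @param n_electrodes Total electrodes in the well (silent electrodes are
#'   reported with zero spikes).
#' @param min_rate_per_min Activity threshold (spikes/min, strict `>`).
#' @return Tibble: `electrode`, `n_spikes`, `rate_per_min`, `active`.
#' @export
classify_active_electrodes <- function(spikes, duration_s, n_electrodes,
                                       min_rate_per_min = 5) {
  check_positive_scalar(duration_s, "duration_s")
  counts <- spikes %>%
    count(.data$electrode, name = "n_spikes")
  tibble(electrode = seq_len(n_electrodes)) %>%
    left_join(counts, by = "electrode") %>%
    mutate(
      n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
      rate_per_min = .data$n_spikes / (duration_s / 60),
      active = .data$rate_per_min > min_rate_per_min
    )
}

#' Mean firing rate per active electrode
#'
#' Mean over the active electrodes of spike count / duration, in spikes
#' per second. Undefined (NA) when the active set is empty - never zero.
#'
#' @param spikes Spike tibble (`electrode`, `time`).
#' @param duration_s Recording duration (s).
#' @param active Integer vector of active electrode ids, or the tibble
#'   returned by [classify_active_electrodes()].
#' @return Scalar spikes/s, or `NA` for an empty active set.
#' @export
mean_firing_rate <- function(spikes, duration_s, active) {
  check_positive_scalar(duration_s, "duration_s")
  if (is.data.frame(active)) active <- active$electrode[active$active]
  if (length(active) == 0L) {
    return(undefined_metric())
  }
  rates <- vapply(
    active,
    function(el) sum(spikes$electrode == el) / duration_s,
    numeric(1)
  )
  mean(rates)
}
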