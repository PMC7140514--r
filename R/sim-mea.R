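#' Configuration for simulated MEA recordings
#'
#' Builds the parameter block consumed by [simulate_spike_trains()] and
#' [simulate_mea_recording()]. Defaults emulate one well of a 48-well MEA
#' plate: 16 electrodes sampled at 12.5 kHz for 5 minutes, spontaneous
#' background firing plus electrode-level burst epochs and well-wide
#' network events shared by a subset of electrodes.
#'
#' `amplitude_uV` is defined as the spike peak height *after* the default
#' 200-3000 Hz band-pass filter, so the detector-domain signal-to-noise
#' ratio is directly controllable: post-filter SNR equals
#' `amplitude_uV / (noise_sd_uV * filter_noise_gain(...))`.
#'
#' @param seed Integer RNG seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @param n_electrodes Electrodes per well.
#' @param duration_s Recording length in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param background_rate_hz Homogeneous Poisson background firing rate per
#'   electrode (Hz).
#' @param burst_rate_per_min Rate of electrode-level burst epochs
#'   (epochs/min/electrode).
#' @param intra_burst_rate_hz Firing rate inside a burst epoch (Hz).
#' @param burst_duration_s Duration of one burst epoch (s).
#' @param network_rate_per_min Rate of well-wide network events (events/min).
#' @param network_event_rate_hz Firing rate on participating electrodes
#'   during a network event (Hz).
#' @param network_event_duration_s Network event duration (s); default one
#'   100 ms analysis window.
#' @param network_fraction Fraction of electrodes participating in each
#'   network event (the first `ceiling(fraction * n)` electrodes).
#' @param align_network_events Snap network event onsets to the 100 ms
#'   analysis grid so implanted events land in single analysis windows.
#' @param amplitude_uV Post-filter spike peak amplitude (uV).
#' @param noise_sd_uV SD of the raw (pre-filter) Gaussian electrode noise (uV).
#' @return A list of class `mea_sim_config`.
#' @export
mea_sim_config <- function(seed = 1L,
                           n_electrodes = 16L,
                           duration_s = 300,
                           rate_hz = 12500,
                           background_rate_hz = 2,
                           burst_rate_per_min = 2,
                           intra_burst_rate_hz = 80,
                           burst_duration_s = 0.3,
                           network_rate_per_min = 1,
                           network_event_rate_hz = 700,
                           network_event_duration_s = 0.1,
                           network_fraction = 0.5,
                           align_network_events = TRUE,
                           amplitude_uV = 40,
                           noise_sd_uV = 5) {
  if (n_electrodes < 1L) stop_invalid("`n_electrodes` must be >= 1")
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(rate_hz, "rate_hz")
  check_nonnegative(background_rate_hz, "background_rate_hz")
  check_nonnegative(burst_rate_per_min, "burst_rate_per_min")
  check_nonnegative(intra_burst_rate_hz, "intra_burst_rate_hz")
  check_positive_scalar(burst_duration_s, "burst_duration_s")
  check_nonnegative(network_rate_per_min, "network_rate_per_min")
  check_nonnegative(network_event_rate_hz, "network_event_rate_hz")
  check_positive_scalar(network_event_duration_s, "network_event_duration_s")
  check_fraction(network_fraction, "network_fraction")
  check_nonnegative(amplitude_uV, "amplitude_uV")
  check_nonnegative(noise_sd_uV, "noise_sd_uV")
  structure(
    list(
      seed = as.integer(seed),
      n_electrodes = as.integer(n_electrodes),
      duration_s = duration_s,
      rate_hz = rate_hz,
      background_rate_hz = background_rate_hz,
      burst_rate_per_min = burst_rate_per_min,
      intra_burst_rate_hz = intra_burst_rate_hz,
      burst_duration_s = burst_duration_s,
      network_rate_per_min = network_rate_per_min,
      network_event_rate_hz = network_event_rate_hz,
      network_event_duration_s = network_event_duration_s,
      network_fraction = network_fraction,
      align_network_events = isTRUE(align_network_events),
      amplitude_uV = amplitude_uV,
      noise_sd_uV = noise_sd_uV
    ),
    class = "mea_sim_config"
  )
}

# Poisson event times on [0, duration). Returns a sorted numeric vector.
poisson_times <- function(rate_hz, duration_s) {
  n <- rpois(1L, rate_hz * duration_s)
  sort(runif(n, 0, duration_s))
}

#' Simulate ground-truth spike trains for one MEA well
#'
#' Draws per-electrode spike trains as the superposition of a homogeneous
#' Poisson background, burst epochs (a two-state process: epoch starts are
#' Poisson, spikes inside an epoch fire at `intra_burst_rate_hz`), and
#' well-wide network events implanted simultaneously on a fixed electrode
#' subset. This is the ground truth underlying [simulate_mea_recording()];
#' use it directly when voltage-level realism is not needed.
#'
#' @param config A [mea_sim_config()].
#' @return A list of class `spike_sim` with elements `spikes` (tibble:
#'   `electrode`, `time`, `source`), `network_events` (tibble: `time`),
#'   `network_electrodes` (integer vector), `duration_s`, `n_electrodes`,
#'   and `config`.
#' @export
simulate_spike_trains <- function(config) {
  stopifnot(inherits(config, "mea_sim_config"))
  with_seed(config$seed, {
    dur <- config$duration_s
    n_el <- config$n_electrodes

    per_electrode <- purrr::map(seq_len(n_el), function(el) {
      bg <- poisson_times(config$background_rate_hz, dur)
      epoch_starts <- poisson_times(config$burst_rate_per_min / 60, dur)
      burst <- purrr::map(epoch_starts, function(t0) {
        t0 + sort(runif(
          rpois(1L, config$intra_burst_rate_hz * config$burst_duration_s),
          0, config$burst_duration_s
        ))
      })
      burst <- unlist(burst, use.names = FALSE)
      if (is.null(burst)) burst <- numeric(0)
      tibble(
        electrode = el,
        time = c(bg, burst),
        source = rep(c("background", "burst"), c(length(bg), length(burst)))
      )
    })

    net_times <- poisson_times(config$network_rate_per_min / 60, dur)
    if (config$align_network_events && length(net_times)) {
      net_times <- unique(floor(net_times / 0.1) * 0.1)
      net_times <- net_times[net_times + config$network_event_duration_s <= dur]
    }
    n_part <- ceiling(config$network_fraction * n_el)
    net_electrodes <- seq_len(n_part)
    net_spikes <- purrr::map(net_times, function(t0) {
      purrr::map(net_electrodes, function(el) {
        k <- rpois(1L, config$network_event_rate_hz * config$network_event_duration_s)
        tibble(
          electrode = el,
          time = t0 + sort(runif(k, 0, config$network_event_duration_s)),
          source = "network"
        )
      }) %>% bind_rows()
    }) %>% bind_rows()

    spikes <- bind_rows(bind_rows(per_electrode), net_spikes) %>%
      filter(.data$time >= 0, .data$time < dur) %>%
      distinct(.data$electrode, .data$time, .keep_all = TRUE) %>%
      arrange(.data$electrode, .data$time)

    structure(
      list(
        spikes = spikes,
        network_events = tibble(time = net_times),
        network_electrodes = net_electrodes,
        duration_s = dur,
        n_electrodes = n_el,
        config = config
      ),
      class = "spike_sim"
    )
  })
}

# Biphasic spike template (one sine cycle, 1 ms wide), scaled so that the
# post-filter peak equals `amplitude` for the supplied band-pass design.
spike_template <- function(rate_hz, amplitude, filt = spike_band_filter(rate_hz)) {
  n <- max(3L, round(rate_hz * 1e-3))
  shape <- sin(2 * pi * seq(0, 1, length.out = n))
  pad <- 6L * n
  probe <- c(rep(0, pad), shape, rep(0, pad))
  peak_post <- max(signal::filtfilt(filt, probe))
  if (peak_post <= 0) stop_invalid("degenerate spike template")
  shape * amplitude / peak_post
}

#' Simulate a raw MEA voltage recording
#'
#' Synthesises an extracellular voltage matrix as Gaussian electrode noise
#' plus a biphasic 1 ms spike waveform placed at each ground-truth spike
#' time from [simulate_spike_trains()]. The waveform is pre-calibrated so
#' its peak after the default 200-3000 Hz band-pass equals
#' `config$amplitude_uV`, making detectability (SNR) exact in the
#' detector's domain.
#'
#' @param config A [mea_sim_config()].
#' @return A list of class `mea_recording` with elements `voltage`
#'   (electrodes x samples matrix, uV), `rate_hz`, `duration_s`, plus the
#'   ground truth under `truth` (the `spike_sim` object).
#' @export
simulate_mea_recording <- function(config) {
  stopifnot(inherits(config, "mea_sim_config"))
  truth <- simulate_spike_trains(config)
  n_samp <- round(config$duration_s * config$rate_hz)
  filt <- spike_band_filter(config$rate_hz)
  tmpl <- spike_template(config$rate_hz, config$amplitude_uV, filt)
  n_t <- length(tmpl)
  peak_off <- which.max(tmpl) - 1L # samples before the raw peak

  with_seed(config$seed + 1L, {
    v <- matrix(
      rnorm(config$n_electrodes * n_samp, sd = config$noise_sd_uV),
      nrow = config$n_electrodes
    )
    for (el in seq_len(config$n_electrodes)) {
      times <- truth$spikes$time[truth$spikes$electrode == el]
      idx_peak <- round(times * config$rate_hz) + 1L
      for (ip in idx_peak) {
        i0 <- ip - peak_off
        j <- seq(i0, i0 + n_t - 1L)
        keep <- j >= 1L & j <= n_samp
        v[el, j[keep]] <- v[el, j[keep]] + tmpl[keep]
      }
    }
    structure(
      list(
        voltage = v,
        rate_hz = config$rate_hz,
        duration_s = config$duration_s,
        truth = truth
      ),
      class = "mea_recording"
    )
  })
}
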