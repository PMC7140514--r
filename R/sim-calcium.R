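#' Configuration for simulated GCaMP ROI traces
#'
#' Parameters for [simulate_calcium_traces()]. Defaults emulate a
#' wide-field GCaMP movie of 5000 frames at ~31.5 ms/frame: a fraction of
#' ROIs carry calcium events (kernel-convolved event trains), all traces
#' decay linearly from photobleaching, and Gaussian read noise is added.
#'
#' @param seed Integer RNG seed.
#' @param n_rois Number of ROIs.
#' @param n_frames Frames per trace (>= 2).
#' @param frame_interval_s Frame interval (s).
#' @param active_fraction Fraction of ROIs bearing events (Bernoulli per
#'   ROI); silent ROIs have zero events.
#' @param shared_fraction Fraction of the active ROIs that share one
#'   common (network) event train instead of independent trains; used for
#'   synchrony tests.
#' @param event_rate_hz Event rate per active ROI (Hz).
#' @param rise_s,decay_s Double-exponential kernel time constants (s).
#' @param amplitude Event peak amplitude in raw fluorescence units (so the
#'   dF/F peak of one event is `amplitude / f0`).
#' @param f0 Baseline fluorescence at frame 0 (a.u.); must be >= 0.
#' @param bleach_per_frame Linear photobleach slope (a.u. lost per frame).
#' @param bleach_model `"linear"` (default, matches the first-minus-last
#'   frame correction) or `"exponential"` for robustness tests.
#' @param noise_sd Gaussian noise SD (a.u.). The default keeps trace
#'   noise well below the 0.01 dF/F spike-positivity threshold (the
#'   full-trace noise range stays under 1% of F0), the regime implied by
#'   that threshold.
#' @param mcherry_fraction Fraction of ROIs flagged mCherry-positive.
#' @return A list of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(seed = 1L,
                               n_rois = 30L,
                               n_frames = 5000L,
                               frame_interval_s = 0.0315,
                               active_fraction = 0.4,
                               shared_fraction = 0,
                               event_rate_hz = 0.05,
                               rise_s = 0.2,
                               decay_s = 1.5,
                               amplitude = 30,
                               f0 = 100,
                               bleach_per_frame = 0.002,
                               bleach_model = c("linear", "exponential"),
                               noise_sd = 0.1,
                               mcherry_fraction = 0.5) {
  if (n_frames < 2L) stop_invalid("`n_frames` must be >= 2")
  if (f0 < 0) stop_invalid("`f0` must be >= 0")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_fraction(active_fraction, "active_fraction")
  check_fraction(shared_fraction, "shared_fraction")
  check_fraction(mcherry_fraction, "mcherry_fraction")
  check_nonnegative(event_rate_hz, "event_rate_hz")
  check_positive_scalar(rise_s, "rise_s")
  check_positive_scalar(decay_s, "decay_s")
  check_nonnegative(amplitude, "amplitude")
  check_nonnegative(noise_sd, "noise_sd")
  check_nonnegative(bleach_per_frame, "bleach_per_frame")
  structure(
    list(
      seed = as.integer(seed), n_rois = as.integer(n_rois),
      n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
      active_fraction = active_fraction, shared_fraction = shared_fraction,
      event_rate_hz = event_rate_hz, rise_s = rise_s, decay_s = decay_s,
      amplitude = amplitude, f0 = f0, bleach_per_frame = bleach_per_frame,
      bleach_model = match.arg(bleach_model), noise_sd = noise_sd,
      mcherry_fraction = mcherry_fraction
    ),
    class = "calcium_sim_config"
  )
}

#' Calcium event kernel
#'
#' Double-exponential transient `(1 - exp(-t/rise)) * exp(-t/decay)`
#' normalised to unit peak.
#'
#' @param t Times (s), non-negative.
#' @param rise_s,decay_s Time constants (s).
#' @return Kernel values; zero for `t < 0`.
#' @export
calcium_kernel <- function(t, rise_s = 0.2, decay_s = 1.5) {
  k <- ifelse(t < 0, 0, (1 - exp(-t / rise_s)) * exp(-t / decay_s))
  t_peak <- rise_s * log(1 + decay_s / rise_s)
  peak <- (1 - exp(-t_peak / rise_s)) * exp(-t_peak / decay_s)
  k / peak
}

#' Simulate GCaMP ROI traces with ground truth
#'
#' Each raw trace is `f0 + sum(events (x) kernel) - bleach + noise`.
#' A configurable subset of the active ROIs shares one common event train
#' (for synchrony tests); silent ROIs carry no events.
#'
#' @param config A [calcium_sim_config()].
#' @return A list of class `calcium_sim`: `traces` (long tibble `roi`,
#'   `frame` (0-based), `time`, `f`), `truth` (per-ROI tibble with
#'   `active`, `shared`, `mcherry_pos`, `n_events`, `event_times`
#'   list-column, `bleach_per_frame`), `frame_interval_s`, `config`.
#' @export
simulate_calcium_traces <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  with_seed(config$seed, {
    n <- config$n_rois
    nf <- config$n_frames
    dt <- config$frame_interval_s
    t_frames <- (seq_len(nf) - 1) * dt
    dur <- nf * dt

    active <- runif(n) < config$active_fraction
    # Shared ROIs: the first ceiling(shared_fraction * n_active) active ROIs.
    idx_active <- which(active)
    n_shared <- ceiling(config$shared_fraction * length(idx_active))
    shared <- rep(FALSE, n)
    if (n_shared > 0) shared[idx_active[seq_len(n_shared)]] <- TRUE
    mch <- runif(n) < config$mcherry_fraction

    # Event-bearing ROIs carry at least one transient, and events stay a
    # few frames clear of the trace end so every event has a visible onset.
    event_window <- max(dur - 5 * dt, dt)
    draw_events <- function() {
      k <- max(1L, rpois(1L, config$event_rate_hz * event_window))
      sort(runif(k, 0, event_window))
    }
    shared_events <- draw_events()

    truth <- tibble(
      roi = seq_len(n),
      active = active,
      shared = shared,
      mcherry_pos = mch,
      event_times = purrr::map(seq_len(n), function(i) {
        if (!active[i]) {
          numeric(0)
        } else if (shared[i]) {
          shared_events
        } else {
          draw_events()
        }
      }),
      bleach_per_frame = config$bleach_per_frame
    ) %>%
      mutate(n_events = lengths(.data$event_times))

    traces <- purrr::map(seq_len(n), function(i) {
      f <- rep(config$f0, nf)
      for (te in truth$event_times[[i]]) {
        f <- f + config$amplitude *
          calcium_kernel(t_frames - te, config$rise_s, config$decay_s)
      }
      frames0 <- seq_len(nf) - 1
      f <- switch(config$bleach_model,
        linear = f - config$bleach_per_frame * frames0,
        exponential = f * exp(-config$bleach_per_frame / max(config$f0, 1) * frames0)
      )
      if (config$noise_sd > 0) f <- f + rnorm(nf, sd = config$noise_sd)
      tibble(roi = i, frame = frames0, time = t_frames, f = f)
    }) %>% bind_rows()

    structure(
      list(
        traces = traces, truth = truth,
        frame_interval_s = dt, config = config
      ),
      class = "calcium_sim"
    )
  })
}
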