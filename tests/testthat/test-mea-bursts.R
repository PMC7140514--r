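test_that("a burst needs strictly more than 5 spikes in a 100 ms window", {
  spikes <- dplyr::bind_rows(
    tibble::tibble(electrode = 1L, time = seq(0.001, 0.099, length.out = 6)),
    tibble::tibble(electrode = 1L, time = seq(0.201, 0.299, length.out = 5))
  )
  b <- detect_bursts(spikes, 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$window_start, 0)
  expect_equal(b$n_spikes, 6L)
})

test_that("burst calls match the brute-force bin-count oracle on random trains", {
  set.seed(77)
  for (i in 1:300) {
    dur <- sample(c(1, 3, 10), 1)
    n <- sample(0:200, 1)
    times <- random_spike_train(n, dur)
    spikes <- tibble::tibble(electrode = 1L, time = times)
    expect_identical(
      nrow(detect_bursts(spikes, dur)),
      as.integer(oracle_burst_count(times, dur))
    )
  }
})

test_that("a 5 Hz Poisson train almost never bursts", {
  set.seed(123)
  spikes <- tibble::tibble(electrode = 1L, time = random_spike_train(300, 60))
  # Pr(Poisson(0.5) > 5) ~ 1.4e-5 per bin; 600 bins -> expected ~0.01 bursts
  expect_lte(nrow(detect_bursts(spikes, 60)), 1L)
})

test_that("network bursts need > 50 spikes on >= ceiling(35% of electrodes)", {
  bin_train <- function(el, n) {
    tibble::tibble(electrode = el, time = seq(0.3001, 0.3999, length.out = n))
  }
  # 6 of 16 electrodes (37.5%) at 51 spikes: one network burst
  s6 <- dplyr::bind_rows(lapply(1:6, bin_train, n = 51))
  expect_equal(nrow(detect_network_bursts(s6, 1, 16)), 1L)
  # 5 of 16 (31.25%): none
  s5 <- dplyr::bind_rows(lapply(1:5, bin_train, n = 51))
  expect_equal(nrow(detect_network_bursts(s5, 1, 16)), 0L)
  # exactly 50 spikes never counts as participating
  s50 <- dplyr::bind_rows(lapply(1:16, bin_train, n = 50))
  expect_equal(nrow(detect_network_bursts(s50, 1, 16)), 0L)
})

test_that("network-burst calls match the explicit per-bin oracle", {
  set.seed(99)
  for (i in 1:30) {
    n_el <- sample(c(8, 16), 1)
    dur <- 2
    spikes <- dplyr::bind_rows(lapply(seq_len(n_el), function(el) {
      tibble::tibble(
        electrode = el,
        time = random_spike_train(sample(c(0, 30, 400), 1), dur)
      )
    }))
    expect_identical(
      nrow(detect_network_bursts(spikes, dur, n_el)),
      as.integer(oracle_network_bursts(spikes, dur, n_el))
    )
  }
})

test_that("implanted network events are recovered exactly at zero background", {
  cfg <- mea_sim_config(
    seed = 21, n_electrodes = 16, duration_s = 180,
    background_rate_hz = 0, burst_rate_per_min = 0,
    network_rate_per_min = 1, network_event_rate_hz = 1000,
    network_fraction = 0.5
  )
  sim <- simulate_spike_trains(cfg)
  nb <- detect_network_bursts(sim$spikes, sim$duration_s, sim$n_electrodes)
  expect_equal(nrow(nb), nrow(sim$network_events))
  expect_equal(sort(nb$window_start), sort(sim$network_events$time), tolerance = 1e-9)
})

test_that("burst and network-burst counts are monotone in their thresholds", {
  set.seed(42)
  spikes <- dplyr::bind_rows(lapply(1:8, function(el) {
    tibble::tibble(electrode = el, time = random_spike_train(800, 10))
  }))
  b_counts <- vapply(
    c(8, 5, 3, 1),
    function(ms) nrow(detect_bursts(spikes, 10, min_spikes = ms)), integer(1)
  )
  expect_true(all(diff(b_counts) >= 0))
  nb_counts <- vapply(
    c(0.9, 0.5, 0.35, 0.1),
    function(pf) {
      nrow(detect_network_bursts(spikes, 10, 8,
        min_spikes = 5,
        participation_fraction = pf
      ))
    }, integer(1)
  )
  expect_true(all(diff(nb_counts) >= 0))
})

test_that("well metrics assemble the five readouts and flag silent wells", {
  silent <- compute_well_metrics(
    tibble::tibble(electrode = integer(), time = numeric()), 300, 16
  )
  expect_equal(silent$n_active, 0L)
  expect_true(is.na(silent$mean_firing_rate_hz))
  expect_equal(silent$n_bursts, 0L)
  expect_equal(silent$n_bursting_electrodes, 0L)
  expect_equal(silent$network_burst_per_min, 0)

  cfg <- mea_sim_config(
    seed = 33, n_electrodes = 16, duration_s = 180,
    background_rate_hz = 0, burst_rate_per_min = 0,
    network_rate_per_min = 1, network_event_rate_hz = 1000
  )
  sim <- simulate_spike_trains(cfg)
  wm <- compute_well_metrics(sim$spikes, 180, 16)
  expect_equal(wm$network_burst_per_min, nrow(sim$network_events) / 3)
})

test_that("well metrics agree between voltage-level and ground-truth spikes", {
  cfg <- mea_sim_config(
    seed = 13, n_electrodes = 4, duration_s = 20,
    background_rate_hz = 4, burst_rate_per_min = 2,
    network_rate_per_min = 0, noise_sd_uV = 0, amplitude_uV = 50
  )
  rec <- simulate_mea_recording(cfg)
  sp <- detect_spikes(bandpass_filter(rec), sigma = rep(1, 4))
  # ground truth collapsed to detector resolution: spikes closer than the
  # 1 ms dead time produce one superposed waveform and one detection
  dead <- round(1e-3 * cfg$rate_hz)
  truth_res <- rec$truth$spikes |>
    dplyr::group_by(electrode) |>
    dplyr::group_modify(function(df, key) {
      idx <- round(sort(df$time) * cfg$rate_hz)
      keep <- logical(length(idx))
      last <- -Inf
      for (i in seq_along(idx)) {
        if (idx[i] - last >= dead) {
          keep[i] <- TRUE
          last <- idx[i]
        }
      }
      tibble::tibble(time = sort(df$time)[keep])
    }) |>
    dplyr::ungroup()
  wm_v <- compute_well_metrics(sp, 20, 4)
  wm_t <- compute_well_metrics(truth_res, 20, 4)
  expect_equal(wm_v$n_active, wm_t$n_active)
  expect_equal(wm_v$mean_firing_rate_hz, wm_t$mean_firing_rate_hz,
    tolerance = 0.01
  )
  expect_equal(wm_v$n_bursts, wm_t$n_bursts)
})

test_that("raster export writes one row per spike with burst flags", {
  spikes <- tibble::tibble(
    electrode = c(1L, 1L, 2L),
    time = c(0.05, 0.5, 0.05)
  )
  bursts <- tibble::tibble(
    electrode = 1L, window_start = 0, window_end = 0.1, n_spikes = 6L
  )
  nb <- tibble::tibble(
    window_start = 0, window_end = 0.1,
    n_participating = 2L, participants = list(1:2)
  )
  tab <- export_raster(spikes, bursts, nb)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$in_burst, c(TRUE, FALSE, FALSE))
  expect_equal(tab$in_network_burst, c(TRUE, FALSE, TRUE))

  path <- withr::local_tempfile(fileext = ".csv")
  export_raster(spikes, bursts, nb, path = path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 3L)

  empty <- export_raster(spikes[0, ], bursts[0, ], nb[0, ])
  expect_equal(nrow(empty), 0L)
  expect_s3_class(plot_raster(spikes, bursts, nb), "ggplot")
})
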