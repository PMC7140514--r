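test_that("bleach correction flattens a pure linear decay and is idempotent on flat traces", {
  f <- 100 - 0.01 * (0:999)
  out <- bleach_correct(make_trace(f))
  expect_equal(out$f, rep(100, 1000))

  flat <- make_trace(rep(50, 200))
  expect_equal(bleach_correct(flat)$f, flat$f)

  expect_error(bleach_correct(make_trace(5)), class = "neurophenor_invalid_config")
})

test_that("bleach correction recovers event kernels on simulated traces", {
  cfg <- calcium_sim_config(
    seed = 4, n_rois = 6, n_frames = 2000,
    active_fraction = 1, noise_sd = 0, bleach_per_frame = 0.01
  )
  sim <- simulate_calcium_traces(cfg)
  corrected <- bleach_correct(sim$traces)
  # closed form: the first-to-last anchored ramp removes the true linear
  # bleach exactly but adds (K(0) - K(N)) * frame/N, where K is the event
  # component
  t_frames <- (0:1999) * cfg$frame_interval_s
  for (i in sim$truth$roi) {
    kern <- rep(0, 2000)
    for (te in sim$truth$event_times[[i]]) {
      kern <- kern + cfg$amplitude * calcium_kernel(t_frames - te)
    }
    expected <- cfg$f0 + kern + (kern[1] - kern[2000]) * (0:1999) / 1999
    got <- corrected$f[corrected$roi == i]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("dF/F is (F - F0)/F0 with F0 at frame zero and is scale invariant", {
  f <- c(100, 120, 150, 90)
  d <- compute_dff(make_trace(f))
  expect_equal(d$dff, (f - 100) / 100)
  expect_equal(d$f0[1], 100)
  expect_equal(compute_dff(make_trace(3 * f))$dff, d$dff)

  flat <- compute_dff(make_trace(rep(7, 10)))
  expect_true(all(flat$dff == 0))

  bad <- compute_dff(make_trace(c(0, 5, 10)))
  expect_false(any(bad$valid))
  expect_true(all(is.na(bad$dff)))
})

test_that("dFmax modes report range (default) or max of the dF/F trace", {
  f0 <- 100
  f <- f0 * (1 + c(0, -0.02, 0.30, 0.1))
  d <- compute_dff(make_trace(f))
  expect_equal(compute_dfmax(d)$dfmax, 0.32)
  expect_equal(compute_dfmax(d, mode = "max")$dfmax, 0.30)
  expect_equal(compute_dfmax(compute_dff(make_trace(rep(5, 50))))$dfmax, 0)
})

test_that("a single event of known kernel peak yields dFmax equal to the peak", {
  nf <- 800
  dt <- 0.0315
  t_frames <- (0:(nf - 1)) * dt
  t_peak <- 0.2 * log(1 + 1.5 / 0.2)
  te <- t_frames[100] - t_peak # one frame lands exactly on the kernel peak
  f <- 100 + 30 * calcium_kernel(t_frames - te)
  d <- compute_dfmax(compute_dff(make_trace(f)))
  expect_equal(d$dfmax, 0.3, tolerance = 1e-9)
})

test_that("bleaching alone never creates calcium activity", {
  f <- 200 - 0.05 * (0:4999)
  d <- make_trace(f) |>
    bleach_correct() |>
    compute_dff() |>
    compute_dfmax()
  expect_lt(d$dfmax, 1e-9)
})

test_that("spike positivity is strict at dFmax > 0.01", {
  flags <- classify_spike_positive(c(0.005, 0.009, 0.010, 0.011, 0.020))
  expect_equal(sum(flags$positive), 2L)
  expect_equal(max(flags$dfmax[!flags$positive]), 0.010)
  expect_equal(attr(flags, "fraction"), 0.4)

  none <- classify_spike_positive(tibble::tibble(
    roi = 1:2, dfmax = c(NA_real_, NA_real_), valid = c(FALSE, FALSE)
  ))
  expect_true(is.na(attr(none, "fraction")))
})

test_that("event-bearing ROI fraction is recovered within binomial 3 sigma", {
  cfg <- calcium_sim_config(seed = 15, n_rois = 200, n_frames = 1200,
    active_fraction = 0.4
  )
  sim <- simulate_calcium_traces(cfg)
  dfm <- sim$traces |>
    bleach_correct() |>
    compute_dff() |>
    compute_dfmax()
  flags <- classify_spike_positive(dfm)
  expect_equal(flags$positive, sim$truth$active)
  se <- sqrt(0.4 * 0.6 / 200)
  expect_lt(abs(attr(flags, "fraction") - 0.4), 3 * se)
})

test_that("silent zero-noise simulations yield zero positive fraction", {
  cfg <- calcium_sim_config(seed = 2, n_rois = 20, n_frames = 500,
    active_fraction = 0, noise_sd = 0
  )
  dfm <- simulate_calcium_traces(cfg)$traces |>
    bleach_correct() |>
    compute_dff() |>
    compute_dfmax()
  expect_equal(attr(classify_spike_positive(dfm), "fraction"), 0)
})

test_that("synchrony index separates shared from independent event trains", {
  d_ident <- dplyr::bind_rows(
    make_trace(100 + sin(1:2000), roi = 1L),
    make_trace(100 + sin(1:2000), roi = 2L)
  )
  expect_equal(synchrony_index(compute_dff(d_ident), rois = 1:2), 1)

  set.seed(6)
  d_noise <- dplyr::bind_rows(
    make_trace(100 + rnorm(5000), roi = 1L),
    make_trace(100 + rnorm(5000), roi = 2L)
  )
  expect_lt(abs(synchrony_index(compute_dff(d_noise), rois = 1:2)), 0.05)

  sync_of <- function(shared_fraction) {
    cfg <- calcium_sim_config(seed = 7, n_rois = 16, n_frames = 1500,
      active_fraction = 0.8, shared_fraction = shared_fraction,
      event_rate_hz = 0.1
    )
    dff <- simulate_calcium_traces(cfg)$traces |>
      bleach_correct() |>
      compute_dff()
    synchrony_index(dff)
  }
  expect_gt(sync_of(1), sync_of(0))
  expect_true(is.na(synchrony_index(
    compute_dff(make_trace(rep(1, 10))),
    rois = 1L
  )))
})

test_that("shared-event ROIs carry identical ground-truth event times", {
  cfg <- calcium_sim_config(seed = 3, n_rois = 10, active_fraction = 1,
    shared_fraction = 1, n_frames = 300
  )
  tr <- simulate_calcium_traces(cfg)$truth
  expect_true(all(vapply(
    tr$event_times,
    function(e) identical(e, tr$event_times[[1]]), logical(1)
  )))
})

test_that("mCherry-positive fraction among traced nuclei matches ground truth", {
  cfg <- field_sim_config(seed = 19, width_px = 700, height_px = 700,
    n_cells = 70, pyknotic_fraction = 0, n_neurites = 0,
    n_syni = 0, n_psd95 = 0, p_mcherry = 0.3
  )
  fs <- render_synthetic_field(cfg)
  nuc <- segment_nuclei(fs$stack)
  frac <- mcherry_positive_fraction(fs$stack, nuc)
  truth <- mean(fs$truth$cells$mcherry)
  expect_lt(abs(frac - truth), 3 * sqrt(0.3 * 0.7 / 70))

  all_neg <- field_sim_config(seed = 20, width_px = 400, height_px = 400,
    n_cells = 15, pyknotic_fraction = 0, n_neurites = 0, n_syni = 0,
    n_psd95 = 0, p_mcherry = 0
  )
  fs0 <- render_synthetic_field(all_neg)
  expect_equal(
    mcherry_positive_fraction(fs0$stack, segment_nuclei(fs0$stack)), 0
  )
  all_pos <- field_sim_config(seed = 21, width_px = 400, height_px = 400,
    n_cells = 15, pyknotic_fraction = 0, n_neurites = 0, n_syni = 0,
    n_psd95 = 0, p_mcherry = 1
  )
  fs1 <- render_synthetic_field(all_pos)
  expect_equal(
    mcherry_positive_fraction(fs1$stack, segment_nuclei(fs1$stack)), 1
  )
})
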