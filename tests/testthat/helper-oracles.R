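# Independent brute-force oracles used to cross-check the analysis code.

# Burst oracle: histogram counts in fixed 100 ms bins, strict threshold.
oracle_burst_count <- function(times, duration_s, window_s = 0.1, min_spikes = 5) {
  if (length(times) == 0) {
    return(0L)
  }
  breaks <- seq(0, ceiling(duration_s / window_s) * window_s, by = window_s)
  counts <- hist(times, breaks = breaks, plot = FALSE, right = FALSE)$counts
  sum(counts > min_spikes)
}

# Network-burst oracle: loop over every bin and electrode explicitly.
oracle_network_bursts <- function(spikes, duration_s, n_electrodes,
                                  window_s = 0.1, min_spikes = 50,
                                  fraction = 0.35) {
  n_bins <- ceiling(duration_s / window_s)
  need <- ceiling(fraction * n_electrodes)
  hits <- 0L
  for (b in seq_len(n_bins) - 1L) {
    lo <- b * window_s
    hi <- lo + window_s
    participating <- 0L
    for (el in seq_len(n_electrodes)) {
      cnt <- sum(spikes$electrode == el & spikes$time >= lo & spikes$time < hi)
      if (cnt > min_spikes) participating <- participating + 1L
    }
    if (participating >= need) hits <- hits + 1L
  }
  hits
}

random_spike_train <- function(n, duration_s) {
  sort(runif(n, 0, duration_s))
}

# Spike-time matching (greedy, +/- tol) returning recall and precision.
match_spikes <- function(detected, truth, tol = 1e-3) {
  tp <- 0L
  for (el in unique(truth$electrode)) {
    dt <- detected$time[detected$electrode == el]
    tt <- truth$time[truth$electrode == el]
    used <- rep(FALSE, length(dt))
    for (t in tt) {
      j <- which(!used & abs(dt - t) <= tol)
      if (length(j)) {
        used[j[1L]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(recall = tp / nrow(truth), precision = tp / nrow(detected))
}

# Direct trace builder for calcium tests.
make_trace <- function(f, roi = 1L) {
  tibble::tibble(roi = roi, frame = seq_along(f) - 1L, f = f)
}
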