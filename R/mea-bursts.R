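#' Detect single-electrode bursts
#'
#' The recording is tiled into fixed, non-overlapping windows (default
#' 100 ms); every window in which an electrode fires strictly more than
#' `min_spikes` spikes (default 5) counts as one burst. Adjacent
#' qualifying windows are counted separately (count semantics). A
#' sliding-window variant is available but non-default.
#'
#' @param spikes Spike tibble (`electrode`, `time`).
#' @param duration_s Recording duration (s).
#' @param window_ms Analysis window length (ms).
#' @param min_spikes Burst threshold (spikes per window, strict `>`).
#' @param mode `"fixed"` (default) or `"sliding"` (windows anchored at
#'   each spike; overlapping qualifying windows merged into one call).
#' @return Tibble: `electrode`, `window_start`, `window_end` (s),
#'   `n_spikes`.
#' @export
detect_bursts <- function(spikes, duration_s, window_ms = 100, min_spikes = 5,
                          mode = c("fixed", "sliding")) {
  mode <- match.arg(mode)
  check_positive_scalar(duration_s, "duration_s")
  w <- window_ms / 1000
  empty <- tibble(
    electrode = integer(), window_start = numeric(),
    window_end = numeric(), n_spikes = integer()
  )
  if (nrow(spikes) == 0L) {
    return(empty)
  }
  if (mode == "fixed") {
    spikes %>%
      mutate(bin = floor(.data$time / w)) %>%
      count(.data$electrode, .data$bin, name = "n_spikes") %>%
      filter(.data$n_spikes > min_spikes) %>%
      mutate(
        window_start = .data$bin * w,
        window_end = (.data$bin + 1) * w
      ) %>%
      select("electrode", "window_start", "window_end", "n_spikes") %>%
      arrange(.data$electrode, .data$window_start)
  } else {
    out <- spikes %>%
      group_by(.data$electrode) %>%
      dplyr::group_modify(function(df, key) {
        tt <- sort(df$time)
        n_in <- vapply(tt, function(t0) sum(tt >= t0 & tt < t0 + w), integer(1))
        hit <- which(n_in > min_spikes)
        if (!length(hit)) {
          return(tibble(
            window_start = numeric(), window_end = numeric(),
            n_spikes = integer()
          ))
        }
        starts <- tt[hit]
        ends <- starts + w
        merged_s <- starts[1]
        merged_e <- ends[1]
        ms <- numeric(0)
        me <- numeric(0)
        for (i in seq_along(starts)[-1]) {
          if (starts[i] <= merged_e) {
            merged_e <- max(merged_e, ends[i])
          } else {
            ms <- c(ms, merged_s)
            me <- c(me, merged_e)
            merged_s <- starts[i]
            merged_e <- ends[i]
          }
        }
        ms <- c(ms, merged_s)
        me <- c(me, merged_e)
        tibble(
          window_start = ms, window_end = me,
          n_spikes = vapply(
            seq_along(ms),
            function(i) sum(tt >= ms[i] & tt < me[i]), integer(1)
          )
        )
      }) %>%
      ungroup()
    if (nrow(out) == 0L) empty else out
  }
}

#' Detect network bursts
#'
#' For each fixed window (default 100 ms), an electrode participates when
#' it fires strictly more than `min_spikes` spikes (default 50) inside
#' that window. The window is a network burst when at least
#' `ceiling(participation_fraction * n_electrodes)` electrodes participate
#' (default fraction 0.35).
#'
#' @param spikes Spike tibble (`electrode`, `time`).
#' @param duration_s Recording duration (s).
#' @param n_electrodes Electrodes in the well.
#' @param window_ms Analysis window (ms).
#' @param min_spikes Participation threshold (spikes per window, strict `>`).
#' @param participation_fraction Fraction of well electrodes that must
#'   participate simultaneously.
#' @return Tibble: `window_start`, `window_end` (s), `n_participating`,
#'   and `participants` (list-column of electrode ids). The network burst
#'   frequency is `nrow(result) / (duration_s / 60)` per minute.
#' @export
detect_network_bursts <- function(spikes, duration_s, n_electrodes,
                                  window_ms = 100, min_spikes = 50,
                                  participation_fraction = 0.35) {
  check_positive_scalar(duration_s, "duration_s")
  check_fraction(participation_fraction, "participation_fraction")
  w <- window_ms / 1000
  need <- ceiling(participation_fraction * n_electrodes)
  empty <- tibble(
    window_start = numeric(), window_end = numeric(),
    n_participating = integer(), participants = list()
  )
  if (nrow(spikes) == 0L) {
    return(empty)
  }
  per_bin <- spikes %>%
    mutate(bin = floor(.data$time / w)) %>%
    count(.data$bin, .data$electrode, name = "n_spikes") %>%
    filter(.data$n_spikes > min_spikes)
  if (nrow(per_bin) == 0L) {
    return(empty)
  }
  per_bin %>%
    group_by(.data$bin) %>%
    summarise(
      n_participating = dplyr::n(),
      participants = list(sort(.data$electrode)),
      .groups = "drop"
    ) %>%
    filter(.data$n_participating >= need) %>%
    mutate(
      window_start = .data$bin * w,
      window_end = (.data$bin + 1) * w
    ) %>%
    select("window_start", "window_end", "n_participating", "participants") %>%
    arrange(.data$window_start)
}

#' Assemble per-well MEA metrics
#'
#' Computes the five headline well metrics: number of active electrodes,
#' mean firing rate per active electrode (spikes/s; NA when no electrode
#' is active), burst count, number of bursting electrodes, and network
#' burst frequency (per minute).
#'
#' @param spikes Spike tibble (`electrode`, `time`).
#' @param duration_s Recording duration (s).
#' @param n_electrodes Electrodes in the well.
#' @param min_rate_per_min Active-electrode threshold (spikes/min).
#' @param burst_window_ms,burst_min_spikes Single-electrode burst rule.
#' @param net_window_ms,net_min_spikes,participation_fraction Network
#'   burst rule.
#' @return One-row tibble: `n_active`, `mean_firing_rate_hz`, `n_bursts`,
#'   `n_bursting_electrodes`, `network_burst_per_min`.
#' @export
compute_well_metrics <- function(spikes, duration_s, n_electrodes,
                                 min_rate_per_min = 5,
                                 burst_window_ms = 100, burst_min_spikes = 5,
                                 net_window_ms = 100, net_min_spikes = 50,
                                 participation_fraction = 0.35) {
  act <- classify_active_electrodes(spikes, duration_s, n_electrodes,
    min_rate_per_min = min_rate_per_min
  )
  bursts <- detect_bursts(spikes, duration_s,
    window_ms = burst_window_ms,
    min_spikes = burst_min_spikes
  )
  nb <- detect_network_bursts(spikes, duration_s, n_electrodes,
    window_ms = net_window_ms, min_spikes = net_min_spikes,
    participation_fraction = participation_fraction
  )
  tibble(
    n_active = sum(act$active),
    mean_firing_rate_hz = mean_firing_rate(spikes, duration_s, act),
    n_bursts = nrow(bursts),
    n_bursting_electrodes = dplyr::n_distinct(bursts$electrode),
    network_burst_per_min = nrow(nb) / (duration_s / 60)
  )
}

#' Tidy raster table and export
#'
#' Builds a tidy per-spike table flagging whether each spike falls inside
#' a single-electrode burst window and/or a network-burst window, writes
#' it to CSV, and optionally writes the raster figure.
#'
#' @param spikes Spike tibble (`electrode`, `time`).
#' @param bursts Output of [detect_bursts()].
#' @param net_bursts Output of [detect_network_bursts()].
#' @param path CSV output path, or `NULL` to skip writing.
#' @param plot_path Optional figure path (extension chooses the device,
#'   e.g. `.png`/`.svg`).
#' @return The tidy tibble (`electrode`, `time`, `in_burst`,
#'   `in_network_burst`), invisibly when written to disk.
#' @export
export_raster <- function(spikes, bursts, net_bursts, path = NULL,
                          plot_path = NULL) {
  tab <- spikes %>%
    select("electrode", "time") %>%
    mutate(
      in_burst = purrr::map2_lgl(
        .data$electrode, .data$time,
        function(el, t) {
          any(bursts$electrode == el & bursts$window_start <= t &
            t < bursts$window_end)
        }
      ),
      in_network_burst = purrr::map_lgl(
        .data$time,
        function(t) any(net_bursts$window_start <= t & t < net_bursts$window_end)
      )
    )
  if (!is.null(path)) readr::write_csv(tab, path)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, plot_raster(spikes, bursts, net_bursts),
      width = 8, height = 5
    )
  }
  if (is.null(path) && is.null(plot_path)) tab else invisible(tab)
}

#' Raster plot of well activity
#'
#' One tick per spike per electrode; spikes inside single-electrode bursts
#' are coloured, and network-burst windows are shaded.
#'
#' @inheritParams export_raster
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, bursts = NULL, net_bursts = NULL) {
  bursts <- bursts %||% tibble(
    electrode = integer(), window_start = numeric(), window_end = numeric()
  )
  net_bursts <- net_bursts %||% tibble(
    window_start = numeric(), window_end = numeric()
  )
  tab <- export_raster(spikes, bursts, net_bursts)
  p <- ggplot2::ggplot()
  if (nrow(net_bursts)) {
    p <- p + ggplot2::geom_rect(
      data = net_bursts,
      ggplot2::aes(
        xmin = .data$window_start, xmax = .data$window_end,
        ymin = -Inf, ymax = Inf
      ),
      fill = "magenta", alpha = 0.2
    )
  }
  p +
    ggplot2::geom_point(
      data = tab,
      ggplot2::aes(
        x = .data$time, y = factor(.data$electrode),
        colour = .data$in_burst
      ),
      shape = "|", size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "blue")) +
    ggplot2::labs(x = "time (s)", y = "electrode") +
    ggplot2::theme_minimal()
}
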