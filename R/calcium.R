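#' Photobleach correction of ROI traces
#'
#' Removes the monotonic intensity loss caused by photobleaching. The
#' default `"ramp"` mode fits the straight line through the first and
#' last frames of each trace and removes it, re-anchoring at the frame-0
#' intensity: a trace that is a pure linear decay becomes constant at
#' F(0). The `"offset"` mode subtracts the scalar first-minus-last
#' difference from every frame (a literal constant shift) and is kept for
#' comparison only.
#'
#' @param traces Long tibble with columns `roi`, `frame` (0-based) and
#'   `f`, e.g. `simulate_calcium_traces(...)$traces`.
#' @param mode `"ramp"` (default) or `"offset"`.
#' @return The tibble with `f` replaced by the corrected intensity.
#' @export
bleach_correct <- function(traces, mode = c("ramp", "offset")) {
  mode <- match.arg(mode)
  stopifnot(all(c("roi", "frame", "f") %in% names(traces)))
  traces %>%
    group_by(.data$roi) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) stop_invalid("bleach correction needs >= 2 frames")
      df <- arrange(df, .data$frame)
      drop <- df$f[1L] - df$f[nrow(df)]
      span <- df$frame[nrow(df)] - df$frame[1L]
      df$f <- switch(mode,
        ramp = df$f + drop * (df$frame - df$frame[1L]) / span,
        offset = df$f - drop
      )
      df
    }) %>%
    ungroup()
}

#' Normalised fluorescence change dF/F
#'
#' Computes `dF/F = (F - F0) / F0` per ROI, with F0 the fluorescence at
#' the starting point of exposure (frame 0). ROIs with `F0 <= 0` are
#' flagged invalid (`valid = FALSE`, `dff = NA`) and excluded from
#' summaries.
#'
#' @param traces Long tibble (`roi`, `frame`, `f`).
#' @return Long tibble `roi`, `frame`, `dff`, `f0`, `valid`.
#' @export
compute_dff <- function(traces) {
  stopifnot(all(c("roi", "frame", "f") %in% names(traces)))
  traces %>%
    group_by(.data$roi) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(
      f0 = .data$f[1L],
      valid = .data$f0 > 0,
      dff = ifelse(.data$valid, (.data$f - .data$f0) / .data$f0, NA_real_)
    ) %>%
    ungroup() %>%
    select("roi", "frame", "dff", "f0", "valid")
}

#' Largest dF/F excursion per ROI
#'
#' `dFmax` summarises the largest change of the dF/F trace. The default
#' `"range"` mode reports `max(dff) - min(dff)`; the `"max"` mode reports
#' `max(dff)` only. Both are offered because either reading of "largest
#' change" is defensible; the classification threshold is applied to
#' whichever mode is configured.
#'
#' @param dff Output of [compute_dff()].
#' @param mode `"range"` (default) or `"max"`.
#' @return Tibble `roi`, `dfmax`, `valid`.
#' @export
compute_dfmax <- function(dff, mode = c("range", "max")) {
  mode <- match.arg(mode)
  dff %>%
    group_by(.data$roi) %>%
    summarise(
      valid = all(.data$valid),
      dfmax = if (all(.data$valid)) {
        switch(mode,
          range = max(.data$dff) - min(.data$dff),
          max = max(.data$dff)
        )
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    select("roi", "dfmax", "valid")
}

#' Classify calcium-spike-positive ROIs
#'
#' An ROI is spike-positive when its dFmax strictly exceeds `threshold`
#' (default 0.01). The positive fraction over valid ROIs is attached as
#' the `"fraction"` attribute (NA when no ROI is valid).
#'
#' @param dfmax Tibble from [compute_dfmax()] (columns `roi`, `dfmax`,
#'   optionally `valid`), or a bare numeric vector of dFmax values.
#' @param threshold Positivity threshold on dFmax (strict `>`).
#' @return Tibble `roi`, `dfmax`, `valid`, `positive`, with attribute
#'   `fraction`.
#' @export
classify_spike_positive <- function(dfmax, threshold = 0.01) {
  if (is.numeric(dfmax)) {
    dfmax <- tibble(roi = seq_along(dfmax), dfmax = as.numeric(dfmax))
  }
  if (!"valid" %in% names(dfmax)) dfmax$valid <- !is.na(dfmax$dfmax)
  out <- dfmax %>%
    mutate(positive = .data$valid & .data$dfmax > threshold)
  n_valid <- sum(out$valid)
  attr(out, "fraction") <-
    if (n_valid == 0L) undefined_metric() else sum(out$positive) / n_valid
  out
}

#' Pairwise synchrony of active ROIs
#'
#' Mean pairwise Pearson correlation of the dF/F traces across
#' spike-positive ROIs, clipped to [0, 1]. Quantifies network-level
#' co-activation ("amplitude synchronised among cells"). Undefined (NA)
#' with fewer than two active ROIs.
#'
#' @param dff Output of [compute_dff()].
#' @param rois Optional integer vector of ROI ids to correlate; default
#'   is the set classified spike-positive at the default 0.01 threshold.
#' @param threshold Threshold forwarded to [classify_spike_positive()]
#'   when `rois` is NULL.
#' @return Scalar in [0, 1], or NA.
#' @export
synchrony_index <- function(dff, rois = NULL, threshold = 0.01) {
  if (is.null(rois)) {
    flags <- classify_spike_positive(compute_dfmax(dff), threshold)
    rois <- flags$roi[flags$positive]
  }
  if (length(rois) < 2L) {
    return(undefined_metric())
  }
  wide <- dff %>%
    filter(.data$roi %in% rois) %>%
    select("roi", "frame", "dff") %>%
    tidyr::pivot_wider(names_from = "roi", values_from = "dff") %>%
    arrange(.data$frame) %>%
    select(-"frame") %>%
    as.matrix()
  cm <- stats::cor(wide)
  val <- mean(cm[upper.tri(cm)])
  min(max(val, 0), 1)
}

#' Fraction of mCherry-positive cells among traced nuclei
#'
#' Counts nuclei whose mean nuclear mCherry intensity exceeds the
#' positivity threshold, divided by all traced nuclei (the Hoechst count
#' defines the total). Default threshold: background mean + 3 x
#' background SD, with background taken outside all nuclei.
#'
#' @param stack A `channel_stack` (see [render_synthetic_field()]) with an
#'   `mcherry` channel.
#' @param nuclei A `nucleus_set` from [segment_nuclei()].
#' @param threshold Optional absolute intensity threshold overriding the
#'   background rule.
#' @return Scalar fraction in [0, 1]; NA for an empty nucleus set.
#' @export
mcherry_positive_fraction <- function(stack, nuclei, threshold = NULL) {
  ch <- get_channel(stack, "mcherry")
  lab <- nuclei$labels
  traced <- nuclei$cells$label[nuclei$cells$traced]
  if (length(traced) == 0L) {
    return(undefined_metric())
  }
  if (is.null(threshold)) {
    bg <- ch[lab == 0]
    threshold <- mean(bg) + 3 * sd(bg)
  }
  means <- tapply(ch[lab > 0], lab[lab > 0], mean)
  means <- means[as.character(traced)]
  mean(means > threshold)
}

#' Per-condition calcium summary
#'
#' Assembles the figure-style calcium readouts: spike-positive fraction,
#' mean dFmax, and (optionally) the mean dFmax normalised to a reference
#' group's mean.
#'
#' @param dfmax Tibble from [compute_dfmax()] with an added `group`
#'   column, or a list of such tibbles.
#' @param reference Optional group level used as normalisation reference.
#' @param threshold Spike-positivity threshold.
#' @return Tibble per group: `group`, `n_rois`, `spike_positive_fraction`,
#'   `mean_dfmax`, `mean_dfmax_rel` (when `reference` given).
#' @export
summarize_calcium <- function(dfmax, reference = NULL, threshold = 0.01) {
  stopifnot("group" %in% names(dfmax))
  out <- dfmax %>%
    filter(!is.na(.data$dfmax)) %>%
    group_by(.data$group) %>%
    summarise(
      n_rois = dplyr::n(),
      spike_positive_fraction = mean(.data$dfmax > threshold),
      mean_dfmax = mean(.data$dfmax),
      .groups = "drop"
    )
  if (!is.null(reference)) {
    ref <- out$mean_dfmax[out$group == reference]
    if (length(ref) != 1L) stop_invalid("reference group not found")
    out <- mutate(out, mean_dfmax_rel = .data$mean_dfmax / ref)
  }
  out
}

#' Plot dF/F traces
#'
#' @param dff Output of [compute_dff()].
#' @param rois Optional subset of ROI ids.
#' @return A ggplot object (one facet-free line per ROI, offset stacked).
#' @export
plot_dff <- function(dff, rois = NULL) {
  if (!is.null(rois)) dff <- filter(dff, .data$roi %in% rois)
  ggplot2::ggplot(
    dff,
    ggplot2::aes(
      x = .data$frame, y = .data$dff + 0.5 * as.integer(factor(.data$roi)),
      group = .data$roi
    )
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = expression(Delta * F / F ~ "(stacked)")) +
    ggplot2::theme_minimal()
}
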