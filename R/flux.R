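#' Configuration for simulated OCR profiles
#'
#' Parameters for [simulate_ocr_profile()]: plateau oxygen consumption
#' rates for the four injection phases of a mitochondrial stress test
#' (baseline, post-oligomycin, post-FCCP, post-rotenone/antimycin A),
#' measurement noise, and the Hoechst+ cell count used for
#' normalisation.
#'
#' @param seed Integer RNG seed.
#' @param plateaus Named numeric vector of the four phase plateaus
#'   (pmol/min), in injection order: `baseline`, `oligomycin`, `fccp`,
#'   `rot_aa`.
#' @param n_per_phase Measurements per phase (3 on the instrument).
#' @param noise_sd Gaussian noise SD (pmol/min).
#' @param cells Hoechst-positive cell count in the well.
#' @param interval_min Minutes between successive measurements.
#' @return A list of class `ocr_sim_config`.
#' @export
ocr_sim_config <- function(seed = 1L,
                           plateaus = c(
                             baseline = 100, oligomycin = 40,
                             fccp = 150, rot_aa = 20
                           ),
                           n_per_phase = 3L,
                           noise_sd = 2,
                           cells = 4000L,
                           interval_min = 6.5) {
  if (length(plateaus) < 4L) {
    stop_invalid("all four phase plateaus (baseline, oligomycin, fccp, rot_aa) are required")
  }
  need <- c("baseline", "oligomycin", "fccp", "rot_aa")
  if (!all(need %in% names(plateaus))) {
    stop_invalid("`plateaus` must be named baseline, oligomycin, fccp, rot_aa")
  }
  check_nonnegative(noise_sd, "noise_sd")
  check_positive_scalar(n_per_phase, "n_per_phase")
  structure(
    list(
      seed = as.integer(seed), plateaus = plateaus[need],
      n_per_phase = as.integer(n_per_phase), noise_sd = noise_sd,
      cells = cells, interval_min = interval_min
    ),
    class = "ocr_sim_config"
  )
}

#' Simulate an OCR time course
#'
#' Generates `n_per_phase` measurements per injection phase at the
#' configured plateau value plus Gaussian noise, with phase labels
#' attached, and records the ground-truth respiration metrics implied by
#' the noise-free plateaus.
#'
#' @param config An [ocr_sim_config()].
#' @return A list of class `ocr_sim`: `profile` (tibble: `well`,
#'   `time_min`, `ocr`, `phase`, `cells`), `truth` (list with the
#'   noise-free `basal`, `maximal`, `spare`), `config`.
#' @export
simulate_ocr_profile <- function(config) {
  stopifnot(inherits(config, "ocr_sim_config"))
  with_seed(config$seed, {
    phases <- names(config$plateaus)
    n <- config$n_per_phase
    profile <- tibble(
      well = "A1",
      phase = factor(rep(phases, each = n), levels = phases),
      time_min = seq_len(length(phases) * n) * config$interval_min,
      ocr = rep(as.numeric(config$plateaus), each = n) +
        rnorm(length(phases) * n, 0, config$noise_sd),
      cells = config$cells
    ) %>% select("well", "time_min", "ocr", "phase", "cells")
    p <- config$plateaus
    non_mito <- p[["rot_aa"]]
    truth <- list(
      basal = p[["baseline"]] - non_mito,
      maximal = p[["fccp"]] - non_mito,
      spare = (p[["fccp"]] - non_mito) / (p[["baseline"]] - non_mito)
    )
    structure(list(profile = profile, truth = truth, config = config),
      class = "ocr_sim"
    )
  })
}

#' Respiration metrics from an OCR profile
#'
#' Implements the mitochondrial stress-test reductions: non-mitochondrial
#' respiration is the aggregate of the rotenone/antimycin-A phase
#' (default: its mean; `"min"` available); basal OCR is the *third*
#' baseline measurement minus non-mitochondrial respiration; maximal OCR
#' is the FCCP-phase aggregate minus non-mitochondrial respiration; and
#' spare respiratory capacity is the ratio maximal / basal
#' (dimensionless).
#'
#' @param profile Tibble with columns `well`, `ocr`, `phase` (levels
#'   baseline, oligomycin, fccp, rot_aa in injection order), optionally
#'   `time_min` (used to order measurements) and `cells`.
#' @param aggregate `"mean"` (default) or `"min"` for the post-injection
#'   phase aggregates.
#' @param spare_as_percent Report spare capacity multiplied by 100.
#' @return Tibble per well: `basal`, `maximal`, `spare` (NA when basal
#'   <= 0), carrying `cells` when present.
#' @export
compute_respiration_metrics <- function(profile, aggregate = c("mean", "min"),
                                        spare_as_percent = FALSE) {
  aggregate <- match.arg(aggregate)
  need <- c("baseline", "oligomycin", "fccp", "rot_aa")
  stopifnot(all(c("ocr", "phase") %in% names(profile)))
  if (!"well" %in% names(profile)) profile$well <- "well1"
  agg_fun <- if (aggregate == "mean") mean else min
  profile %>%
    group_by(.data$well) %>%
    dplyr::group_modify(function(df, key) {
      if (!all(need %in% as.character(df$phase))) {
        stop_invalid("all four phases (baseline, oligomycin, fccp, rot_aa) are required")
      }
      if ("time_min" %in% names(df)) df <- arrange(df, .data$time_min)
      base3 <- df$ocr[df$phase == "baseline"]
      if (length(base3) < 3L) {
        rlang::warn("fewer than 3 baseline measurements; using the last one")
      }
      base3 <- base3[min(3L, length(base3))]
      non_mito <- agg_fun(df$ocr[df$phase == "rot_aa"])
      maximal <- agg_fun(df$ocr[df$phase == "fccp"]) - non_mito
      basal <- base3 - non_mito
      spare <- if (basal > 0) maximal / basal else undefined_metric()
      if (spare_as_percent && !is.na(spare)) spare <- spare * 100
      out <- tibble(basal = basal, maximal = maximal, spare = spare)
      if ("cells" %in% names(df)) out$cells <- df$cells[1L]
      out
    }) %>%
    ungroup()
}

#' Normalise respiration metrics by cell count
#'
#' Divides basal and maximal OCR by the number of Hoechst-positive cells
#' in units of 1000 cells; the spare capacity ratio is scale-free and
#' left unchanged.
#'
#' @param metrics Tibble from [compute_respiration_metrics()].
#' @param cells Cell count per well; defaults to the `cells` column.
#' @return The tibble with `basal_per_1k` and `maximal_per_1k` added.
#' @export
normalize_by_cells <- function(metrics, cells = NULL) {
  if (is.null(cells)) {
    if (!"cells" %in% names(metrics)) stop_invalid("cell counts required")
    cells <- metrics$cells
  }
  if (any(!is.finite(cells)) || any(cells <= 0)) {
    stop_invalid("cell counts must be > 0")
  }
  k_cells <- rep_len(cells, nrow(metrics)) / 1000
  metrics %>%
    mutate(
      basal_per_1k = .data$basal / k_cells,
      maximal_per_1k = .data$maximal / k_cells
    )
}

#' Plot an OCR time course
#'
#' @param profile OCR tibble (`time_min`, `ocr`, `phase`, optionally
#'   `well`).
#' @return A ggplot object with injection phases distinguished by colour.
#' @export
plot_ocr <- function(profile) {
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$time_min, y = .data$ocr, colour = .data$phase)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = if ("well" %in% names(profile)) {
      .data$well
    } else {
      1
    }), alpha = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "time (min)", y = "OCR (pmol/min)",
      colour = "phase"
    ) +
    ggplot2::theme_minimal()
}
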