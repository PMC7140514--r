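default_experiment_config <- function() {
  list(
    n_wells = 4L,
    control = "bmirs_minus",
    conditions = list(
      bmirs_minus = list(
        mea = list(duration_s = 180, background_rate_hz = 1,
          burst_rate_per_min = 1, network_rate_per_min = 0.5),
        calcium = list(n_rois = 30L, n_frames = 2000L, active_fraction = 0.2)
      ),
      bmirs_plus = list(
        mea = list(duration_s = 180, background_rate_hz = 3,
          burst_rate_per_min = 4, network_rate_per_min = 2),
        calcium = list(n_rois = 30L, n_frames = 2000L, active_fraction = 0.6)
      )
    )
  )
}

apply_overrides <- function(fn, overrides, seed) {
  do.call(fn, c(list(seed = seed), overrides))
}

#' Run a virtual two-condition experiment
#'
#' Chains simulate -> analyze -> stats for a two-condition culture
#' comparison (e.g. a maturation-factor-negative vs -positive
#' parameterisation): per well, MEA spike trains are simulated and
#' reduced to well metrics, and calcium traces are simulated and reduced
#' to spike-positive fractions and mean dFmax; each metric is then
#' compared between conditions with Student's t-test. All randomness
#' derives from `seed`, so identical calls produce identical bundles.
#'
#' @param config A config list (see `default_experiment_config` in the
#'   package sources), a YAML file path with the same structure, or NULL
#'   for the default two-condition setup.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, the bundle is written
#'   as CSV files plus a manifest with MD5 hashes.
#' @return List of class `virtual_experiment`: `well_metrics`,
#'   `calcium_summary`, `comparisons`, `manifest`.
#' @export
run_virtual_experiment <- function(config = NULL, seed = 1L, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% default_experiment_config()
  if (is.null(config$conditions) || length(config$conditions) < 2L) {
    stop_invalid("config$conditions must name at least two conditions")
  }
  n_wells <- config$n_wells %||% 4L
  cond_names <- names(config$conditions)

  well_metrics <- list()
  calcium_rows <- list()
  for (ci in seq_along(cond_names)) {
    cn <- cond_names[ci]
    cc <- config$conditions[[cn]]
    for (w in seq_len(n_wells)) {
      sub_seed <- as.integer((seed * 131L + ci * 17L + w) %% .Machine$integer.max)
      sim <- apply_overrides(mea_sim_config, cc$mea %||% list(), sub_seed)
      st <- simulate_spike_trains(sim)
      wm <- compute_well_metrics(st$spikes, st$duration_s, st$n_electrodes)
      well_metrics[[length(well_metrics) + 1L]] <-
        mutate(wm, condition = cn, well = w)

      csim <- apply_overrides(calcium_sim_config, cc$calcium %||% list(),
        sub_seed + 1L
      )
      ca <- simulate_calcium_traces(csim)
      dfm <- ca$traces %>%
        bleach_correct() %>%
        compute_dff() %>%
        compute_dfmax()
      flags <- classify_spike_positive(dfm)
      calcium_rows[[length(calcium_rows) + 1L]] <- tibble(
        condition = cn, well = w,
        spike_positive_fraction = attr(flags, "fraction"),
        mean_dfmax = mean(dfm$dfmax, na.rm = TRUE)
      )
    }
  }
  well_metrics <- bind_rows(well_metrics)
  calcium_summary <- bind_rows(calcium_rows)

  metrics <- c(
    "n_active", "mean_firing_rate_hz", "n_bursts",
    "n_bursting_electrodes", "network_burst_per_min"
  )
  comp_mea <- purrr::map(metrics, function(m) {
    d <- tibble(group = well_metrics$condition, value = well_metrics[[m]])
    d <- filter(d, is.finite(.data$value))
    if (dplyr::n_distinct(d$group) < 2L || any(table(d$group) < 2L) ||
      all(tapply(d$value, d$group, stats::var) == 0)) {
      return(NULL)
    }
    mutate(tidy(t_test(d)), metric = m)
  })
  comp_ca <- purrr::map(
    c("spike_positive_fraction", "mean_dfmax"),
    function(m) {
      d <- tibble(group = calcium_summary$condition, value = calcium_summary[[m]])
      d <- filter(d, is.finite(.data$value))
      if (dplyr::n_distinct(d$group) < 2L || any(table(d$group) < 2L) ||
        all(tapply(d$value, d$group, stats::var) == 0)) {
        return(NULL)
      }
      mutate(tidy(t_test(d)), metric = m)
    }
  )
  comparisons <- bind_rows(c(comp_mea, comp_ca))

  bundle <- list(
    well_metrics = well_metrics,
    calcium_summary = calcium_summary,
    comparisons = comparisons,
    manifest = tibble(seed = seed, n_wells = n_wells,
      conditions = paste(cond_names, collapse = ";")
    )
  )
  class(bundle) <- "virtual_experiment"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      well_metrics = file.path(out_dir, "well_metrics.csv"),
      calcium_summary = file.path(out_dir, "calcium_summary.csv"),
      comparisons = file.path(out_dir, "comparisons.csv")
    )
    readr::write_csv(well_metrics, paths[["well_metrics"]])
    readr::write_csv(calcium_summary, paths[["calcium_summary"]])
    readr::write_csv(comparisons, paths[["comparisons"]])
    manifest <- tibble(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths)),
      seed = seed
    )
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    bundle$manifest <- manifest
  }
  bundle
}

# Required columns per known table kind.
format_schemas <- list(
  spikes = c("electrode", "time"),
  traces = c("roi", "frame", "f"),
  ocr = c("well", "time_min", "ocr", "phase"),
  ct = c("gene", "condition", "ct"),
  elisa = c("ab40", "ab42", "protein_ug"),
  groups = c("group", "value")
)

#' Validate input table formats
#'
#' Checks that CSV files (or in-memory data frames) carry the columns
#' each analysis entry point expects, and returns actionable diagnostics
#' instead of erroring.
#'
#' @param inputs Named list/vector; names are table kinds (spikes,
#'   traces, ocr, ct, elisa, groups), values are file paths or data
#'   frames.
#' @return Tibble: `kind`, `ok`, `message` (empty when valid).
#' @export
validate_formats <- function(inputs) {
  purrr::imap(inputs, function(x, kind) {
    schema <- format_schemas[[kind]]
    if (is.null(schema)) {
      return(tibble(kind = kind, ok = FALSE,
        message = sprintf("unknown table kind '%s'", kind)
      ))
    }
    df <- tryCatch(
      if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else x,
      error = function(e) NULL
    )
    if (is.null(df)) {
      return(tibble(kind = kind, ok = FALSE, message = "file unreadable"))
    }
    missing <- setdiff(schema, names(df))
    if (length(missing)) {
      tibble(kind = kind, ok = FALSE,
        message = paste("missing column(s):", paste(missing, collapse = ", "))
      )
    } else {
      tibble(kind = kind, ok = TRUE, message = "")
    }
  }) %>% bind_rows()
}
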