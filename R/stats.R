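significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

new_comparison <- function(tab, method) {
  tab$method <- method
  tab$stars <- significance_stars(tab$adj_p_value)
  class(tab) <- c("neuro_comparison", class(tab))
  tab
}

check_group_data <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  data <- filter(data, is.finite(.data$value))
  sizes <- data %>% count(.data$group)
  if (any(sizes$n < 2L)) stop_invalid("every group needs >= 2 replicates")
  data
}

# One-way ANOVA building blocks shared by Tukey and Dunnett.
anova_parts <- function(data) {
  g <- data %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value), v = var(.data$value),
      .groups = "drop"
    )
  df <- sum(g$n) - nrow(g)
  mse <- sum((g$n - 1) * g$v) / df
  list(groups = g, df = df, mse = mse)
}

#' Student's t-test for a single comparison
#'
#' Two-sided equal-variance (Student's) two-sample t-test. Welch's
#' correction is available behind `var_equal = FALSE`.
#'
#' @param data Tibble with columns `group` (exactly two levels) and
#'   `value`.
#' @param var_equal Assume equal variances (default TRUE, Student's).
#' @return A one-row comparison tibble: `contrast`, `estimate`,
#'   `statistic`, `df`, `p_value`, `adj_p_value` (= raw p), `method`,
#'   `stars`.
#' @export
t_test <- function(data, var_equal = TRUE) {
  data <- check_group_data(data)
  lev <- unique(data$group)
  if (length(lev) != 2L) stop_invalid("t_test requires exactly 2 groups")
  x <- data$value[data$group == lev[1L]]
  y <- data$value[data$group == lev[2L]]
  fit <- t.test(x, y, var.equal = var_equal)
  new_comparison(
    tibble(
      contrast = paste(lev[1L], "-", lev[2L]),
      estimate = mean(x) - mean(y),
      statistic = unname(fit$statistic),
      df = unname(fit$parameter),
      p_value = fit$p.value,
      adj_p_value = fit$p.value
    ),
    method = if (var_equal) "student_t" else "welch_t"
  )
}

#' Tukey's honestly-significant-difference test
#'
#' All-pairs comparisons after one-way ANOVA, with family-wise adjustment
#' through the studentized range distribution (Tukey-Kramer for unequal
#' group sizes).
#'
#' @param data Tibble with columns `group` (>= 3 levels) and `value`.
#' @return Comparison tibble, one row per pair: `contrast`, `estimate`,
#'   `statistic` (q), `df`, `p_value`, `adj_p_value`, `method`, `stars`.
#'   The adjusted p equals the raw p (the studentized-range p is already
#'   family-wise).
#' @export
tukey_hsd <- function(data) {
  data <- check_group_data(data)
  k <- dplyr::n_distinct(data$group)
  if (k < 3L) {
    stop_invalid("tukey_hsd requires >= 3 groups; use t_test for two")
  }
  ap <- anova_parts(data)
  g <- ap$groups
  pairs <- utils::combn(seq_len(k), 2L)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]
    i2 <- pairs[2L, j]
    diff <- g$mean[i1] - g$mean[i2]
    se <- sqrt(ap$mse / 2 * (1 / g$n[i1] + 1 / g$n[i2]))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = ap$df, lower.tail = FALSE)
    tibble(
      contrast = paste(g$group[i1], "-", g$group[i2]),
      estimate = diff, statistic = q, df = ap$df,
      p_value = p, adj_p_value = p
    )
  }) %>% bind_rows()
  new_comparison(out, method = "tukey_hsd")
}

#' Dunnett's many-to-one comparisons
#'
#' Compares every group against the designated control after one-way
#' ANOVA. The family-wise adjusted p-value is the tail probability of
#' max|T| under the joint multivariate-t reference distribution,
#' approximated by seeded Monte Carlo (default 1e5 draws), so results
#' are reproducible and accurate to Monte Carlo error ~1/sqrt(draws).
#'
#' @param data Tibble with columns `group` and `value`.
#' @param control Control group level.
#' @param n_draws Monte Carlo draws (>= 1e5 recommended).
#' @param seed RNG seed for the draws.
#' @return Comparison tibble, one row per non-control group: `contrast`,
#'   `estimate`, `statistic` (t), `df`, `p_value` (unadjusted two-sided
#'   t), `adj_p_value` (family-wise), `method`, `stars`.
#' @export
dunnett_test <- function(data, control, n_draws = 1e5, seed = 1L) {
  data <- check_group_data(data)
  if (missing(control) || !control %in% data$group) {
    stop_invalid("a control group present in the data is required")
  }
  ap <- anova_parts(data)
  g <- ap$groups
  i0 <- which(g$group == control)
  others <- setdiff(seq_len(nrow(g)), i0)
  if (length(others) == 0L) stop_invalid("need at least one non-control group")

  tstat <- vapply(others, function(i) {
    (g$mean[i] - g$mean[i0]) /
      sqrt(ap$mse * (1 / g$n[i] + 1 / g$n[i0]))
  }, numeric(1))

  # Correlation of the contrasts sharing the control mean.
  lam <- sqrt(g$n[others] / (g$n[others] + g$n[i0]))
  R <- outer(lam, lam)
  diag(R) <- 1

  maxT <- with_seed(seed, {
    m <- length(others)
    Z <- matrix(rnorm(n_draws * m), n_draws, m) %*% chol(R)
    W <- sqrt(rchisq(n_draws, df = ap$df) / ap$df)
    mx <- abs(Z[, 1L])
    for (j in seq_len(m)[-1L]) mx <- pmax(mx, abs(Z[, j]))
    mx / W
  })

  out <- tibble(
    contrast = paste(g$group[others], "-", control),
    estimate = g$mean[others] - g$mean[i0],
    statistic = tstat,
    df = ap$df,
    p_value = 2 * pt(-abs(tstat), ap$df),
    adj_p_value = vapply(tstat, function(t) mean(maxT >= abs(t)), numeric(1))
  )
  new_comparison(out, method = "dunnett_mc")
}

#' Figure-style group summary
#'
#' Per-group mean, dispersion (SD or SEM) and n, optionally normalised to
#' a reference group's mean (the reference group then averages 1.0).
#'
#' @param data Tibble with columns `group` and `value`.
#' @param dispersion `"sd"` or `"sem"`.
#' @param reference Optional reference group for normalisation.
#' @return Tibble per group: `group`, `n`, `mean`, `sd` or `sem`
#'   (NA when n < 2), and `mean_rel` when a reference is given.
#' @export
summarize_groups <- function(data, dispersion = c("sd", "sem"),
                             reference = NULL) {
  dispersion <- match.arg(dispersion)
  stopifnot(all(c("group", "value") %in% names(data)))
  out <- data %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      disp = if (dplyr::n() < 2L) NA_real_ else {
        if (dispersion == "sd") sd(.data$value) else sd(.data$value) / sqrt(dplyr::n())
      },
      .groups = "drop"
    ) %>%
    rename(!!dispersion := "disp")
  if (!is.null(reference)) {
    ref <- out$mean[out$group == reference]
    if (length(ref) != 1L) stop_invalid("reference group not found")
    out <- mutate(out, mean_rel = .data$mean / ref)
  }
  out
}

#' @method tidy neuro_comparison
#' @export
tidy.neuro_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance neuro_comparison
#' @export
glance.neuro_comparison <- function(x, ...) {
  tibble(
    method = x$method[1L],
    n_contrasts = nrow(x),
    n_significant = sum(x$adj_p_value < 0.05, na.rm = TRUE),
    min_adj_p = suppressWarnings(min(x$adj_p_value, na.rm = TRUE))
  )
}

#' @method autoplot neuro_comparison
#' @export
autoplot.neuro_comparison <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$estimate, y = .data$contrast)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
      vjust = -0.6, size = 5
    ) +
    ggplot2::labs(x = "difference in means", y = NULL) +
    ggplot2::theme_minimal()
}
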