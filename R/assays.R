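#' Configuration for simulated qPCR and ELISA tables
#'
#' Parameters for [simulate_assay_tables()]. Ct values are constructed so
#' that fold change equals `2^(-ddCt)` exactly before noise; the ELISA
#' table carries amyloid-beta concentrations and culture protein with the
#' configured ratios.
#'
#' @param seed Integer RNG seed.
#' @param genes Character vector of target genes.
#' @param conditions Character vector of condition names; the first is
#'   the reference condition.
#' @param fold_changes Matrix or data frame (genes x conditions) of true
#'   fold changes relative to the reference condition; defaults to 1 for
#'   the reference and 2 elsewhere.
#' @param reference_gene Housekeeping gene (ActB).
#' @param ref_gene_ct Ct of the reference gene (cycles).
#' @param base_ct Ct of each target gene in the reference condition.
#' @param n_replicates Replicates per gene x condition.
#' @param ct_noise_sd Gaussian Ct noise (cycles).
#' @param ab40_pg_ml,ab42_pg_ml True amyloid-beta concentrations (pg/ml)
#'   per sample (recycled over `n_elisa` samples).
#' @param protein_ug Culture protein (ug) per sample.
#' @param n_elisa Number of ELISA samples.
#' @param elisa_cv Multiplicative noise CV for ELISA concentrations.
#' @return A list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(seed = 1L,
                             genes = c("Map2", "Syn1", "Dlg4"),
                             conditions = c("ngn2_d20", "ngn2_bmirs_d20"),
                             fold_changes = NULL,
                             reference_gene = "ActB",
                             ref_gene_ct = 15,
                             base_ct = 24,
                             n_replicates = 3L,
                             ct_noise_sd = 0,
                             ab40_pg_ml = 100,
                             ab42_pg_ml = 10,
                             protein_ug = 2,
                             n_elisa = 4L,
                             elisa_cv = 0) {
  if (is.null(fold_changes)) {
    fold_changes <- matrix(2,
      nrow = length(genes), ncol = length(conditions),
      dimnames = list(genes, conditions)
    )
    fold_changes[, 1L] <- 1
  }
  fold_changes <- as.matrix(fold_changes)
  if (!is.null(dimnames(fold_changes))) {
    genes <- rownames(fold_changes)
    conditions <- colnames(fold_changes)
  } else {
    if (!all(dim(fold_changes) == c(length(genes), length(conditions)))) {
      stop_invalid("`fold_changes` must be genes x conditions")
    }
    dimnames(fold_changes) <- list(genes, conditions)
  }
  if (any(fold_changes <= 0)) stop_invalid("fold changes must be > 0")
  check_nonnegative(ct_noise_sd, "ct_noise_sd")
  check_nonnegative(c(ab40_pg_ml, ab42_pg_ml, protein_ug), "concentrations")
  structure(
    list(
      seed = as.integer(seed), genes = genes, conditions = conditions,
      fold_changes = fold_changes, reference_gene = reference_gene,
      ref_gene_ct = ref_gene_ct, base_ct = base_ct,
      n_replicates = as.integer(n_replicates), ct_noise_sd = ct_noise_sd,
      ab40_pg_ml = ab40_pg_ml, ab42_pg_ml = ab42_pg_ml,
      protein_ug = protein_ug, n_elisa = as.integer(n_elisa),
      elisa_cv = elisa_cv
    ),
    class = "assay_sim_config"
  )
}

#' Simulate Ct and ELISA tables with known ground truth
#'
#' The Ct table satisfies `fold = 2^(-ddCt)` exactly at zero noise:
#' `Ct(gene, cond) = base_ct - log2(fold(gene, cond))` with the reference
#' gene fixed at `ref_gene_ct` in every sample. The ELISA table carries
#' the configured amyloid-beta concentrations and protein amounts.
#'
#' @param config An [assay_sim_config()].
#' @return A list of class `assay_sim`: `ct` (tibble: `gene`,
#'   `condition`, `replicate`, `ct`), `elisa` (tibble: `sample`, `ab40`,
#'   `ab42`, `protein_ug`), `truth` (list: `fold_changes`,
#'   `ab42_40_ratio`), `config`.
#' @export
simulate_assay_tables <- function(config) {
  stopifnot(inherits(config, "assay_sim_config"))
  if (!nzchar(config$reference_gene)) stop_invalid("reference gene required")
  with_seed(config$seed, {
    grid <- tidyr::expand_grid(
      gene = config$genes,
      condition = config$conditions,
      replicate = seq_len(config$n_replicates)
    ) %>%
      mutate(
        ct = config$base_ct -
          log2(config$fold_changes[cbind(.data$gene, .data$condition)]) +
          rnorm(dplyr::n(), 0, config$ct_noise_sd)
      )
    ref <- tidyr::expand_grid(
      gene = config$reference_gene,
      condition = config$conditions,
      replicate = seq_len(config$n_replicates)
    ) %>%
      mutate(ct = config$ref_gene_ct + rnorm(dplyr::n(), 0, config$ct_noise_sd))
    ct <- bind_rows(grid, ref) %>% arrange(.data$gene, .data$condition)

    noise <- function(x) x * exp(rnorm(length(x), 0, config$elisa_cv))
    elisa <- tibble(
      sample = paste0("s", seq_len(config$n_elisa)),
      ab40 = noise(rep_len(config$ab40_pg_ml, config$n_elisa)),
      ab42 = noise(rep_len(config$ab42_pg_ml, config$n_elisa)),
      protein_ug = rep_len(config$protein_ug, config$n_elisa)
    )
    structure(
      list(
        ct = ct, elisa = elisa,
        truth = list(
          fold_changes = config$fold_changes,
          ab42_40_ratio = rep_len(config$ab42_pg_ml, config$n_elisa) /
            rep_len(config$ab40_pg_ml, config$n_elisa)
        ),
        config = config
      ),
      class = "assay_sim"
    )
  })
}

#' Comparative (ddCt) relative expression
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference gene)`; per condition, the
#' replicate mean dCt is taken, and `ddCt = mean dCt(condition) - mean
#' dCt(reference condition)`. Returns `-ddCt` (the heatmap value: higher
#' expression gives a larger `-ddCt`) and the fold change `2^(-ddCt)`,
#' assuming amplification efficiency 2.
#'
#' @param ct Tibble with columns `gene`, `condition`, `replicate`, `ct`.
#' @param reference_gene Housekeeping gene name (default `"ActB"`).
#' @param reference_condition Condition every gene is standardised to;
#'   default is the first condition in the table.
#' @return Tibble: `gene`, `condition`, `dct`, `minus_ddct`, `fold`.
#'   The reference condition column is 0 (`minus_ddct`) / 1 (`fold`) by
#'   construction.
#' @export
compute_ddct <- function(ct, reference_gene = "ActB",
                         reference_condition = NULL) {
  stopifnot(all(c("gene", "condition", "ct") %in% names(ct)))
  if (!reference_gene %in% ct$gene) {
    stop_invalid(sprintf("reference gene '%s' missing from Ct table", reference_gene))
  }
  if (is.null(reference_condition)) reference_condition <- ct$condition[[1L]]
  if (!reference_condition %in% ct$condition) {
    stop_invalid("reference condition missing from Ct table")
  }
  if (!"replicate" %in% names(ct)) ct$replicate <- 1L

  ref_ct <- ct %>%
    filter(.data$gene == reference_gene) %>%
    select("condition", "replicate", ref_ct = "ct")
  missing_ref <- ct %>%
    distinct(.data$condition, .data$replicate) %>%
    dplyr::anti_join(ref_ct, by = c("condition", "replicate"))
  if (nrow(missing_ref) > 0L) {
    stop_invalid("reference gene must be measured in every sample")
  }

  dct <- ct %>%
    filter(.data$gene != reference_gene) %>%
    left_join(ref_ct, by = c("condition", "replicate")) %>%
    mutate(dct = .data$ct - .data$ref_ct) %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(dct = mean(.data$dct), .groups = "drop")

  dct %>%
    group_by(.data$gene) %>%
    mutate(
      minus_ddct = -(.data$dct - .data$dct[.data$condition == reference_condition]),
      fold = 2^.data$minus_ddct
    ) %>%
    ungroup()
}

#' Expression heatmap matrix
#'
#' Pivots a [compute_ddct()] result into the genes x conditions matrix of
#' `-ddCt` values used for expression heatmaps.
#'
#' @param ddct Tibble from [compute_ddct()].
#' @return Numeric matrix (genes x conditions).
#' @export
expression_matrix <- function(ddct) {
  wide <- ddct %>%
    select("gene", "condition", "minus_ddct") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "minus_ddct")
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene
  m
}

#' Protein-normalised ELISA quantities
#'
#' Normalises each amyloid-beta concentration by the culture protein
#' amount and computes the Ab42/Ab40 ratio on the raw concentrations
#' (the ratio is invariant to protein normalisation). Rows with
#' non-positive protein are flagged invalid; the ratio is defined only
#' when Ab40 > 0.
#'
#' @param elisa Tibble with columns `ab40`, `ab42` (pg/ml) and
#'   `protein_ug`.
#' @return The tibble with `ab40_per_ug`, `ab42_per_ug` (pg/ug),
#'   `ratio_42_40` and `valid` added.
#' @export
normalize_elisa <- function(elisa) {
  stopifnot(all(c("ab40", "ab42", "protein_ug") %in% names(elisa)))
  if (any(elisa$ab40 < 0 | elisa$ab42 < 0, na.rm = TRUE)) {
    stop_invalid("concentrations must be >= 0")
  }
  elisa %>%
    mutate(
      valid = is.finite(.data$protein_ug) & .data$protein_ug > 0,
      ab40_per_ug = ifelse(.data$valid, .data$ab40 / .data$protein_ug, NA_real_),
      ab42_per_ug = ifelse(.data$valid, .data$ab42 / .data$protein_ug, NA_real_),
      ratio_42_40 = ifelse(.data$ab40 > 0, .data$ab42 / .data$ab40, NA_real_)
    )
}
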