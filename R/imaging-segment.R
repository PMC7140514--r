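#' Segment and trace nuclei from the Hoechst channel
#'
#' Otsu threshold, hole filling, and watershed on the distance transform
#' split the Hoechst channel into candidate nuclei. A candidate is a
#' *traced* nucleus when its area strictly exceeds `area_min_um2`
#' (default 50 um^2) and its mean intensity stays below the pyknotic
#' brightness threshold (field median nuclear intensity times
#' `pyknotic_intensity_factor`); small bright pyknotic nuclei and debris
#' are thereby excluded.
#'
#' @param stack A [channel_stack()] with a Hoechst channel.
#' @param area_min_um2 Minimum traced area (um^2, strict `>`).
#' @param pyknotic_intensity_factor Brightness multiplier over the field
#'   median nuclear intensity above which a nucleus is called pyknotic.
#' @param watershed_tolerance Tolerance passed to `EBImage::watershed`.
#' @return A list of class `nucleus_set`: `labels` (integer matrix over
#'   all candidates), `cells` (tibble: `label`, `area_um2`,
#'   `mean_hoechst`, `centroid_row`, `centroid_col`, `pyknotic`,
#'   `traced`), `pixel_size_um`.
#' @export
segment_nuclei <- function(stack, area_min_um2 = 50,
                           pyknotic_intensity_factor = 2,
                           watershed_tolerance = 1) {
  if (!has_channel(stack, "hoechst")) stop_invalid("Hoechst channel required")
  img <- get_channel(stack, "hoechst")
  ps <- stack$pixel_size_um

  rng <- range(img)
  norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  thr <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > thr
  bw <- EBImage::fillHull(EBImage::Image(bw))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"

  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) {
    return(structure(
      list(
        labels = lab,
        cells = tibble(
          label = integer(), area_um2 = numeric(), mean_hoechst = numeric(),
          centroid_row = numeric(), centroid_col = numeric(),
          pyknotic = logical(), traced = logical()
        ),
        pixel_size_um = ps
      ),
      class = "nucleus_set"
    ))
  }
  fg <- lab > 0
  labf <- lab[fg]
  area_px <- tabulate(labf, nbins = max(ids))[ids]
  mean_i <- as.numeric(tapply(img[fg], labf, mean))
  rows <- row(lab)[fg]
  cols <- col(lab)[fg]
  cy <- as.numeric(tapply(rows, labf, mean))
  cx <- as.numeric(tapply(cols, labf, mean))

  pyk_thr <- median(mean_i) * pyknotic_intensity_factor
  cells <- tibble(
    label = ids,
    area_um2 = area_px * ps^2,
    mean_hoechst = mean_i,
    centroid_row = cy,
    centroid_col = cx,
    pyknotic = mean_i > pyk_thr
  ) %>%
    mutate(traced = .data$area_um2 > area_min_um2 & !.data$pyknotic)

  structure(
    list(labels = lab, cells = cells, pixel_size_um = ps),
    class = "nucleus_set"
  )
}

#' Expand traced nuclear regions into cell regions
#'
#' Grows every traced nucleus outward into the surrounding cytoplasm,
#' label-competitively (each background pixel can be claimed by its
#' nearest nucleus only, so neighbouring regions never overlap). The
#' default `"area"` mode stops each region when it reaches
#' `(1 + expansion_fraction)` times its nuclear area (default +50% area);
#' the `"radius"` mode instead grows by `expansion_fraction` of the
#' equivalent nuclear radius.
#'
#' @param nuclei A `nucleus_set` from [segment_nuclei()].
#' @param expansion_fraction Relative growth (default 0.5).
#' @param mode `"area"` (default) or `"radius"`.
#' @return A list of class `cell_region_set`: `labels` (expanded label
#'   matrix over traced nuclei), `nucleus_labels`, `cells` (tibble:
#'   `label`, `nucleus_area_um2`, `region_area_um2`, `area_ratio`),
#'   `pixel_size_um`.
#' @export
expand_regions <- function(nuclei, expansion_fraction = 0.5,
                           mode = c("area", "radius")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nuclei, "nucleus_set"))
  check_nonnegative(expansion_fraction, "expansion_fraction")
  ps <- nuclei$pixel_size_um
  lab <- nuclei$labels
  traced <- nuclei$cells$label[nuclei$cells$traced]
  seed <- lab
  seed[!(seed %in% traced)] <- 0L

  if (length(traced) == 0L || expansion_fraction == 0) {
    cells <- nuclei$cells %>%
      filter(.data$traced) %>%
      mutate(
        nucleus_area_um2 = .data$area_um2,
        region_area_um2 = .data$area_um2,
        area_ratio = 1
      ) %>%
      select("label", "nucleus_area_um2", "region_area_um2", "area_ratio")
    return(structure(
      list(
        labels = seed, nucleus_labels = seed, cells = cells,
        pixel_size_um = ps
      ),
      class = "cell_region_set"
    ))
  }

  # Nearest traced nucleus for every pixel (Voronoi via propagate) and
  # Euclidean distance to the nearest nucleus pixel.
  vor <- EBImage::propagate(EBImage::Image(seed * 0), EBImage::Image(seed))
  vor <- EBImage::imageData(vor)
  dist_bg <- EBImage::imageData(EBImage::distmap(EBImage::Image(seed == 0)))

  out <- seed
  areas <- tabulate(seed[seed > 0], nbins = max(traced))
  cells <- purrr::map(traced, function(L) {
    a_nuc <- areas[L]
    target <- if (mode == "area") {
      ceiling((1 + expansion_fraction) * a_nuc)
    } else {
      NA_integer_
    }
    cand <- which(vor == L & seed == 0L)
    if (mode == "area") {
      need <- target - a_nuc
      if (need > 0 && length(cand) > 0) {
        take <- cand[order(dist_bg[cand])][seq_len(min(need, length(cand)))]
        out[take] <<- L
      }
    } else {
      r_grow <- expansion_fraction * sqrt(a_nuc / pi)
      take <- cand[dist_bg[cand] <= r_grow]
      out[take] <<- L
    }
    a_reg <- a_nuc + if (mode == "area") {
      min(max(target - a_nuc, 0), length(cand))
    } else {
      sum(dist_bg[cand] <= r_grow)
    }
    tibble(
      label = L,
      nucleus_area_um2 = a_nuc * ps^2,
      region_area_um2 = a_reg * ps^2,
      area_ratio = a_reg / a_nuc
    )
  }) %>% bind_rows()

  structure(
    list(
      labels = out, nucleus_labels = seed, cells = cells,
      pixel_size_um = ps
    ),
    class = "cell_region_set"
  )
}
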