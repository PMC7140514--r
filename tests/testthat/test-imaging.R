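# Build a channel stack with hand-placed square nuclei of exact pixel
# areas (pixel size 1 um/px so area in px equals area in um^2).
stack_with_regions <- function(areas_px, intensity = 0.5, nrow_px = 300,
                               pixel_size = 1, gap = 60) {
  img <- matrix(0, nrow_px, nrow_px)
  for (i in seq_along(areas_px)) {
    side <- floor(sqrt(areas_px[i]))
    extra <- areas_px[i] - side^2
    r0 <- 40
    c0 <- 20 + (i - 1) * gap
    img[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- intensity
    if (extra > 0) img[r0 + side, c0:(c0 + extra - 1)] <- intensity
  }
  channel_stack(list(hoechst = img), pixel_size)
}

test_that("traced nuclei need strictly more than 50 um^2", {
  st <- stack_with_regions(c(49, 50, 51))
  nuc <- segment_nuclei(st)
  expect_equal(nrow(nuc$cells), 3L)
  expect_equal(sum(nuc$cells$traced), 1L)
  expect_equal(nuc$cells$area_um2[nuc$cells$traced], 51)
})

test_that("an empty field yields an empty nucleus set", {
  st <- channel_stack(list(hoechst = matrix(0, 100, 100)), 0.5)
  nuc <- segment_nuclei(st)
  expect_equal(nrow(nuc$cells), 0L)
  expect_error(
    segment_nuclei(channel_stack(list(tubb3 = matrix(0, 10, 10)), 1)),
    class = "neurophenor_invalid_config"
  )
})

test_that("pyknotic nuclei (small, bright) are excluded from tracing", {
  cfg <- field_sim_config(seed = 5, width_px = 800, height_px = 800,
    n_cells = 80, pyknotic_fraction = 0.2, n_neurites = 0,
    n_syni = 0, n_psd95 = 0
  )
  fs <- render_synthetic_field(cfg)
  nuc <- segment_nuclei(fs$stack)
  expect_equal(sum(nuc$cells$traced), sum(!fs$truth$cells$pyknotic))
  expect_equal(sum(nuc$cells$pyknotic), sum(fs$truth$cells$pyknotic))
})

test_that("traced count is monotone non-increasing in the area cutoff", {
  cfg <- field_sim_config(seed = 6, width_px = 600, height_px = 600,
    n_cells = 40, n_neurites = 0, n_syni = 0, n_psd95 = 0
  )
  fs <- render_synthetic_field(cfg)
  counts <- vapply(
    c(20, 50, 80, 110),
    function(a) sum(segment_nuclei(fs$stack, area_min_um2 = a)$cells$traced),
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("region expansion grows area by 50% and never merges labels", {
  # isolated disc nucleus at fine resolution
  img <- matrix(0, 220, 220)
  img[(row(img) - 110)^2 + (col(img) - 110)^2 <= 45^2] <- 0.5
  nuc <- segment_nuclei(channel_stack(list(hoechst = img), 0.2))
  reg <- expand_regions(nuc)
  expect_equal(reg$cells$area_ratio, 1.5, tolerance = 0.05)
  expect_true(all(reg$labels[nuc$labels > 0] == nuc$labels[nuc$labels > 0]))

  # zero expansion leaves the nuclei untouched
  reg0 <- expand_regions(nuc, expansion_fraction = 0)
  expect_identical(reg0$labels, reg0$nucleus_labels)

  # two nearby nuclei expand competitively without overlap
  img2 <- matrix(0, 200, 260)
  img2[(row(img2) - 100)^2 + (col(img2) - 100)^2 <= 30^2] <- 0.5
  img2[(row(img2) - 100)^2 + (col(img2) - 175)^2 <= 30^2] <- 0.5
  nuc2 <- segment_nuclei(channel_stack(list(hoechst = img2), 0.2))
  expect_equal(sum(nuc2$cells$traced), 2L)
  reg2 <- expand_regions(nuc2)
  expect_equal(sort(unique(as.integer(reg2$labels[reg2$labels > 0]))),
    sort(nuc2$cells$label[nuc2$cells$traced])
  )
  expect_true(all(reg2$cells$area_ratio >= 1.4 & reg2$cells$area_ratio <= 1.55))
})

test_that("marker fractions are recovered within binomial 3 sigma", {
  cfg <- field_sim_config(seed = 8, width_px = 900, height_px = 900,
    n_cells = 120, pyknotic_fraction = 0, n_neurites = 0, n_syni = 0,
    n_psd95 = 0, p_tubb3 = 0.8, p_map2 = 0.6, p_neun = 0.5
  )
  fs <- render_synthetic_field(cfg)
  reg <- expand_regions(segment_nuclei(fs$stack))
  sc <- score_markers(reg, fs$stack)
  ct <- fs$truth$cells
  n <- nrow(ct)
  expect_lt(
    abs(sc$fractions$tubb3_per_ho - mean(ct$tubb3)),
    3 * sqrt(0.8 * 0.2 / n)
  )
  expect_lt(
    abs(sc$fractions$map2_per_tubb3 - sum(ct$map2) / sum(ct$tubb3)),
    3 * sqrt(0.6 * 0.4 / sum(ct$tubb3))
  )
  expect_lt(
    abs(sc$fractions$neun_per_tubb3 - sum(ct$neun) / sum(ct$tubb3)),
    3 * sqrt(0.5 * 0.5 / sum(ct$tubb3))
  )
})

test_that("blank marker channels give zero fractions; saturated give one", {
  img <- matrix(0, 200, 200)
  img[(row(img) - 60)^2 + (col(img) - 60)^2 <= 12^2] <- 0.5
  img[(row(img) - 140)^2 + (col(img) - 140)^2 <= 12^2] <- 0.5
  blank <- matrix(0, 200, 200)
  st <- channel_stack(
    list(hoechst = img, tubb3 = blank, map2 = blank, neun = blank), 1
  )
  reg <- expand_regions(segment_nuclei(st))
  sc <- score_markers(reg, st)
  expect_equal(sc$fractions$tubb3_per_ho, 0)
  expect_true(is.na(sc$fractions$map2_per_tubb3))

  # marker signal in every cell: both conditional fractions reach one
  full <- matrix(0, 200, 200)
  full[img > 0] <- 0.8
  st2 <- channel_stack(
    list(hoechst = img, tubb3 = full, map2 = full, neun = full), 1
  )
  sc2 <- score_markers(expand_regions(segment_nuclei(st2)), st2)
  expect_equal(sc2$fractions$tubb3_per_ho, 1)
  expect_equal(sc2$fractions$map2_per_tubb3, 1)
})

test_that("neurite length is recovered within 5% and is additive", {
  cfg <- field_sim_config(seed = 23, width_px = 900, height_px = 900,
    n_cells = 10, n_neurites = 4, neurite_length_um = 120,
    n_syni = 0, n_psd95 = 0
  )
  fs <- render_synthetic_field(cfg)
  expect_gt(fs$truth$n_neurites_drawn, 0)
  len <- measure_neurite_length(fs$stack)
  expect_equal(len, fs$truth$neurite_length_um, tolerance = 0.05)

  blank <- channel_stack(list(tubb3 = matrix(0, 100, 100)), 0.5)
  expect_equal(measure_neurite_length(blank), 0)
})

test_that("skeletonization reduces thick lines to unit-width paths of correct length", {
  mask <- matrix(FALSE, 60, 240)
  mask[30:34, 20:219] <- TRUE
  sk <- skeletonize(mask)
  expect_lte(max(rowSums(sk)[rowSums(sk) > 0]), 200)
  horiz_len <- neurophenor:::skeleton_length_px(sk)
  expect_equal(horiz_len, 199, tolerance = 0.07)

  diag_mask <- matrix(FALSE, 260, 260)
  for (i in 1:200) {
    diag_mask[max(1, 18 + i - 2):(18 + i + 2), max(1, 18 + i - 2):(18 + i + 2)] <- TRUE
  }
  dlen <- neurophenor:::skeleton_length_px(skeletonize(diag_mask))
  expect_equal(dlen, 200 * sqrt(2), tolerance = 0.07)
})

test_that("synaptic area per neurite matches construction and doubles with punctum count", {
  base <- field_sim_config(seed = 31, width_px = 900, height_px = 900,
    n_cells = 10, n_neurites = 5, neurite_length_um = 120,
    n_syni = 25, n_psd95 = 0, punctum_radius_px = 2
  )
  fs <- render_synthetic_field(base)
  res <- synaptic_area_per_neurite(fs$stack, "syni")
  truth_ratio <- fs$truth$syni_on_tubb3_um2 / fs$truth$neurite_length_um
  expect_equal(res$area_per_um, truth_ratio, tolerance = 0.05)

  dbl <- base
  dbl$n_syni <- 50L
  fs2 <- render_synthetic_field(dbl)
  res2 <- synaptic_area_per_neurite(fs2$stack, "syni")
  expect_equal(res2$area_um2 / res$area_um2, 2, tolerance = 0.1)

  # puncta placed away from any Tubb3 signal contribute nothing
  off <- field_sim_config(seed = 32, width_px = 900, height_px = 900,
    n_cells = 10, n_neurites = 5, neurite_length_um = 120,
    n_syni = 25, n_psd95 = 0, puncta_on_neurite = FALSE
  )
  fs3 <- render_synthetic_field(off)
  res3 <- synaptic_area_per_neurite(fs3$stack, "syni")
  expect_equal(res3$area_um2, 0)
})

test_that("CellROX positivity is scored among Tubb3+ cells only", {
  cfg <- field_sim_config(seed = 41, width_px = 900, height_px = 900,
    n_cells = 110, pyknotic_fraction = 0, n_neurites = 0, n_syni = 0,
    n_psd95 = 0, p_tubb3 = 0.8, p_cellrox = 0.25
  )
  fs <- render_synthetic_field(cfg)
  reg <- expand_regions(segment_nuclei(fs$stack))
  frac <- cellrox_fraction(reg, fs$stack)
  ct <- fs$truth$cells
  truth <- sum(ct$cellrox) / sum(ct$tubb3)
  expect_lt(abs(frac - truth), 3 * sqrt(0.25 * 0.75 / sum(ct$tubb3)))

  # CellROX signal only in Tubb3- cells counts as zero by definition
  img <- matrix(0, 200, 200)
  img[(row(img) - 60)^2 + (col(img) - 60)^2 <= 12^2] <- 0.5
  img[(row(img) - 140)^2 + (col(img) - 140)^2 <= 12^2] <- 0.5
  tubb3 <- matrix(0, 200, 200)
  tubb3[(row(img) - 60)^2 + (col(img) - 60)^2 <= 16^2] <- 0.7
  crox <- matrix(0, 200, 200)
  crox[(row(img) - 140)^2 + (col(img) - 140)^2 <= 16^2] <- 0.7
  st <- channel_stack(list(hoechst = img, tubb3 = tubb3, cellrox = crox), 1)
  reg2 <- expand_regions(segment_nuclei(st))
  expect_equal(cellrox_fraction(reg2, st), 0)
})

test_that("rendered fields are deterministic under a fixed seed", {
  cfg <- field_sim_config(seed = 50, width_px = 300, height_px = 300,
    n_cells = 10, n_neurites = 2, n_syni = 5, n_psd95 = 5
  )
  a <- render_synthetic_field(cfg)
  b <- render_synthetic_field(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)
})
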