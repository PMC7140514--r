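test_that("respiration metrics follow the closed-form definitions", {
  prof <- simulate_ocr_profile(ocr_sim_config(noise_sd = 0))$profile
  m <- compute_respiration_metrics(prof)
  expect_equal(m$basal, 80)
  expect_equal(m$maximal, 130)
  expect_equal(m$spare, 1.625)
  expect_equal(
    compute_respiration_metrics(prof, spare_as_percent = TRUE)$spare, 162.5
  )

  # zero-noise profile reproduces the 12 plateau values exactly
  expect_equal(prof$ocr, rep(c(100, 40, 150, 20), each = 3))
  expect_identical(
    prof,
    simulate_ocr_profile(ocr_sim_config(noise_sd = 0))$profile
  )
})

test_that("no mitochondrial respiration yields basal 0 and undefined spare", {
  prof <- simulate_ocr_profile(ocr_sim_config(
    plateaus = c(baseline = 100, oligomycin = 100, fccp = 100, rot_aa = 100),
    noise_sd = 0
  ))$profile
  m <- compute_respiration_metrics(prof)
  expect_equal(m$basal, 0)
  expect_true(is.na(m$spare))
})

test_that("metrics are invariant to an additive OCR offset", {
  prof <- simulate_ocr_profile(ocr_sim_config(seed = 3, noise_sd = 2))$profile
  m0 <- compute_respiration_metrics(prof)
  shifted <- dplyr::mutate(prof, ocr = ocr + 37.5)
  m1 <- compute_respiration_metrics(shifted)
  expect_equal(m1$basal, m0$basal)
  expect_equal(m1$maximal, m0$maximal)
  expect_equal(m1$spare, m0$spare)
})

test_that("noisy metrics stay within the propagated error bound", {
  sigma <- 2
  errs <- vapply(1:200, function(i) {
    prof <- simulate_ocr_profile(ocr_sim_config(seed = i, noise_sd = sigma))$profile
    compute_respiration_metrics(prof)$basal - 80
  }, numeric(1))
  # basal = single baseline draw - mean of 3: SD = sigma * sqrt(1 + 1/3)
  expect_lt(abs(mean(errs)), 3 * sigma * sqrt(4 / 3) / sqrt(200))
  expect_lt(sd(errs), sigma * sqrt(4 / 3) * 1.25)
})

test_that("cell-count normalisation scales rates but not the spare ratio", {
  m <- compute_respiration_metrics(
    simulate_ocr_profile(ocr_sim_config(noise_sd = 0))$profile
  )
  n1 <- normalize_by_cells(m) # 4000 cells from config
  expect_equal(n1$basal_per_1k, 20)
  expect_equal(n1$spare, m$spare)
  n2 <- normalize_by_cells(m, cells = 8000)
  expect_equal(n2$basal_per_1k, 10)
  expect_error(normalize_by_cells(m, cells = 0), class = "neurophenor_invalid_config")
})

test_that("missing phases and malformed configs error", {
  prof <- simulate_ocr_profile(ocr_sim_config())$profile
  expect_error(
    compute_respiration_metrics(dplyr::filter(prof, phase != "fccp")),
    class = "neurophenor_invalid_config"
  )
  expect_error(
    ocr_sim_config(plateaus = c(baseline = 1, oligomycin = 2, fccp = 3)),
    class = "neurophenor_invalid_config"
  )
})

test_that("ddCt recovers configured fold changes exactly at zero noise", {
  fc <- matrix(c(1, 8, 1, 4, 1, 0.5), 3, 2,
    byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), c("ref", "treated"))
  )
  sim <- simulate_assay_tables(assay_sim_config(fold_changes = fc))
  out <- compute_ddct(sim$ct, reference_condition = "ref")
  expect_equal(
    out$fold[out$condition == "treated"][match(c("g1", "g2", "g3"),
      out$gene[out$condition == "treated"]
    )],
    c(8, 4, 0.5)
  )
  expect_equal(out$minus_ddct[out$gene == "g1" & out$condition == "treated"], 3)
  expect_true(all(out$minus_ddct[out$condition == "ref"] == 0))
  expect_true(all(out$fold[out$condition == "ref"] == 1))

  m <- expression_matrix(out)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["g2", "treated"], 2)
})

test_that("ddCt requires the reference gene in every sample", {
  sim <- simulate_assay_tables(assay_sim_config())
  expect_error(
    compute_ddct(dplyr::filter(sim$ct, gene != "ActB")),
    class = "neurophenor_invalid_config"
  )
  dropped <- dplyr::filter(
    sim$ct,
    !(gene == "ActB" & condition == "ngn2_d20" & replicate == 1)
  )
  expect_error(compute_ddct(dropped), class = "neurophenor_invalid_config")
})

test_that("ELISA normalisation divides by protein and the 42/40 ratio is invariant", {
  tab <- tibble::tibble(
    sample = c("a", "b", "c"),
    ab40 = c(100, 120, 50),
    ab42 = c(10, 12, 25),
    protein_ug = c(2, 3, 0)
  )
  out <- normalize_elisa(tab)
  expect_equal(out$ab40_per_ug[1], 50)
  expect_equal(out$ratio_42_40, c(0.1, 0.1, 0.5))
  expect_false(out$valid[3])
  expect_true(is.na(out$ab40_per_ug[3]))
  # ratio computed on raw concentrations, so protein scaling cannot move it
  out2 <- normalize_elisa(dplyr::mutate(tab, protein_ug = protein_ug * 10))
  expect_equal(out2$ratio_42_40, out$ratio_42_40)
})

test_that("simulated ELISA tables carry the configured ground-truth ratio", {
  sim <- simulate_assay_tables(assay_sim_config(
    ab40_pg_ml = 100, ab42_pg_ml = 10, elisa_cv = 0
  ))
  out <- normalize_elisa(sim$elisa)
  expect_equal(out$ratio_42_40, sim$truth$ab42_40_ratio)
})
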