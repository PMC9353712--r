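test_that("a zero-amplitude, zero-noise gene is exactly flat", {
  p <- cosinor_params("flat", baseline = 5, amplitude = 0, noise_sd = 0)
  tc <- generate_timecourse(p, sampling_design(), seed = 1)
  expect_true(all(tc_values(tc) == 5))
})

test_that("equal seeds give bitwise-identical matrices, different seeds not", {
  p <- cosinor_params(sprintf("g%d", 1:5), baseline = 10, amplitude = 3,
                      phase = c(0, 5, 10, 15, 20), noise_sd = 1)
  a <- generate_timecourse(p, seed = 42)
  b <- generate_timecourse(p, seed = 42)
  c <- generate_timecourse(p, seed = 43)
  expect_identical(a, b)
  expect_false(identical(tc_values(a), tc_values(c)))
})

test_that("a noiseless cosine peaks at its planted phase", {
  p <- cosinor_params("g", baseline = 5, amplitude = 2, phase = 6,
                      noise_sd = 0)
  tc <- generate_timecourse(p, seed = 1)
  v <- tc_values(tc)
  expect_equal(tc_zt(tc)[which.max(v)], 6)
})

test_that("non-finite or invalid parameters are rejected with the feature id", {
  expect_error(cosinor_params(c("ok", "bad"), baseline = c(5, NaN),
                              amplitude = 1, noise_sd = 0),
               "bad")
  expect_error(cosinor_params("neg", baseline = 5, amplitude = -1), "neg")
  expect_error(cosinor_params("big", baseline = 2, amplitude = 3), "big")
  expect_error(cosinor_params("per", baseline = 5, amplitude = 1,
                              period = 12), "per")
})

test_that("values are truncated at zero, never negative", {
  p <- cosinor_params("g", baseline = 1, amplitude = 1, noise_sd = 5)
  tc <- generate_timecourse(p, seed = 7)
  expect_true(all(tc_values(tc) >= 0))
})

test_that("inherited mature RNA copies the transcription phase plus delay", {
  genes <- sprintf("g%02d", 1:10)
  phases <- seq(0, 22.5, by = 2.5)
  lp <- dplyr::bind_rows(
    tibble::tibble(feature = genes, layer = "transcription", baseline = 10,
                   amplitude = 4, phase = phases, period = 24, noise_sd = 0,
                   rhythm_source = "layer_specific"),
    tibble::tibble(feature = genes, layer = "mature_rna", baseline = 10,
                   amplitude = 4, phase = 0, period = 24, noise_sd = 0,
                   rhythm_source = "inherited")
  )
  truth <- multilayer_truth(lp, delay = 3)
  bundle <- generate_multilayer(truth, seed = 1)
  rna <- bundle$resolved[bundle$resolved$layer == "mature_rna", ]
  expect_equal(rna$phase[match(genes, rna$feature)], (phases + 3) %% 24)
  # and the generated series actually peak there (zero noise, grid phases)
  v <- tc_values(bundle$layers$mature_rna)
  zt <- tc_zt(bundle$layers$mature_rna)
  on_grid <- ((phases + 3) %% 24) %in% zt
  peak <- zt[apply(v, 1, which.max)]
  expect_equal(peak[on_grid], ((phases + 3) %% 24)[on_grid])
})

test_that("a layer-specific translation-rate rhythm makes protein cycle while RNA stays flat", {
  g <- "g1"
  lp <- dplyr::bind_rows(
    tibble::tibble(feature = g, layer = "transcription", baseline = 10,
                   amplitude = 0, phase = 0, period = 24, noise_sd = 0.3,
                   rhythm_source = "none"),
    tibble::tibble(feature = g, layer = "mature_rna", baseline = 10,
                   amplitude = 0, phase = 0, period = 24, noise_sd = 0.3,
                   rhythm_source = "none"),
    tibble::tibble(feature = g, layer = "te", baseline = 1, amplitude = 0.5,
                   phase = 9, period = 24, noise_sd = 0.02,
                   rhythm_source = "layer_specific"),
    tibble::tibble(feature = g, layer = "protein", baseline = 10,
                   amplitude = 0, phase = 0, period = 24, noise_sd = 0.3,
                   rhythm_source = "inherited")
  )
  bundle <- generate_multilayer(multilayer_truth(lp), seed = 2)
  fit_prot <- tidy(jtk(bundle$layers$protein))
  fit_rna <- tidy(jtk(bundle$layers$mature_rna))
  expect_true(fit_prot$rhythmic)
  expect_false(fit_rna$rhythmic)
})

test_that("contradictory coupling flags are rejected", {
  base <- tibble::tibble(feature = "g", baseline = 10, amplitude = 0,
                         phase = 0, period = 24, noise_sd = 0,
                         rhythm_source = "none")
  # inherited with a flat upstream layer
  lp <- dplyr::bind_rows(
    dplyr::mutate(base, layer = "transcription"),
    dplyr::mutate(base, layer = "mature_rna", rhythm_source = "inherited")
  )
  expect_error(multilayer_truth(lp), "no upstream rhythm")
  # inherited on a layer with no upstream at all
  expect_error(
    multilayer_truth(dplyr::mutate(base, layer = "transcription",
                                   rhythm_source = "inherited")),
    "without an upstream"
  )
  # "none" claiming an amplitude
  expect_error(
    multilayer_truth(dplyr::mutate(base, layer = "transcription",
                                   amplitude = 2)),
    "none"
  )
})

test_that("pairing maps with unknown ids are rejected; empty maps are fine", {
  lp <- tibble::tibble(feature = "g1", layer = "transcription",
                       baseline = 10, amplitude = 2, phase = 0, period = 24,
                       noise_sd = 0, rhythm_source = "layer_specific")
  expect_error(
    multilayer_truth(lp, enhancer_gene_pairs =
                       tibble::tibble(enhancer = "eX", gene = "g1")),
    "eX"
  )
  truth <- multilayer_truth(lp)
  expect_s3_class(generate_multilayer(truth, seed = 1), "layer_bundle")
  expect_equal(nrow(truth$enhancer_gene_pairs), 0)
})

test_that("truth_table reflects the planted flags losslessly", {
  b <- simulate_study(n_conserved = 4, n_disrupted = 2, n_enhanced = 2,
                      n_null = 2, n_erna = 6, n_triads = 2, seed = 5)
  tt <- truth_table(b$truth)
  lp <- b$truth$layer_params
  expect_setequal(tt$feature,
                  unique(lp$feature[grepl("^g", lp$feature)]))
  # spot-check categories against the raw flags
  for (i in seq_len(nrow(tt))) {
    up <- tt$rhythmic_mature_rna[i]
    down <- tt$rhythmic_protein[i]
    expected <- if (up && down) "conserved" else if (up) "disrupted"
                else if (down) "enhanced" else "neither"
    expect_identical(tt$category_mature_rna_protein[i], expected)
  }
  # phosphosites only on the planted genes
  planted <- b$truth$phospho$feature[b$truth$phospho$phospho_present]
  expect_setequal(tt$feature[tt$phospho_present], planted)
  # empty truth gives an empty table
  empty <- multilayer_truth(
    tibble::tibble(feature = "e1", layer = "erna", baseline = 5,
                   amplitude = 1, phase = 0, period = 24, noise_sd = 0,
                   rhythm_source = "layer_specific"))
  expect_equal(nrow(truth_table(empty)), 0)
})

test_that("whole bundles are deterministic under a fixed seed", {
  a <- simulate_study(n_conserved = 3, n_disrupted = 2, n_enhanced = 2,
                      n_null = 1, n_erna = 5, n_triads = 1, seed = 11)
  b <- simulate_study(n_conserved = 3, n_disrupted = 2, n_enhanced = 2,
                      n_null = 1, n_erna = 5, n_triads = 1, seed = 11)
  expect_identical(lapply(a$layers, tc_values), lapply(b$layers, tc_values))
  expect_identical(a$truth$layer_params, b$truth$layer_params)
})

test_that("coverage generation follows expression, strand and bounds", {
  genes <- toy_genes()
  design <- sampling_design(timepoints = c(0, 12))
  ex <- timecourse(genes$id,
                   matrix(c(5, 5,    # long_p
                            0, 0,    # mid_p: silent
                            2, 4,    # short_p
                            3, 3),   # long_m
                          nrow = 4, byrow = TRUE),
                   design)
  dir <- withr::local_tempdir()
  cov <- generate_coverage(genes, ex, design, seed = 3, dir = dir,
                           reads_per_unit = 10)
  long <- read_coverage_set(cov$coverage_files)
  # silent gene: no coverage over its window
  w <- gene_body_window(genes)
  mid <- w[w$id == "mid_p", ]
  in_mid <- long$strand == "+" & long$start < mid$end & long$end > mid$start
  expect_equal(sum(long$value[in_mid]), 0)
  # minus-strand gene appears only in the minus-strand files
  wm <- w[w$id == "long_m", ]
  in_wm <- long$start < wm$end & long$end > wm$start
  expect_true(all(long$strand[in_wm] == "-"))
  # placed read counts follow expression exactly (round(expr * rpu))
  expect_equal(cov$totals$placed, c(10 * (5 + 0 + 2 + 3), 10 * (5 + 0 + 4 + 3)))
  # out-of-bounds gene rejected
  bad <- gene_model("far", "chrT", "+", tss = 9.9e6, tes = 2e7)
  expect_error(generate_coverage(bad, timecourse("far", matrix(c(1, 1), 1),
                                                 design),
                                 design, seed = 1, dir = dir),
               "far")
})
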