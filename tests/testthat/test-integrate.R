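calls <- function(ids, flags) tibble::tibble(feature = ids, rhythmic = flags)

test_that("detection_filter keeps features detected in every dataset", {
  d <- sampling_design(timepoints = c(0, 12))
  m1 <- timecourse(c("a", "b", "c"), matrix(c(5, 5, 5, 5, 5, 5), 3), d)
  m2 <- timecourse(c("a", "b"), matrix(c(5, 5, 5, 5), 2), d)
  m3 <- timecourse(c("a", "b", "c"), matrix(c(5, 5, 0, 0, 5, 5), 3,
                                            byrow = TRUE), d)
  # b fails the floor in m3 (mean 0), c absent from m2
  expect_setequal(detection_filter(list(m1, m2, m3)), "a")
  # identical matrices: identity on detected features
  expect_setequal(detection_filter(list(m1, m1, m1)), c("a", "b", "c"))
  expect_warning(
    out <- detection_filter(list(m1, timecourse("z", matrix(c(1, 1), 1), d))),
    "empty"
  )
  expect_length(out, 0)
})

test_that("classify_pair applies the definitional category map and fraction", {
  up <- calls(c("a", "b", "c", "d"), c(TRUE, TRUE, FALSE, FALSE))
  down <- calls(c("a", "b", "c", "d"), c(TRUE, FALSE, TRUE, FALSE))
  cp <- classify_pair(up, down)
  expect_equal(cp$category,
               c("conserved", "disrupted", "enhanced", "neither"))
  g <- glance(cp)
  expect_equal(g$n, 4L)
  expect_equal(g$conserved_fraction, 0.5)
  # 6 conserved + 4 disrupted -> 0.60
  up2 <- calls(sprintf("g%d", 1:10), rep(TRUE, 10))
  down2 <- calls(sprintf("g%d", 1:10), c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(conserved_fraction(classify_pair(up2, down2)), 0.6)
  # empty intersection: empty comparison, fraction missing
  cp0 <- classify_pair(calls("x", TRUE), calls("y", TRUE))
  expect_equal(nrow(cp0), 0)
  expect_true(is.na(conserved_fraction(cp0)))
})

test_that("genes missing a call in either layer are excluded with a message", {
  up <- calls(c("a", "b"), c(TRUE, TRUE))
  down <- calls("a", TRUE)
  expect_message(cp <- classify_pair(up, down, detected_both = c("a", "b")),
                 "excluded")
  expect_equal(cp$feature, "a")
})

test_that("categories always partition the detected-in-both set", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    ids <- sprintf("g%d", seq_len(n))
    cp <- classify_pair(calls(ids, sample(c(TRUE, FALSE), n, TRUE)),
                        calls(ids, sample(c(TRUE, FALSE), n, TRUE)))
    g <- glance(cp)
    expect_equal(g$conserved + g$disrupted + g$enhanced + g$neither, g$n)
    if (!is.na(g$conserved_fraction)) {
      expect_gte(g$conserved_fraction, 0)
      expect_lte(g$conserved_fraction, 1)
    }
  }
})

test_that("adding a conserved gene never decreases the conserved fraction", {
  ids <- sprintf("g%d", 1:9)
  up_f <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  dn_f <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  base <- conserved_fraction(classify_pair(calls(ids, up_f), calls(ids, dn_f)))
  plus <- conserved_fraction(classify_pair(calls(c(ids, "new"), c(up_f, TRUE)),
                                           calls(c(ids, "new"), c(dn_f, TRUE))))
  expect_gte(plus, base)
})

test_that("TE variation separates planted high- and low-CV groups", {
  d <- sampling_design()
  zt <- seq(0, 21, 3)
  n <- 50
  set.seed(5)
  low <- t(sapply(1:n, function(i) 2 + rnorm(8, 0, 0.1)))   # CV ~ 0.05
  high <- t(sapply(1:n, function(i) pmax(2 + 2 * cos(2 * pi * (zt - runif(1, 0, 24)) / 24) +
                                           rnorm(8, 0, 0.3), 0.01)))  # CV ~ 0.5
  te <- timecourse(c(sprintf("c%d", 1:n), sprintf("d%d", 1:n)),
                   rbind(low, high), d, unit = "ratio")
  tv <- te_variation_compare(te, sprintf("c%d", 1:n), sprintf("d%d", 1:n))
  expect_lt(tv$mean_cv_conserved, tv$mean_cv_disrupted)
  expect_lt(tv$p, 0.01)
  g <- glance(tv)
  expect_named(g, c("mean_cv_conserved", "mean_cv_disrupted", "t", "p"))
})

test_that("TE variation handles identical groups and constant series", {
  d <- sampling_design(timepoints = c(0, 6, 12, 18))
  te <- timecourse(c("a", "b", "c"),
                   matrix(c(1, 2, 1, 2,
                            1, 2, 1, 2,
                            3, 3, 3, 3), 3, byrow = TRUE), d, unit = "ratio")
  tv <- te_variation_compare(te, c("a", "b"), c("a", "b"))
  expect_equal(tv$t, 0)
  expect_equal(tv$p, 1)
  # constant TE has CV zero
  tvc <- tidy(te_variation_compare(te, c("c", "a"), c("a", "b")))
  expect_equal(tvc$cv[tvc$feature == "c"], 0)
  expect_error(te_variation_compare(te, "a", c("a", "b")), "at least 2")
})

test_that("translation attribution counts rhythmic-TE genes, tracking unknowns", {
  te_calls <- tibble::tibble(feature = sprintf("g%d", 1:20),
                             adj_p = c(rep(0.01, 9), rep(0.5, 11)))
  at <- attribute_translation(sprintf("g%d", 1:20), te_calls)
  expect_equal(at$fraction, 0.45)
  # empty analyzed set: fraction missing
  at0 <- attribute_translation(character(0), te_calls)
  expect_true(is.na(at0$fraction))
  # genes without TE data drop out of the denominator
  expect_message(
    at2 <- attribute_translation(c("g1", "g2", "gX"), te_calls),
    "lack usable"
  )
  expect_equal(at2$fraction, 1)
  expect_equal(glance(at2)$unknown, 1L)
})

test_that("phosphorylation attribution is binary phosphosite presence", {
  det <- tibble::tibble(feature = sprintf("d%d", 1:8),
                        detected = c(rep(TRUE, 5), rep(FALSE, 3)))
  at <- attribute_phosphorylation(sprintf("d%d", 1:8), det)
  expect_equal(at$fraction, 0.625)
  at0 <- attribute_phosphorylation(sprintf("d%d", 6:8), det)
  expect_equal(at0$fraction, 0)
  expect_message(
    atm <- attribute_phosphorylation(c("d1", "zz"), det),
    "not phosphorylated"
  )
  expect_equal(atm$fraction, 0.5)
})

test_that("triads require both links and all three rhythmic members", {
  dbp <- calls(c("D1", "D2"), c(TRUE, TRUE))
  erna <- calls(c("E1", "E2"), c(TRUE, FALSE))
  txn <- calls(c("G1", "G2"), c(TRUE, TRUE))
  de <- tibble::tibble(dbp = c("D1", "D2"), enhancer = c("E1", "E2"))
  eg <- tibble::tibble(enhancer = c("E1", "E2"), gene = c("G1", "G2"))
  tr <- link_triads(dbp, erna, txn, de, eg)
  expect_equal(nrow(tr), 1)
  expect_equal(unlist(tr[1, ]), c(dbp = "D1", enhancer = "E1", gene = "G1"))
  # non-rhythmic enhancer breaks the triad (E2 row absent above);
  # dangling ids are rejected by name
  expect_error(
    link_triads(dbp, erna, txn,
                tibble::tibble(dbp = "DX", enhancer = "E1"), eg),
    "DX"
  )
})

test_that("nearest-TSS pairing respects the distance cap", {
  genes <- gene_model(c("g1", "g2"), "chrT", "+", tss = c(10000, 500000),
                      tes = c(20000, 520000))
  enh <- tibble::tibble(id = c("e_near", "e_far"), chrom = "chrT",
                        center = c(15000, 250000))
  pairs <- pair_enhancers_to_genes(enh, genes, max_dist = 1e5)
  expect_equal(pairs$enhancer, "e_near")
  expect_equal(pairs$gene, "g1")
})

test_that("planted cross-layer structure is recovered on a low-noise bundle", {
  b <- simulate_study(n_conserved = 40, n_disrupted = 20, n_enhanced = 20,
                      n_null = 20, n_erna = 20, n_triads = 6,
                      noise_sd = 0.6, te_noise_sd = 0.03, seed = 21)
  thr <- default_layer_thresholds()
  fits <- lapply(stats::setNames(nm = names(b$layers)), function(ly) {
    jtk(b$layers[[ly]], threshold = thr[[ly]])
  })
  tt <- truth_table(b$truth)
  pairs <- list(c("transcription", "mature_rna"),
                c("mature_rna", "protein"),
                c("protein", "dbp"))
  for (pr in pairs) {
    cp <- classify_pair(fits[[pr[1]]], fits[[pr[2]]])
    truth_col <- tt[[paste0("category_", pr[1], "_", pr[2])]]
    agree <- mean(cp$category == truth_col[match(cp$feature, tt$feature)])
    expect_gt(agree, 0.9)
    planted_cf <- {
      cat <- truth_col
      sum(cat == "conserved") /
        (sum(cat == "conserved") + sum(cat == "disrupted"))
    }
    expect_lt(abs(conserved_fraction(cp) - planted_cf), 0.05)
  }
  # mechanism attributions recover the planted fractions
  cp2 <- classify_pair(fits$mature_rna, fits$protein)
  prot_specific <- cp2$feature[cp2$category == "enhanced"]
  at_te <- attribute_translation(prot_specific, fits$te)
  planted_te <- mean(tt$te_dependent[tt$category_mature_rna_protein ==
                                       "enhanced"])
  expect_lt(abs(at_te$fraction - planted_te), 0.15)
  cp3 <- classify_pair(fits$protein, fits$dbp)
  dbp_specific <- cp3$feature[cp3$category == "enhanced"]
  at_ph <- attribute_phosphorylation(dbp_specific, b$phospho_detect)
  planted_ph <- mean(tt$phospho_present[tt$category_protein_dbp == "enhanced"])
  expect_lt(abs(at_ph$fraction - planted_ph), 0.15)
  # triads recovered up to per-member detection noise
  tr <- link_triads(fits$dbp, fits$erna, fits$transcription,
                    b$truth$dbp_enhancer_pairs, b$truth$enhancer_gene_pairs)
  expect_gte(nrow(tr), 5)
  expect_lte(nrow(tr), 6)
  expect_true(all(tr$dbp %in% tt$feature[tt$rhythmic_dbp]))
})

test_that("at near-zero noise exactly the planted triads are recovered", {
  b <- simulate_study(n_conserved = 10, n_disrupted = 5, n_enhanced = 5,
                      n_null = 5, n_erna = 12, n_triads = 4,
                      noise_sd = 0.2, te_noise_sd = 0.01, seed = 33)
  thr <- default_layer_thresholds()
  fit <- function(ly) jtk(b$layers[[ly]], threshold = thr[[ly]])
  tr <- link_triads(fit("dbp"), fit("erna"), fit("transcription"),
                    b$truth$dbp_enhancer_pairs, b$truth$enhancer_gene_pairs)
  expect_equal(nrow(tr), 4)
  expect_setequal(tr$enhancer, sprintf("e%03d", 1:4))
})
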