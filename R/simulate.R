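# Study-level simulator: plants conserved / disrupted / enhanced cohorts for
# every adjacent layer pair, translation-rate-driven and phosphorylation-
# flagged mechanism genes, and DBP-enhancer-gene triads, then generates the
# coupled bundle.

#' Simulate a complete multi-layer diurnal study with known truth
#'
#' Builds a [multilayer_truth()] with planted cross-layer structure and
#' generates the bundle. For each adjacent layer pair (transcription to
#' mature RNA, mature RNA to protein, protein to DBP activity) a cohort of
#' genes is planted rhythmic in both layers (conserved), only upstream
#' (disrupted) or only downstream (enhanced); since a cohort planted for one
#' pair is flat elsewhere, the realized per-pair category counts follow from
#' the whole table — [truth_table()] is the reference, not the nominal
#' cohort sizes. Genes rhythmic in protein but not mature RNA are split into
#' translation-rate-driven (rhythmic TE, protein inherited as RNA x TE) and
#' independently rhythmic protein; DBP-specific genes get a phosphosite with
#' probability-free planted fractions (deterministic rounding). Triads wire
#' rhythmic DBPs through rhythmic eRNA loci to genes with rhythmic
#' transcription, alongside non-rhythmic decoy pairings.
#'
#' Default oscillation strength is amplitude/noise = 3 with a relative
#' amplitude of 0.3 of baseline.
#'
#' @param n_conserved,n_disrupted,n_enhanced Cohort sizes per adjacent layer
#'   pair.
#' @param n_null Genes flat in every layer.
#' @param n_erna Total eRNA loci (triad members are rhythmic; about 30% of
#'   loci are rhythmic overall, the rest flat).
#' @param n_triads Planted DBP-enhancer-gene triads with all three members
#'   rhythmic.
#' @param te_dependent_frac Fraction of protein-specific rhythmic genes
#'   whose rhythm is carried by the translation rate.
#' @param phospho_dependent_frac Fraction of DBP-specific rhythmic genes
#'   carrying a detected phosphosite.
#' @param baseline,amplitude,noise_sd Cosinor parameters of the abundance
#'   layers.
#' @param te_baseline,te_amplitude,te_noise_sd Cosinor parameters of the
#'   translation-rate layer (ratio scale).
#' @param delay Transcription-to-mature-RNA processing delay in hours.
#' @param design A [sampling_design()].
#' @param seed Integer seed.
#' @return A `layer_bundle` (see [generate_multilayer()]).
#' @export
simulate_study <- function(n_conserved = 200, n_disrupted = 100,
                           n_enhanced = 100, n_null = 100,
                           n_erna = 60, n_triads = 12,
                           te_dependent_frac = 0.45,
                           phospho_dependent_frac = 0.62,
                           baseline = 20, amplitude = 6, noise_sd = 2,
                           te_baseline = 1, te_amplitude = 0.3,
                           te_noise_sd = 0.1,
                           delay = 0,
                           design = sampling_design(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_triads <= n_enhanced, n_triads <= n_conserved,
            n_triads <= n_erna)

  cohorts <- c(rep("C1", n_conserved), rep("D1", n_disrupted),
               rep("E1", n_enhanced),
               rep("C2", n_conserved), rep("D2", n_disrupted),
               rep("E2", n_enhanced),
               rep("C3", n_conserved), rep("D3", n_disrupted),
               rep("E3", n_enhanced),
               rep("N", n_null))
  n_genes <- length(cohorts)
  genes <- sprintf("g%04d", seq_len(n_genes))

  # phases drawn deterministically from the seed, uniform over the cycle
  phases <- withr::with_seed(seed, stats::runif(n_genes, 0, 24))

  ls_row <- function(g, layer, ph, b = baseline, a = amplitude,
                     sd = noise_sd) {
    tibble::tibble(feature = g, layer = layer, baseline = b, amplitude = a,
                   phase = ph, period = 24, noise_sd = sd,
                   rhythm_source = "layer_specific")
  }
  flat_row <- function(g, layer, b = baseline, sd = noise_sd) {
    tibble::tibble(feature = g, layer = layer, baseline = b, amplitude = 0,
                   phase = 0, period = 24, noise_sd = sd,
                   rhythm_source = "none")
  }
  inh_row <- function(g, layer, b = baseline, a = amplitude,
                      sd = noise_sd) {
    tibble::tibble(feature = g, layer = layer, baseline = b, amplitude = a,
                   phase = 0, period = 24, noise_sd = sd,
                   rhythm_source = "inherited")
  }

  # which protein-rhythmic-with-flat-RNA genes run through the TE mechanism
  te_driven <- logical(n_genes)
  for (ch in c("E2", "C3", "D3")) {
    idx <- which(cohorts == ch)
    k <- round(te_dependent_frac * length(idx))
    te_driven[idx[seq_len(k)]] <- TRUE
  }

  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    ph <- phases[i]
    ch <- cohorts[i]
    txn <- if (ch %in% c("C1", "D1")) ls_row(g, "transcription", ph)
           else flat_row(g, "transcription")
    rna <- switch(ch,
      C1 = inh_row(g, "mature_rna"),
      E1 = ls_row(g, "mature_rna", ph),
      C2 = ls_row(g, "mature_rna", ph),
      D2 = ls_row(g, "mature_rna", ph),
      flat_row(g, "mature_rna"))
    te <- if (ch == "D2" || ((ch %in% c("E2", "C3", "D3")) && te_driven[i])) {
      ls_row(g, "te", ph, b = te_baseline, a = te_amplitude,
             sd = te_noise_sd)
    } else {
      flat_row(g, "te", b = te_baseline, sd = te_noise_sd)
    }
    prot <- switch(ch,
      C2 = inh_row(g, "protein"),
      C3 = if (te_driven[i]) inh_row(g, "protein") else ls_row(g, "protein", ph),
      D3 = if (te_driven[i]) inh_row(g, "protein") else ls_row(g, "protein", ph),
      E2 = if (te_driven[i]) inh_row(g, "protein") else ls_row(g, "protein", ph),
      flat_row(g, "protein"))
    dbp <- switch(ch,
      C3 = inh_row(g, "dbp"),
      E3 = ls_row(g, "dbp", ph),
      flat_row(g, "dbp"))
    rows[[i]] <- dplyr::bind_rows(txn, rna, te, prot, dbp)
  }

  # eRNA loci: triad members rhythmic, ~30% rhythmic overall, rest flat
  ernas <- sprintf("e%03d", seq_len(n_erna))
  n_erna_rhythmic <- max(n_triads, round(0.3 * n_erna))
  erna_phases <- withr::with_seed(seed + 1L, stats::runif(n_erna, 0, 24))
  erna_rows <- dplyr::bind_rows(lapply(seq_len(n_erna), function(j) {
    if (j <= n_erna_rhythmic) {
      ls_row(ernas[j], "erna", erna_phases[j], b = baseline / 4,
             a = amplitude / 4, sd = noise_sd / 4)
    } else {
      flat_row(ernas[j], "erna", b = baseline / 4, sd = noise_sd / 4)
    }
  }))

  # phosphosites: a planted fraction of the DBP-specific cohort
  e3 <- genes[cohorts == "E3"]
  n_phos <- round(phospho_dependent_frac * length(e3))
  phospho <- tibble::tibble(
    feature = e3,
    phospho_present = seq_along(e3) <= n_phos
  )
  phos_rows <- dplyr::bind_rows(lapply(e3[seq_len(n_phos)], function(g) {
    flat_row(g, "phospho", b = baseline / 2, sd = noise_sd / 2)
  }))

  # triads: rhythmic DBP (E3) -> rhythmic eRNA -> rhythmic transcription (C1),
  # plus decoy pairings through non-rhythmic members
  dbp_ids <- genes[cohorts == "E3"][seq_len(n_triads)]
  tgt_ids <- genes[cohorts == "C1"][seq_len(n_triads)]
  tri_ernas <- ernas[seq_len(n_triads)]
  flat_ernas <- if (n_erna_rhythmic < n_erna) {
    ernas[(n_erna_rhythmic + 1):n_erna]
  } else {
    character(0)
  }
  n_decoy <- min(length(flat_ernas), 5L, n_disrupted)
  dbp_enhancer_pairs <- dplyr::bind_rows(
    tibble::tibble(dbp = dbp_ids, enhancer = tri_ernas),
    tibble::tibble(dbp = genes[cohorts == "D3"][seq_len(n_decoy)],
                   enhancer = flat_ernas[seq_len(n_decoy)])
  )
  enhancer_gene_pairs <- dplyr::bind_rows(
    tibble::tibble(enhancer = tri_ernas, gene = tgt_ids),
    tibble::tibble(enhancer = flat_ernas[seq_len(n_decoy)],
                   gene = genes[cohorts == "D1"][seq_len(n_decoy)])
  )

  truth <- multilayer_truth(
    layer_params = dplyr::bind_rows(c(rows, list(erna_rows, phos_rows))),
    phospho = phospho,
    enhancer_gene_pairs = enhancer_gene_pairs,
    dbp_enhancer_pairs = dbp_enhancer_pairs,
    delay = delay
  )
  generate_multilayer(truth, design, seed)
}
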