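# Synthetic coupled multi-layer diurnal time courses with known ground truth.
# Layers follow the regulatory cascade transcription -> mature RNA -> protein
# -> DBP activity, with translation rate, eRNA and phosphorylation as the
# mechanistic side channels.

LAYERS <- c("transcription", "mature_rna", "protein", "dbp",
            "erna", "te", "phospho")
CORE_LAYERS <- c("transcription", "mature_rna", "protein", "dbp")
UPSTREAM <- c(mature_rna = "transcription", protein = "mature_rna",
              dbp = "protein")
RHYTHM_SOURCES <- c("inherited", "layer_specific", "none")

#' Default per-layer rhythmicity thresholds
#'
#' Adjusted-p cutoffs used to call a feature rhythmic: 0.05 for the
#' sequencing-based layers (transcription, mature RNA, eRNA, translation
#' rate) and the laxer 0.1 for the mass-spectrometry layers (protein, DBP
#' activity), where fewer timepoints survive detection.
#'
#' @return Named numeric vector of thresholds.
#' @export
default_layer_thresholds <- function() {
  c(transcription = 0.05, mature_rna = 0.05, erna = 0.05, te = 0.05,
    protein = 0.1, dbp = 0.1, phospho = 0.1)
}

#' Cosinor parameters for a set of features
#'
#' One row per feature of the oscillation model
#' `baseline + amplitude * cos(2*pi*(t - phase)/period)` plus additive
#' Gaussian noise truncated at zero.
#'
#' @param feature Character vector of feature ids.
#' @param baseline Mean abundance, > 0.
#' @param amplitude Half peak-to-trough amplitude, `0 <= amplitude <= baseline`
#'   (keeps the expected value positive).
#' @param phase ZT hour of the peak, in `[0, 24)`.
#' @param period Oscillation period in hours, in `[20, 28]`.
#' @param noise_sd Standard deviation of the additive noise, >= 0.
#' @return A tibble with one validated row per feature.
#' @export
cosinor_params <- function(feature, baseline, amplitude, phase = 0,
                           period = 24, noise_sd = 0) {
  p <- tibble::tibble(feature = as.character(feature),
                      baseline = as.numeric(baseline),
                      amplitude = as.numeric(amplitude),
                      phase = as.numeric(phase),
                      period = as.numeric(period),
                      noise_sd = as.numeric(noise_sd))
  validate_cosinor(p)
  p
}

validate_cosinor <- function(p) {
  num <- c("baseline", "amplitude", "phase", "period", "noise_sd")
  bad_finite <- !Reduce(`&`, lapply(p[num], is.finite))
  if (any(bad_finite)) {
    stop("non-finite cosinor parameters for feature(s): ",
         paste(p$feature[bad_finite], collapse = ", "), call. = FALSE)
  }
  bad <- p$baseline <= 0 | p$amplitude < 0 | p$amplitude > p$baseline |
    p$phase < 0 | p$phase >= 24 | p$period < 20 | p$period > 28 |
    p$noise_sd < 0
  if (any(bad)) {
    stop("invalid cosinor parameters for feature(s): ",
         paste(p$feature[bad], collapse = ", "),
         " (need baseline > 0, 0 <= amplitude <= baseline, phase in [0,24), ",
         "period in [20,28], noise_sd >= 0)", call. = FALSE)
  }
  invisible(p)
}

cosinor_mean <- function(p, zt) {
  outer(seq_len(nrow(p)), seq_along(zt),
        function(i, j) p$baseline[i] +
          p$amplitude[i] * cos(2 * pi * (zt[j] - p$phase[i]) / p$period[i]))
}

#' Simulate one omics layer as a cosinor time course
#'
#' Each feature follows its cosinor mean curve with additive Gaussian noise,
#' truncated at zero on the abundance scale. Identical `seed` gives a
#' bitwise-identical table.
#'
#' @param params Cosinor parameter tibble, see [cosinor_params()].
#' @param design A [sampling_design()].
#' @param seed Integer seed; required, so every run is reproducible.
#' @param unit Unit recorded on the resulting table.
#' @return A `tc_tbl` time-course table.
#' @examples
#' p <- cosinor_params("g1", baseline = 5, amplitude = 2, phase = 6)
#' generate_timecourse(p, sampling_design(), seed = 1)
#' @export
generate_timecourse <- function(params, design = sampling_design(), seed,
                                unit = "abundance") {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (nrow(params) == 0) stop("`params` must be non-empty", call. = FALSE)
  validate_cosinor(params)
  st <- sample_times(design)
  mu <- cosinor_mean(params, st$zt)
  withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) *
      params$noise_sd
  })
  timecourse(params$feature, pmax(mu + eps, 0), design, unit = unit)
}

# ---- multi-layer truth ------------------------------------------------------

#' Assemble the ground truth of a coupled multi-layer simulation
#'
#' @param layer_params Long tibble with columns `feature`, `layer` (one of
#'   transcription, mature_rna, protein, dbp, erna, te, phospho), the cosinor
#'   columns of [cosinor_params()], and `rhythm_source` (one of `"inherited"`,
#'   `"layer_specific"`, `"none"`). An `"inherited"` row copies phase and
#'   period from its upstream layer at generation time; `"none"` rows must
#'   have amplitude 0.
#' @param phospho Tibble with `feature` and logical `phospho_present`;
#'   features must exist in `layer_params`.
#' @param enhancer_gene_pairs Tibble `enhancer`, `gene` linking eRNA loci to
#'   target genes.
#' @param dbp_enhancer_pairs Tibble `dbp`, `enhancer` linking DNA-binding
#'   proteins to the enhancers they occupy.
#' @param delay Processing delay in hours added to the phase of an inherited
#'   mature-RNA rhythm (default 0).
#' @return An object of class `multilayer_truth`.
#' @export
multilayer_truth <- function(layer_params,
                             phospho = NULL,
                             enhancer_gene_pairs = NULL,
                             dbp_enhancer_pairs = NULL,
                             delay = 0) {
  lp <- tibble::as_tibble(layer_params)
  needed <- c("feature", "layer", "baseline", "amplitude", "phase", "period",
              "noise_sd", "rhythm_source")
  missing_cols <- setdiff(needed, names(lp))
  if (length(missing_cols)) {
    stop("`layer_params` lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(lp$layer %in% LAYERS)) {
    stop("unknown layer(s): ",
         paste(setdiff(unique(lp$layer), LAYERS), collapse = ", "),
         call. = FALSE)
  }
  if (!all(lp$rhythm_source %in% RHYTHM_SOURCES)) {
    stop("`rhythm_source` must be one of ",
         paste(RHYTHM_SOURCES, collapse = "/"), call. = FALSE)
  }
  validate_cosinor(lp)
  if (anyDuplicated(lp[c("feature", "layer")])) {
    stop("duplicated (feature, layer) rows in `layer_params`", call. = FALSE)
  }

  bad_none <- lp$rhythm_source == "none" & lp$amplitude > 0
  if (any(bad_none)) {
    stop("contradictory flags: rhythm_source \"none\" with amplitude > 0 for ",
         paste(lp$feature[bad_none], collapse = ", "), call. = FALSE)
  }
  bad_ls <- lp$rhythm_source == "layer_specific" & lp$amplitude == 0
  if (any(bad_ls)) {
    stop("contradictory flags: rhythm_source \"layer_specific\" with zero ",
         "amplitude for ", paste(lp$feature[bad_ls], collapse = ", "),
         call. = FALSE)
  }
  inh <- lp[lp$rhythm_source == "inherited", ]
  if (nrow(inh)) {
    no_up <- !inh$layer %in% names(UPSTREAM)
    if (any(no_up)) {
      stop("contradictory flags: layer(s) without an upstream layer marked ",
           "\"inherited\": ",
           paste(unique(inh$layer[no_up]), collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(inh))) {
      up_rhythmic <- layer_is_rhythmic(lp, inh$feature[i],
                                       UPSTREAM[[inh$layer[i]]])
      # protein may also inherit its rhythm from the translation rate
      if (inh$layer[i] == "protein" && !up_rhythmic) {
        up_rhythmic <- layer_is_rhythmic(lp, inh$feature[i], "te")
      }
      if (!up_rhythmic) {
        stop("contradictory flags: \"inherited\" with no upstream rhythm for ",
             inh$feature[i], " (", inh$layer[i], ")", call. = FALSE)
      }
    }
  }

  genes <- unique(lp$feature[lp$layer %in% CORE_LAYERS])
  ernas <- unique(lp$feature[lp$layer == "erna"])
  phospho <- phospho %||%
    tibble::tibble(feature = character(), phospho_present = logical())
  enhancer_gene_pairs <- enhancer_gene_pairs %||%
    tibble::tibble(enhancer = character(), gene = character())
  dbp_enhancer_pairs <- dbp_enhancer_pairs %||%
    tibble::tibble(dbp = character(), enhancer = character())

  check_ids <- function(ids, universe, what) {
    dangling <- setdiff(ids, universe)
    if (length(dangling)) {
      stop(what, " reference unknown id(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  check_ids(phospho$feature, genes, "`phospho` rows")
  check_ids(enhancer_gene_pairs$enhancer, ernas, "`enhancer_gene_pairs`")
  check_ids(enhancer_gene_pairs$gene, genes, "`enhancer_gene_pairs`")
  check_ids(dbp_enhancer_pairs$dbp, genes, "`dbp_enhancer_pairs`")
  check_ids(dbp_enhancer_pairs$enhancer, ernas, "`dbp_enhancer_pairs`")

  structure(
    list(layer_params = lp,
         phospho = tibble::as_tibble(phospho),
         enhancer_gene_pairs = tibble::as_tibble(enhancer_gene_pairs),
         dbp_enhancer_pairs = tibble::as_tibble(dbp_enhancer_pairs),
         delay = delay),
    class = "multilayer_truth"
  )
}

layer_row <- function(lp, feature, layer) {
  lp[lp$feature == feature & lp$layer == layer, ]
}

layer_is_rhythmic <- function(lp, feature, layer) {
  r <- layer_row(lp, feature, layer)
  nrow(r) == 1 && (r$amplitude > 0 || r$rhythm_source == "inherited")
}

#' @export
print.multilayer_truth <- function(x, ...) {
  cat("<multilayer_truth> ",
      length(unique(x$layer_params$feature)), " features across ",
      length(unique(x$layer_params$layer)), " layers; ",
      nrow(x$enhancer_gene_pairs), " enhancer-gene pairs, ",
      nrow(x$dbp_enhancer_pairs), " DBP-enhancer pairs\n", sep = "")
  invisible(x)
}

# ---- bundle generation ------------------------------------------------------

#' Generate a coupled multi-layer bundle from a ground truth
#'
#' Layers are generated in cascade order. A mature-RNA rhythm marked
#' `"inherited"` copies phase and period from transcription (plus the
#' configured processing delay); an `"inherited"` protein is the product of
#' the noiseless mature-RNA and translation-rate curves plus its own noise,
#' so rhythmic translation rate alone is enough to make a protein cycle; an
#' `"inherited"` DBP activity copies the protein phase. Three protein
#' datasets are drawn (same truth, independent noise) to emulate independent
#' mass-spectrometry studies for the detection filter.
#'
#' @param truth A [multilayer_truth()].
#' @param design A [sampling_design()].
#' @param seed Integer seed; equal seeds give byte-identical bundles.
#' @return An object of class `layer_bundle`: list with `layers` (named list
#'   of `tc_tbl`), `protein_datasets` (list of three), `phospho_detect`,
#'   `truth`, `resolved` (phase/period actually used per feature and layer),
#'   `design`, `seed`.
#' @export
generate_multilayer <- function(truth, design = sampling_design(), seed) {
  stopifnot(inherits(truth, "multilayer_truth"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  lp <- truth$layer_params
  st <- sample_times(design)

  resolved <- lp
  # resolve inherited phases top-down (transcription -> rna -> protein -> dbp)
  res_phase <- function(feature, layer) {
    r <- resolved[resolved$feature == feature & resolved$layer == layer, ]
    list(phase = r$phase, period = r$period, amp = r$amplitude)
  }
  for (ly in c("mature_rna", "protein", "dbp")) {
    idx <- which(resolved$layer == ly & resolved$rhythm_source == "inherited")
    for (i in idx) {
      up <- res_phase(resolved$feature[i], UPSTREAM[[ly]])
      if (ly == "protein" && up$amp == 0) up <- res_phase(resolved$feature[i], "te")
      ph <- up$phase
      if (ly == "mature_rna") ph <- circ_mod(ph + truth$delay, 24)
      resolved$phase[i] <- ph
      resolved$period[i] <- up$period
    }
  }

  units <- c(transcription = "RPKTM", mature_rna = "RPKM", protein = "intensity",
             dbp = "activity", erna = "RPKTM", te = "ratio",
             phospho = "occupancy")

  gen_order <- c("transcription", "mature_rna", "te", "protein", "dbp",
                 "erna", "phospho")
  layers <- list()
  protein_datasets <- list()

  withr::with_seed(seed, {
    for (ly in gen_order) {
      p <- resolved[resolved$layer == ly, ]
      if (nrow(p) == 0) next
      if (ly == "protein") {
        mu <- protein_mean(p, resolved, st$zt)
        for (k in 1:3) {
          eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) *
            p$noise_sd
          protein_datasets[[k]] <- timecourse(p$feature, pmax(mu + eps, 0),
                                              design, unit = units[[ly]])
        }
        layers[[ly]] <- protein_datasets[[1]]
      } else {
        mu <- cosinor_mean(p, st$zt)
        eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) *
          p$noise_sd
        layers[[ly]] <- timecourse(p$feature, pmax(mu + eps, 0), design,
                                   unit = units[[ly]])
      }
    }
  })

  phospho_detect <- tibble::tibble(
    feature = unique(lp$feature[lp$layer %in% CORE_LAYERS])
  )
  phospho_detect$detected <-
    phospho_detect$feature %in%
    truth$phospho$feature[truth$phospho$phospho_present]

  structure(
    list(layers = layers,
         protein_datasets = protein_datasets,
         phospho_detect = phospho_detect,
         truth = truth,
         resolved = resolved,
         design = design,
         seed = seed),
    class = "layer_bundle"
  )
}

# mean protein curve: product of noiseless mature-RNA and translation-rate
# curves for inherited proteins, plain cosinor otherwise
protein_mean <- function(p, resolved, zt) {
  mu <- cosinor_mean(p, zt)
  inh <- which(p$rhythm_source == "inherited")
  if (length(inh)) {
    rna <- resolved[resolved$layer == "mature_rna", ]
    te <- resolved[resolved$layer == "te", ]
    rna_mu <- cosinor_mean(rna, zt)[match(p$feature[inh], rna$feature), ,
                                    drop = FALSE]
    te_mu <- cosinor_mean(te, zt)[match(p$feature[inh], te$feature), ,
                                  drop = FALSE]
    mu[inh, ] <- rna_mu * te_mu
  }
  mu
}

#' @export
print.layer_bundle <- function(x, ...) {
  cat("<layer_bundle> seed ", x$seed, "; layers: ",
      paste(sprintf("%s (%d)", names(x$layers),
                    vapply(x$layers, nrow, 0L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Flatten a ground truth into a per-gene label table
#'
#' One row per gene carrying the planted rhythmicity flag of every layer, the
#' planted conserved/disrupted/enhanced/neither category of each adjacent
#' layer pair, and the planted mechanism labels. Lossless with respect to the
#' flags in the truth object.
#'
#' @param truth A [multilayer_truth()].
#' @return A tibble, one row per gene.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "multilayer_truth"))
  lp <- truth$layer_params
  genes <- unique(lp$feature[lp$layer %in% CORE_LAYERS])
  if (length(genes) == 0) {
    return(tibble::tibble(feature = character()))
  }
  flag <- function(layer) {
    vapply(genes, function(g) {
      r <- layer_row(lp, g, layer)
      nrow(r) == 1 && (r$amplitude > 0 || r$rhythm_source == "inherited")
    }, logical(1))
  }
  tt <- tibble::tibble(
    feature = genes,
    rhythmic_transcription = flag("transcription"),
    rhythmic_mature_rna = flag("mature_rna"),
    rhythmic_protein = flag("protein"),
    rhythmic_dbp = flag("dbp"),
    rhythmic_te = flag("te")
  )
  cat4 <- function(up, down) {
    dplyr::case_when(up & down ~ "conserved",
                     up & !down ~ "disrupted",
                     !up & down ~ "enhanced",
                     TRUE ~ "neither")
  }
  tt$category_transcription_mature_rna <-
    cat4(tt$rhythmic_transcription, tt$rhythmic_mature_rna)
  tt$category_mature_rna_protein <-
    cat4(tt$rhythmic_mature_rna, tt$rhythmic_protein)
  tt$category_protein_dbp <- cat4(tt$rhythmic_protein, tt$rhythmic_dbp)
  tt$te_dependent <- tt$rhythmic_protein & !tt$rhythmic_mature_rna &
    tt$rhythmic_te
  tt$phospho_present <- tt$feature %in%
    truth$phospho$feature[truth$phospho$phospho_present]
  tt
}
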