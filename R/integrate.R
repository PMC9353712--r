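# Cross-layer integration: conserved / disrupted / enhanced classification
# between adjacent regulatory layers and mechanism attribution through
# translation rate, phosphorylation and enhancer linkage.

as_calls <- function(x, what = "calls") {
  if (inherits(x, "jtk_fit")) x <- x$results
  x <- tibble::as_tibble(x)
  if (!all(c("feature", "rhythmic") %in% names(x))) {
    stop("`", what, "` needs `feature` and `rhythmic` columns ",
         "(a jtk_fit or its tidy() table)", call. = FALSE)
  }
  x[, c("feature", "rhythmic")]
}

#' Features detected in every dataset
#'
#' Intersection of the features whose mean abundance exceeds the detection
#' floor in every supplied matrix — used to keep only proteins seen in all
#' independent mass-spectrometry datasets before any rhythm comparison.
#'
#' @param matrices A list of `tc_tbl` tables (at least one).
#' @param floor Detection floor on the mean abundance (default 0: any
#'   nonzero signal counts).
#' @return Character vector of retained feature ids.
#' @export
detection_filter <- function(matrices, floor = 0) {
  if (!is.list(matrices) || length(matrices) < 1) {
    stop("`matrices` must be a non-empty list", call. = FALSE)
  }
  detected <- lapply(matrices, function(m) {
    v <- tc_values(m)
    rownames(v)[rowMeans(v, na.rm = TRUE) > floor]
  })
  out <- Reduce(intersect, detected)
  if (length(out) == 0) {
    warning("no feature detected in every dataset; returning empty set")
  }
  out
}

#' Classify rhythmicity change between two adjacent layers
#'
#' Genes detected in both layers are partitioned by their rhythm calls:
#' rhythmic in both = conserved; upstream only = disrupted; downstream only
#' = enhanced; neither = neither. The conserved fraction is
#' `conserved / (conserved + disrupted)` — the share of upstream-rhythmic
#' genes that stay rhythmic downstream.
#'
#' @param calls_up,calls_down Rhythm calls of the upstream / downstream
#'   layer: a `jtk_fit` or a tibble with `feature` and `rhythmic`.
#' @param detected_both Features considered (default: features present in
#'   both call tables). Genes in this set missing a call in either layer are
#'   excluded with a message.
#' @param up,down Layer names carried into the summary.
#' @return A tibble of class `layer_comparison` (`feature`, `category`) with
#'   the summary available via [glance()].
#' @export
classify_pair <- function(calls_up, calls_down, detected_both = NULL,
                          up = "upstream", down = "downstream") {
  cu <- as_calls(calls_up, "calls_up")
  cd <- as_calls(calls_down, "calls_down")
  detected_both <- detected_both %||% intersect(cu$feature, cd$feature)
  have_both <- detected_both %in% cu$feature & detected_both %in% cd$feature
  if (any(!have_both)) {
    rlang::inform(paste0(sum(!have_both), " gene(s) lacked a rhythm call in ",
                         "one layer and were excluded"))
  }
  feats <- detected_both[have_both]
  r_up <- cu$rhythmic[match(feats, cu$feature)]
  r_down <- cd$rhythmic[match(feats, cd$feature)]
  category <- dplyr::case_when(
    r_up & r_down ~ "conserved",
    r_up & !r_down ~ "disrupted",
    !r_up & r_down ~ "enhanced",
    TRUE ~ "neither"
  )
  out <- tibble::tibble(feature = feats, category = category)
  n_cons <- sum(category == "conserved")
  n_disr <- sum(category == "disrupted")
  structure(out,
            up = up, down = down,
            conserved_fraction = if (n_cons + n_disr > 0) {
              n_cons / (n_cons + n_disr)
            } else {
              NA_real_
            },
            class = c("layer_comparison", class(out)))
}

#' Summary of a layer comparison
#' @param x A `layer_comparison` from [classify_pair()].
#' @param ... Unused.
#' @return One-row tibble with category counts and the conserved fraction.
#' @export
glance.layer_comparison <- function(x, ...) {
  tibble::tibble(
    up = attr(x, "up"),
    down = attr(x, "down"),
    n = nrow(x),
    conserved = sum(x$category == "conserved"),
    disrupted = sum(x$category == "disrupted"),
    enhanced = sum(x$category == "enhanced"),
    neither = sum(x$category == "neither"),
    conserved_fraction = attr(x, "conserved_fraction")
  )
}

#' Conserved fraction of a layer comparison
#' @param x A `layer_comparison`.
#' @return `conserved / (conserved + disrupted)`, or `NA` when no gene is
#'   rhythmic upstream.
#' @export
conserved_fraction <- function(x) {
  stopifnot(inherits(x, "layer_comparison"))
  attr(x, "conserved_fraction")
}

#' @export
autoplot.layer_comparison <- function(object, ...) {
  d <- dplyr::count(tibble::as_tibble(object), .data$category)
  d$category <- factor(d$category,
                       levels = c("conserved", "disrupted", "enhanced",
                                  "neither"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes",
                  title = paste(attr(object, "up"), "→",
                                attr(object, "down")))
}

#' Compare translation-rate variability between gene groups
#'
#' Computes each gene's coefficient of variation (sd/mean) of translation
#' rate across timepoints and compares the two groups with a two-sided
#' equal-variance Student's t-test — genes keeping their rhythm from mature
#' RNA into protein are expected to hold their translation rate steady.
#'
#' @param te Translation-rate `tc_tbl` (from [translation_rate()] or a
#'   simulated bundle).
#' @param conserved,disrupted Gene id vectors (each needs at least 2 genes
#'   with a computable CV).
#' @return An object of class `te_variation`; [tidy()] gives per-gene CVs,
#'   [glance()] the group means, t statistic and p-value.
#' @export
te_variation_compare <- function(te, conserved, disrupted) {
  v <- tc_values(te)
  cv_of <- function(ids) {
    ids <- intersect(ids, rownames(v))
    m <- v[ids, , drop = FALSE]
    cv <- apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2 || mean(r) == 0) return(NA_real_)
      stats::sd(r) / mean(r)
    })
    cv[!is.na(cv)]
  }
  cv_c <- cv_of(conserved)
  cv_d <- cv_of(disrupted)
  if (length(cv_c) < 2 || length(cv_d) < 2) {
    stop("each group needs at least 2 genes with usable translation rate",
         call. = FALSE)
  }
  if (stats::sd(c(cv_c, cv_d)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(cv_c, cv_d, var.equal = TRUE)
  }
  structure(
    list(cv = dplyr::bind_rows(
           tibble::tibble(feature = names(cv_c), group = "conserved",
                          cv = unname(cv_c)),
           tibble::tibble(feature = names(cv_d), group = "disrupted",
                          cv = unname(cv_d))),
         mean_cv_conserved = mean(cv_c),
         mean_cv_disrupted = mean(cv_d),
         t = unname(tt$statistic),
         p = tt$p.value),
    class = "te_variation"
  )
}

#' @export
print.te_variation <- function(x, ...) {
  cat("<te_variation> mean CV conserved ",
      format(x$mean_cv_conserved, digits = 3), " vs disrupted ",
      format(x$mean_cv_disrupted, digits = 3), "; t = ",
      format(x$t, digits = 3), ", p = ", format(x$p, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @rdname te_variation_compare
#' @param x A `te_variation`.
#' @param ... Unused.
#' @export
tidy.te_variation <- function(x, ...) x$cv

#' @rdname te_variation_compare
#' @export
glance.te_variation <- function(x, ...) {
  tibble::tibble(mean_cv_conserved = x$mean_cv_conserved,
                 mean_cv_disrupted = x$mean_cv_disrupted,
                 t = x$t, p = x$p)
}

new_attribution <- function(mechanism, table, fraction) {
  structure(list(mechanism = mechanism, table = table, fraction = fraction),
            class = "mechanism_attribution")
}

#' @export
print.mechanism_attribution <- function(x, ...) {
  cat("<mechanism_attribution> ", x$mechanism, ": ",
      sum(x$table$dependent, na.rm = TRUE), "/",
      sum(!is.na(x$table$dependent)), " dependent (fraction ",
      format(x$fraction, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname attribute_translation
#' @param x A `mechanism_attribution`.
#' @param ... Unused.
#' @export
tidy.mechanism_attribution <- function(x, ...) x$table

#' @rdname attribute_translation
#' @export
glance.mechanism_attribution <- function(x, ...) {
  tibble::tibble(mechanism = x$mechanism,
                 analyzed = nrow(x$table),
                 dependent = sum(x$table$dependent, na.rm = TRUE),
                 unknown = sum(is.na(x$table$dependent)),
                 fraction = x$fraction)
}

#' Attribute protein-specific rhythms to rhythmic translation rate
#'
#' Among genes rhythmic in protein but not in mature RNA (the enhanced
#' category of the mature-RNA to protein comparison), counts those whose
#' translation-rate series is itself rhythmic. Genes without usable TE data
#' stay in the analyzed table with `dependent = NA` and are excluded from
#' the fraction's denominator.
#'
#' @param protein_specific Gene ids of the protein-specific rhythmic set.
#' @param te_calls TE rhythm calls: `jtk_fit` or tibble with `feature` and
#'   `adj_p` (or `rhythmic`).
#' @param threshold Adjusted-p cutoff for a rhythmic TE (default 0.05).
#' @return A `mechanism_attribution`.
#' @export
attribute_translation <- function(protein_specific, te_calls,
                                  threshold = 0.05) {
  if (inherits(te_calls, "jtk_fit")) te_calls <- te_calls$results
  te_calls <- tibble::as_tibble(te_calls)
  if ("adj_p" %in% names(te_calls)) {
    te_calls$rhythmic <- te_calls$adj_p < threshold
  }
  if (!all(c("feature", "rhythmic") %in% names(te_calls))) {
    stop("`te_calls` needs `feature` and `adj_p` (or `rhythmic`) columns",
         call. = FALSE)
  }
  dep <- te_calls$rhythmic[match(protein_specific, te_calls$feature)]
  if (anyNA(dep)) {
    rlang::inform(paste0(sum(is.na(dep)), " gene(s) lack usable translation-",
                         "rate data; excluded from the fraction"))
  }
  tab <- tibble::tibble(feature = protein_specific, dependent = dep)
  denom <- sum(!is.na(dep))
  new_attribution("translation_rate", tab,
                  if (denom > 0) sum(dep, na.rm = TRUE) / denom else NA_real_)
}

#' Attribute DBP-specific rhythms to phosphorylation
#'
#' Among DBPs whose binding activity is rhythmic while their protein
#' abundance is not, counts those carrying at least one detected
#' phosphosite. Dependence is binary phosphosite presence, not rhythmic
#' phosphorylation.
#'
#' @param dbp_specific Gene ids of the DBP-specific rhythmic set.
#' @param phospho_detect Tibble with `feature` and logical `detected`.
#'   DBPs absent from the table are treated as not phosphorylated (with a
#'   message).
#' @return A `mechanism_attribution`.
#' @export
attribute_phosphorylation <- function(dbp_specific, phospho_detect) {
  phospho_detect <- tibble::as_tibble(phospho_detect)
  if (!all(c("feature", "detected") %in% names(phospho_detect))) {
    stop("`phospho_detect` needs `feature` and `detected` columns",
         call. = FALSE)
  }
  dep <- phospho_detect$detected[match(dbp_specific, phospho_detect$feature)]
  if (anyNA(dep)) {
    rlang::inform(paste0(sum(is.na(dep)), " DBP(s) absent from the ",
                         "phosphosite table; treated as not phosphorylated"))
    dep[is.na(dep)] <- FALSE
  }
  tab <- tibble::tibble(feature = dbp_specific, dependent = dep)
  new_attribution("phosphorylation", tab,
                  if (length(dep) > 0) mean(dep) else NA_real_)
}

#' Link rhythmic DBPs to rhythmic transcription through rhythmic enhancers
#'
#' Emits every (DBP, enhancer, gene) triad for which both links exist in the
#' pairing maps and all three series — DBP binding activity, eRNA level, and
#' gene transcription rate — are rhythmic.
#'
#' @param dbp_calls,erna_calls,txn_calls Rhythm calls (`jtk_fit` or
#'   feature/rhythmic tibbles) of the three layers.
#' @param dbp_enhancer_pairs Tibble `dbp`, `enhancer`.
#' @param enhancer_gene_pairs Tibble `enhancer`, `gene`.
#' @return Tibble of triads: `dbp`, `enhancer`, `gene`.
#' @export
link_triads <- function(dbp_calls, erna_calls, txn_calls,
                        dbp_enhancer_pairs, enhancer_gene_pairs) {
  dc <- as_calls(dbp_calls, "dbp_calls")
  ec <- as_calls(erna_calls, "erna_calls")
  tc <- as_calls(txn_calls, "txn_calls")
  dangling <- c(setdiff(dbp_enhancer_pairs$dbp, dc$feature),
                setdiff(dbp_enhancer_pairs$enhancer, ec$feature),
                setdiff(enhancer_gene_pairs$enhancer, ec$feature),
                setdiff(enhancer_gene_pairs$gene, tc$feature))
  if (length(dangling)) {
    stop("pairing maps reference id(s) without rhythm calls: ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  triads <- dplyr::inner_join(tibble::as_tibble(dbp_enhancer_pairs),
                              tibble::as_tibble(enhancer_gene_pairs),
                              by = "enhancer",
                              relationship = "many-to-many")
  keep <- dc$rhythmic[match(triads$dbp, dc$feature)] &
    ec$rhythmic[match(triads$enhancer, ec$feature)] &
    tc$rhythmic[match(triads$gene, tc$feature)]
  triads[keep, c("dbp", "enhancer", "gene")]
}

#' Pair enhancer loci to their nearest gene
#'
#' Default enhancer-to-gene assignment for real data: each enhancer is
#' linked to the gene with the nearest TSS on the same chromosome, within
#' `max_dist` (default 100 kb).
#'
#' @param enhancers Tibble with `id`, `chrom`, `center`.
#' @param genes A [gene_model()] tibble.
#' @param max_dist Maximum center-to-TSS distance in bp.
#' @return Tibble `enhancer`, `gene`, `distance`.
#' @export
pair_enhancers_to_genes <- function(enhancers, genes, max_dist = 1e5) {
  rows <- lapply(seq_len(nrow(enhancers)), function(i) {
    g <- genes[genes$chrom == enhancers$chrom[i], ]
    if (nrow(g) == 0) return(NULL)
    d <- abs(g$tss - enhancers$center[i])
    j <- which.min(d)
    if (d[j] > max_dist) return(NULL)
    tibble::tibble(enhancer = enhancers$id[i], gene = g$id[j],
                   distance = d[j])
  })
  dplyr::bind_rows(rows)
}
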