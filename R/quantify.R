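# Layer-specific quantification: gene-body windows for nascent
# transcription, RPKTM/RPKM normalisation, enhancer-RNA locus filtering and
# +/-500 bp quantification, ribosome-profiling translation rate.

#' Build a gene model table
#'
#' Strand-aware gene coordinates in the internal convention: 0-based
#' half-open, with `tss`/`tes` as the 5' and 3' boundaries in transcription
#' direction (for a minus-strand gene `tss > tes`).
#'
#' @param id Gene ids.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes Transcription start / end coordinates.
#' @param exon_length_bp Optional total exonic length used for RPKM; defaults
#'   to the gene-body length.
#' @return A tibble with one row per gene and a `body_length` column.
#' @export
gene_model <- function(id, chrom, strand, tss, tes, exon_length_bp = NULL) {
  g <- tibble::tibble(id = as.character(id), chrom = as.character(chrom),
                      strand = as.character(strand),
                      tss = as.numeric(tss), tes = as.numeric(tes))
  if (!all(g$strand %in% c("+", "-"))) {
    stop("strand must be \"+\" or \"-\"", call. = FALSE)
  }
  if (any(g$tss == g$tes)) {
    stop("tss must differ from tes for gene(s): ",
         paste(g$id[g$tss == g$tes], collapse = ", "), call. = FALSE)
  }
  wrong <- (g$strand == "+" & g$tss > g$tes) |
    (g$strand == "-" & g$tss < g$tes)
  if (any(wrong)) {
    stop("tss/tes orientation inconsistent with strand for gene(s): ",
         paste(g$id[wrong], collapse = ", "), call. = FALSE)
  }
  g$body_length <- abs(g$tes - g$tss)
  g$exon_length_bp <- exon_length_bp %||% g$body_length
  g
}

#' Gene-body quantification window for nascent transcription
#'
#' Selects the stretch of gene body used to quantify run-on signal, avoiding
#' the promoter-proximal pause region: genes longer than 12 kb use the fixed
#' 10 kb window from +2 kb to +12 kb downstream of the TSS; genes of 2-12 kb
#' use +2 kb to the TES; genes shorter than 2 kb use the whole body. Offsets
#' are applied in the 5'-to-3' direction, so minus-strand genes mirror.
#' A gene of exactly 2 kb falls in the middle branch (closed interval),
#' giving a zero-width window and hence zero signal.
#'
#' @param genes A [gene_model()] tibble.
#' @return A tibble of intervals: `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @examples
#' g <- gene_model("a", "chrT", "+", tss = 1000, tes = 16000)
#' gene_body_window(g) # [3000, 13000)
#' @export
gene_body_window <- function(genes) {
  L <- genes$body_length
  a <- ifelse(L < 2000, 0, 2000)
  b <- ifelse(L > 12000, 12000, L)
  plus <- genes$strand == "+"
  tibble::tibble(
    id = genes$id,
    chrom = genes$chrom,
    start = ifelse(plus, genes$tss + a, genes$tss - b),
    end = ifelse(plus, genes$tss + b, genes$tss - a),
    strand = genes$strand
  )
}

#' Quantification windows around enhancer-RNA locus centers
#'
#' Reads within 500 bp of the locus center are counted: the window is
#' `[center - 500, center + 500)`.
#'
#' @param peaks An [filter_erna_peaks()]-style peak tibble with `id`,
#'   `chrom`, `strand`, `center`.
#' @return Interval tibble as in [gene_body_window()].
#' @export
erna_windows <- function(peaks) {
  tibble::tibble(id = peaks$id, chrom = peaks$chrom,
                 start = peaks$center - 500, end = peaks$center + 500,
                 strand = peaks$strand)
}

#' Reads per kilobase per ten million mapped reads
#'
#' The density normalisation used for gene-body run-on signal and eRNA loci:
#' `count / (length_bp / 1000) / (total_mapped / 1e7)`.
#'
#' @param count Read count in the window.
#' @param length_bp Window length, > 0.
#' @param total_mapped Library size (mapped reads), > 0.
#' @return Density value(s).
#' @examples
#' rpktm(100, 10000, 2e7) # 5
#' @export
rpktm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("`length_bp` must be > 0", call. = FALSE)
  if (any(total_mapped <= 0)) stop("`total_mapped` must be > 0", call. = FALSE)
  count / (length_bp / 1000) / (total_mapped / 1e7)
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param count Read count over the exons.
#' @param exon_length_bp Total exonic length, > 0.
#' @param total_mapped Library size, > 0.
#' @return Density value(s).
#' @examples
#' rpkm(100, 1000, 1e6) # 100
#' @export
rpkm <- function(count, exon_length_bp, total_mapped) {
  if (any(exon_length_bp <= 0)) {
    stop("`exon_length_bp` must be > 0", call. = FALSE)
  }
  if (any(total_mapped <= 0)) stop("`total_mapped` must be > 0", call. = FALSE)
  count / (exon_length_bp / 1000) / (total_mapped / 1e6)
}

#' Quantify windows from stranded coverage into a time-course table
#'
#' For every window and timepoint, sums the same-strand coverage within the
#' window (coverage values are 5'-end read counts per base, so the sum is
#' the read count) and normalises to RPKTM with the per-timepoint library
#' size. Windows reaching past the chromosome start are clipped with a
#' warning.
#'
#' @param coverage Long tibble of stranded coverage: columns `zt`, `strand`,
#'   `chrom`, `start`, `end`, `value` (0-based half-open intervals; both
#'   strand files must be present even if empty of the window's strand).
#' @param windows Interval tibble from [gene_body_window()] or
#'   [erna_windows()].
#' @param totals Per-timepoint library sizes: named numeric vector
#'   (names `ZT<t>`) or tibble with `zt` and `total`.
#' @return A `tc_tbl` in RPKTM units, one row per window id.
#' @export
quantify_features <- function(coverage, windows, totals) {
  need <- c("zt", "strand", "chrom", "start", "end", "value")
  missing_cols <- setdiff(need, names(coverage))
  if (length(missing_cols)) {
    stop("`coverage` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(totals)) {
    tot <- stats::setNames(totals$total, paste0("ZT", totals$zt))
  } else {
    tot <- totals
  }
  zts <- sort(unique(coverage$zt))
  if (length(zts) == 0) {
    # coverage files were empty: the totals define the time grid
    zts <- sort(as.numeric(sub("^ZT", "", names(tot))))
  }
  if (!all(paste0("ZT", zts) %in% names(tot))) {
    stop("`totals` must cover every timepoint in `coverage`", call. = FALSE)
  }
  if (any(tot <= 0)) stop("library totals must be > 0", call. = FALSE)

  w <- windows
  if (any(w$start < 0)) {
    warning("window(s) clipped at chromosome start: ",
            paste(w$id[w$start < 0], collapse = ", "))
    w$start <- pmax(w$start, 0)
  }

  vals <- matrix(0, nrow(w), length(zts),
                 dimnames = list(w$id, paste0("ZT", zts)))
  for (t_i in seq_along(zts)) {
    cov_t <- coverage[coverage$zt == zts[t_i], ]
    for (i in seq_len(nrow(w))) {
      if (w$end[i] <= w$start[i]) next  # zero-width window: no signal
      cc <- cov_t[cov_t$strand == w$strand[i] & cov_t$chrom == w$chrom[i], ]
      if (nrow(cc) == 0) next
      ov <- pmin(cc$end, w$end[i]) - pmax(cc$start, w$start[i])
      count <- sum(cc$value[ov > 0] * ov[ov > 0])
      len <- w$end[i] - w$start[i]
      vals[i, t_i] <- rpktm(count, len, tot[[paste0("ZT", zts[t_i])]])
    }
  }
  out <- dplyr::bind_cols(tibble::tibble(feature = w$id),
                          tibble::as_tibble(vals))
  as_timecourse(out, unit = "RPKTM")
}

#' Filter candidate enhancer-RNA loci
#'
#' Keeps peaks with `fdr < 0.001` and `fold_change > 3` whose center lies
#' more than 300 bp from every annotated TSS (promoter-proximal sites are
#' excluded so the signal is enhancer transcription, not promoter runoff).
#'
#' @param peaks Tibble with `id`, `chrom`, `center`, `fdr`, `fold_change`
#'   (and optionally `strand`).
#' @param tss_list TSS coordinates: numeric vector (single-chromosome
#'   genomes) or tibble with `chrom` and `tss`.
#' @return The retained subset of `peaks`.
#' @export
filter_erna_peaks <- function(peaks, tss_list) {
  for (col in c("fdr", "fold_change")) {
    if (!col %in% names(peaks)) {
      stop("`peaks` lacks required score column: ", col, call. = FALSE)
    }
  }
  if (!is.data.frame(tss_list)) {
    tss_list <- tibble::tibble(chrom = unique(peaks$chrom)[1],
                               tss = as.numeric(tss_list))
  }
  min_dist <- vapply(seq_len(nrow(peaks)), function(i) {
    tt <- tss_list$tss[tss_list$chrom == peaks$chrom[i]]
    if (length(tt) == 0) return(Inf)
    min(abs(peaks$center[i] - tt))
  }, numeric(1))
  keep <- peaks$fdr < 0.001 & peaks$fold_change > 3 & min_dist > 300
  peaks[keep, , drop = FALSE]
}

#' Translation rate from ribosome footprints and mature RNA
#'
#' `TE(g, t) = ribo(g, t) / rna(g, t)` over the features and ZT timepoints
#' shared by both tables; where the RNA denominator falls below `floor` the
#' ratio is recorded missing rather than blowing up. Genes with more than
#' `max_missing` of their timepoints missing are flagged unusable.
#'
#' @param ribo Footprint density `tc_tbl` (RPKM).
#' @param rna Mature RNA density `tc_tbl` (RPKM). The two grids are
#'   intersected on shared ZT labels; no interpolation.
#' @param floor RNA density below which the ratio is undefined (default 0.1
#'   RPKM).
#' @param max_missing Missing-fraction above which a gene is flagged
#'   unusable (default 0.25).
#' @return A `tc_tbl` in ratio units with an extra logical `usable` column.
#' @export
translation_rate <- function(ribo, rna, floor = 0.1, max_missing = 0.25) {
  common_zt <- intersect(tc_cols(ribo), tc_cols(rna))
  if (length(common_zt) == 0) {
    stop("ribo and rna share no ZT timepoints", call. = FALSE)
  }
  common <- intersect(ribo$feature, rna$feature)
  rb <- tc_values(ribo)[common, common_zt, drop = FALSE]
  rn <- tc_values(rna)[common, common_zt, drop = FALSE]
  te <- rb / rn
  te[rn < floor] <- NA_real_
  usable <- rowMeans(is.na(te)) <= max_missing
  out <- dplyr::bind_cols(
    tibble::tibble(feature = common, usable = unname(usable)),
    tibble::as_tibble(te)
  )
  as_timecourse(out, unit = "ratio")
}
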