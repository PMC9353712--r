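# Toy-genome coverage emitter: turns an expression time course into
# per-timepoint stranded bedGraph tracks plus a GTF annotation, so the
# file-based quantification path can be exercised end to end without any
# external data. Toy genome: one chromosome "chrT" of 10 Mb.

TOY_CHROM <- "chrT"
TOY_CHROM_LENGTH <- 1e7

#' Emit stranded coverage tracks for a gene expression time course
#'
#' Reads are placed uniformly over each gene's quantification window (see
#' [gene_body_window()]) at a rate proportional to its expression; coverage
#' records 5'-end positions, matching run-on tag semantics. One bedGraph per
#' strand per timepoint plus a 1-based closed GTF and a per-timepoint
#' library-total table are written.
#'
#' @param genes A [gene_model()] tibble; genes must lie within the toy
#'   chromosome and not overlap on the same strand.
#' @param expression A `tc_tbl` over the gene ids (expression units).
#' @param design A [sampling_design()].
#' @param seed Integer seed for read placement.
#' @param dir Output directory (created if needed).
#' @param reads_per_unit Reads placed per expression unit (default 10);
#'   counts are rounded.
#' @param library_size Optional per-timepoint total mapped reads recorded in
#'   the totals table (single number or vector, recycled); defaults to the
#'   reads actually placed, but a larger value emulates a library in which
#'   these genes are a small fraction.
#' @return A list: `coverage_files` (tibble `zt`, `plus`, `minus`), `gtf`,
#'   `totals_file`, `totals` (tibble `zt`, `total`, `placed`).
#' @export
generate_coverage <- function(genes, expression, design = sampling_design(),
                              seed, dir, reads_per_unit = 10,
                              library_size = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (missing(dir)) stop("`dir` is required", call. = FALSE)
  windows <- gene_body_window(genes)
  span_lo <- pmin(genes$tss, genes$tes)
  span_hi <- pmax(genes$tss, genes$tes)
  out_of_bounds <- span_lo < 0 | span_hi > TOY_CHROM_LENGTH |
    genes$chrom != TOY_CHROM
  if (any(out_of_bounds)) {
    stop("gene(s) outside the toy chromosome (", TOY_CHROM, ", ",
         TOY_CHROM_LENGTH, " bp): ",
         paste(genes$id[out_of_bounds], collapse = ", "), call. = FALSE)
  }
  for (s in c("+", "-")) {
    g <- genes[genes$strand == s, ]
    if (nrow(g) > 1) {
      o <- order(pmin(g$tss, g$tes))
      lo <- pmin(g$tss, g$tes)[o]
      hi <- pmax(g$tss, g$tes)[o]
      if (any(lo[-1] < hi[-length(hi)])) {
        stop("genes overlap on strand ", s, call. = FALSE)
      }
    }
  }
  miss <- setdiff(genes$id, expression$feature)
  if (length(miss)) {
    stop("expression lacks gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- tc_values(expression)[genes$id, , drop = FALSE]
  zts <- tc_zt(expression)
  cov_files <- tibble::tibble(zt = zts, plus = NA_character_,
                              minus = NA_character_)
  placed <- numeric(length(zts))

  withr::with_seed(seed, {
    for (t_i in seq_along(zts)) {
      counts_by_strand <- list(`+` = integer(0), `-` = integer(0))
      pos_by_strand <- list(`+` = integer(0), `-` = integer(0))
      for (i in seq_len(nrow(genes))) {
        n_reads <- round(ex[i, t_i] * reads_per_unit)
        w0 <- windows$start[i]
        w1 <- windows$end[i]
        if (n_reads <= 0 || w1 <= w0) next
        pos <- sample.int(w1 - w0, n_reads, replace = TRUE) + w0 - 1L
        s <- windows$strand[i]
        pos_by_strand[[s]] <- c(pos_by_strand[[s]], pos)
      }
      placed[t_i] <- length(pos_by_strand$`+`) + length(pos_by_strand$`-`)
      for (s in c("+", "-")) {
        tag <- if (s == "+") "plus" else "minus"
        path <- file.path(dir, sprintf("cov_ZT%s_%s.bedGraph", zts[t_i], tag))
        write_bedgraph_positions(pos_by_strand[[s]], path)
        cov_files[[tag]][t_i] <- path
      }
    }
  })

  gtf_path <- file.path(dir, "genes.gtf")
  write_toy_gtf(genes, gtf_path)
  totals <- tibble::tibble(
    zt = zts,
    total = if (is.null(library_size)) placed else
      rep_len(library_size, length(zts)),
    placed = placed
  )
  totals_file <- file.path(dir, "totals.tsv")
  readr::write_tsv(totals, totals_file)
  list(coverage_files = cov_files, gtf = gtf_path,
       totals_file = totals_file, totals = totals)
}

# collapse 5'-end positions into a bedGraph (0-based half-open, merged runs)
write_bedgraph_positions <- function(pos, path) {
  if (length(pos) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  tb <- table(pos)
  p <- as.integer(names(tb))
  v <- as.integer(tb)
  # merge adjacent positions with equal counts into runs
  brk <- c(TRUE, diff(p) != 1L | diff(v) != 0L)
  first <- which(brk)
  last <- c(first[-1] - 1L, length(p))
  writeLines(sprintf("%s\t%d\t%d\t%d", TOY_CHROM, p[first], p[last] + 1L,
                     v[first]), path)
  invisible(path)
}

write_toy_gtf <- function(genes, path) {
  lo <- pmin(genes$tss, genes$tes)
  hi <- pmax(genes$tss, genes$tes)
  lines <- sprintf(
    "%s\trhythmlayers\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, as.integer(lo) + 1L, as.integer(hi), genes$strand, genes$id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a set of stranded per-timepoint coverage files
#'
#' @param coverage_files Tibble with `zt`, `plus`, `minus` file paths, as
#'   produced by [generate_coverage()].
#' @return Long coverage tibble for [quantify_features()].
#' @export
read_coverage_set <- function(coverage_files) {
  rows <- lapply(seq_len(nrow(coverage_files)), function(i) {
    dplyr::bind_rows(
      dplyr::mutate(read_bedgraph(coverage_files$plus[i], strand = "+"),
                    zt = coverage_files$zt[i]),
      dplyr::mutate(read_bedgraph(coverage_files$minus[i], strand = "-"),
                    zt = coverage_files$zt[i])
    )
  })
  dplyr::bind_rows(rows)
}
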