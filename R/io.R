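# File formats: time-course TSV with a unit metadata line, GTF/BED/bedGraph
# through rtracklayer, peak tables, YAML configuration.

#' Write / read a time-course table as TSV
#'
#' The TSV carries a `#unit=` metadata line before the header so the
#' measurement unit survives the round trip; columns are written in their
#' stored order, values at full precision.
#'
#' @param tc A `tc_tbl`.
#' @param path File path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the `tc_tbl`.
#' @export
write_matrix <- function(tc, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#unit=", tc_unit(tc)), con)
  writeLines(paste(names(tc), collapse = "\t"), con)
  if (nrow(tc) > 0) {
    cells <- vapply(seq_len(nrow(tc)), function(i) {
      paste(vapply(tc[i, ], function(v) {
        if (is.na(v)) "NA"
        else if (is.numeric(v)) format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE)
        else as.character(v)
      }, character(1)), collapse = "\t")
    }, character(1))
    writeLines(cells, con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  unit <- "abundance"
  meta <- grepl("^#", lines)
  for (m in lines[meta]) {
    if (grepl("^#unit=", m)) unit <- sub("^#unit=", "", m)
  }
  body <- lines[!meta]
  offset <- which(!meta)  # original line numbers, for error messages
  if (length(body) == 0) stop("no header line in ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ncol <- length(header)
  rows <- lapply(seq_along(body)[-1], function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol) {
      stop("line ", offset[i], " of ", path, ": expected ", ncol,
           " fields, found ", length(f), call. = FALSE)
    }
    f
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(ncol, character(0), simplify = FALSE), header))
  }
  names(out) <- header
  value_cols <- grep("^ZT[0-9]", header, value = TRUE)
  for (cn in setdiff(header, "feature")) {
    raw <- out[[cn]]
    if (cn %in% value_cols) {
      num <- suppressWarnings(as.numeric(raw))
      bad <- is.na(num) & raw != "NA"
      if (any(bad)) {
        stop("line ", offset[which(bad)[1] + 1], " of ", path,
             ": non-numeric value in column ", cn, call. = FALSE)
      }
      out[[cn]] <- num
    } else if (all(raw %in% c("TRUE", "FALSE", "NA"))) {
      out[[cn]] <- as.logical(raw)
    }
  }
  as_timecourse(out, unit = unit)
}

need_rtracklayer <- function() {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package `rtracklayer` is required for GTF/BED/bedGraph input",
         call. = FALSE)
  }
}

#' Read gene models from a GTF file
#'
#' GTF coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention; `tss`/`tes` are oriented by strand. Only `gene`
#' rows are used when a `type` field is present.
#'
#' @param path GTF file.
#' @return A [gene_model()] tibble.
#' @export
read_gtf <- function(path) {
  need_rtracklayer()
  gr <- rtracklayer::import(path, format = "gtf")
  d <- as.data.frame(gr)
  if ("type" %in% names(d) && any(d$type == "gene")) {
    d <- d[d$type == "gene", ]
  }
  if (any(!as.character(d$strand) %in% c("+", "-"))) {
    stop("GTF contains feature(s) with unknown strand", call. = FALSE)
  }
  start0 <- d$start - 1L
  if (any(start0 < 0)) {
    stop("GTF coordinate underflow after 1-based conversion", call. = FALSE)
  }
  id <- if ("gene_id" %in% names(d)) d$gene_id else as.character(seq_len(nrow(d)))
  plus <- as.character(d$strand) == "+"
  gene_model(id = id, chrom = as.character(d$seqnames),
             strand = as.character(d$strand),
             tss = ifelse(plus, start0, d$end),
             tes = ifelse(plus, d$end, start0))
}

#' Read intervals from a BED file
#'
#' @param path BED file (BED6 or better).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  need_rtracklayer()
  gr <- rtracklayer::import(path, format = "bed")
  d <- as.data.frame(gr)
  tibble::tibble(chrom = as.character(d$seqnames),
                 start = d$start - 1L, end = d$end,
                 name = if ("name" %in% names(d)) d$name else NA_character_,
                 score = if ("score" %in% names(d)) d$score else NA_real_,
                 strand = as.character(d$strand))
}

#' Read a stranded bedGraph coverage track
#'
#' Overlapping intervals (legal in the wild) are split and summed so the
#' result is a disjoint per-strand coverage.
#'
#' @param path bedGraph file; may be empty.
#' @param strand Strand the file represents (`"+"` or `"-"`).
#' @return Tibble `chrom`, `start`, `end`, `value`, `strand`.
#' @export
read_bedgraph <- function(path, strand) {
  if (!file.exists(path)) {
    stop("missing coverage file for strand ", strand, ": ", path,
         call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric(),
                          strand = character()))
  }
  need_rtracklayer()
  gr <- rtracklayer::import(path, format = "bedGraph")
  d <- as.data.frame(gr)
  out <- tibble::tibble(chrom = as.character(d$seqnames),
                        start = d$start - 1L, end = d$end,
                        value = d$score, strand = strand)
  merge_bedgraph(out)
}

# split overlapping intervals at their breakpoints and sum values
merge_bedgraph <- function(tbl) {
  pieces <- lapply(split(tbl, tbl$chrom), function(d) {
    if (nrow(d) < 2) return(d)
    brk <- sort(unique(c(d$start, d$end)))
    lo <- brk[-length(brk)]
    hi <- brk[-1]
    val <- vapply(seq_along(lo), function(i) {
      sum(d$value[d$start <= lo[i] & d$end >= hi[i]])
    }, numeric(1))
    keep <- val != 0
    tibble::tibble(chrom = d$chrom[1], start = lo[keep], end = hi[keep],
                   value = val[keep], strand = d$strand[1])
  })
  out <- dplyr::bind_rows(pieces)
  out[order(out$chrom, out$start), ]
}

#' Read an enhancer peak table
#'
#' BED6 plus two score columns (FDR, fold change), without header. The peak
#' center is the interval midpoint.
#'
#' @param path Peak file.
#' @return Tibble `id`, `chrom`, `strand`, `center`, `fdr`, `fold_change`.
#' @export
read_peaks <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 8) {
    stop("peak file needs BED6 + fdr + fold_change columns (8); found ",
         ncol(d), call. = FALSE)
  }
  names(d)[1:8] <- c("chrom", "start", "end", "name", "score", "strand",
                     "fdr", "fold_change")
  tibble::tibble(id = as.character(d$name), chrom = d$chrom,
                 strand = d$strand,
                 center = floor((d$start + d$end) / 2),
                 fdr = as.numeric(d$fdr),
                 fold_change = as.numeric(d$fold_change))
}

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end run: sampling design,
#' reference grid, per-layer thresholds, quantification floors, simulator
#' parameters and the master seed.
#'
#' @param design A [sampling_design()].
#' @param periods,lag_step Reference grid, see [reference_waveforms()].
#' @param thresholds Named per-layer adjusted-p cutoffs
#'   (default [default_layer_thresholds()]).
#' @param te_floor,te_max_missing See [translation_rate()].
#' @param detection_floor See [detection_filter()].
#' @param seed Master seed.
#' @param study Named list of overrides passed to [simulate_study()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = sampling_design(),
                            periods = 20:28, lag_step = 1,
                            thresholds = default_layer_thresholds(),
                            te_floor = 0.1, te_max_missing = 0.25,
                            detection_floor = 0,
                            seed = 1, study = list()) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(design = design, periods = periods, lag_step = lag_step,
                 thresholds = thresholds, te_floor = te_floor,
                 te_max_missing = te_max_missing,
                 detection_floor = detection_floor,
                 seed = as.integer(seed), study = study),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; `design` is
#' a mapping with `timepoints`, `period_day`, `replicates`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    sampling_design(timepoints = y$design$timepoints %||% seq(0, 21, 3),
                    period_day = y$design$period_day %||% 24,
                    replicates = y$design$replicates %||% 1)
  } else {
    sampling_design()
  }
  thresholds <- default_layer_thresholds()
  if (!is.null(y$thresholds)) {
    thr <- unlist(y$thresholds)
    thresholds[names(thr)] <- thr
  }
  pipeline_config(
    design = design,
    periods = y$periods %||% 20:28,
    lag_step = y$lag_step %||% 1,
    thresholds = thresholds,
    te_floor = y$te_floor %||% 0.1,
    te_max_missing = y$te_max_missing %||% 0.25,
    detection_floor = y$detection_floor %||% 0,
    seed = y$seed %||% 1,
    study = y$study %||% list()
  )
}
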