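#' Sampling design of a diurnal time course
#'
#' Describes how a 24 h light-dark cycle was sampled: the Zeitgeber times (ZT,
#' hours after lights-on) at which samples were taken, the length of the cycle,
#' and the number of replicates per timepoint. The default is the common
#' one-day design of 8 timepoints every 3 h (ZT0, ZT3, ..., ZT21) with a
#' single replicate.
#'
#' @param timepoints Numeric vector of ZT hours, strictly increasing, all in
#'   `[0, period_day)`.
#' @param period_day Length of the entrained cycle in hours (default 24).
#' @param replicates Number of replicates per timepoint (default 1).
#' @return An object of class `sampling_design`.
#' @examples
#' sampling_design()
#' sampling_design(timepoints = seq(0, 22, 2), replicates = 2)
#' @export
sampling_design <- function(timepoints = seq(0, 21, by = 3),
                            period_day = 24,
                            replicates = 1L) {
  if (!is.numeric(timepoints) || length(timepoints) < 1 || anyNA(timepoints)) {
    stop("`timepoints` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  if (any(timepoints < 0) || any(timepoints >= period_day)) {
    stop("`timepoints` must lie in [0, period_day)", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 1 || is.na(replicates) || replicates < 1) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(timepoints = as.numeric(timepoints),
         period_day = as.numeric(period_day),
         replicates = replicates),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("<sampling_design> ", length(x$timepoints), " timepoints over ",
      x$period_day, "h: ZT", paste(x$timepoints, collapse = ", ZT"),
      " (", x$replicates, " replicate", if (x$replicates > 1) "s", ")\n",
      sep = "")
  invisible(x)
}

#' Sample times of a design, one entry per sample column
#'
#' Expands a [sampling_design()] to the vector of ZT hours of every sample
#' (replicates repeat their timepoint) and the matching column labels used in
#' time-course tables (`ZT0`, `ZT3`, ... or `ZT0_r1`, `ZT0_r2`, ... when
#' replicated).
#'
#' @param design A [sampling_design()].
#' @return A list with numeric `zt` and character `labels`.
#' @export
sample_times <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  zt <- rep(design$timepoints, each = design$replicates)
  labels <- if (design$replicates == 1) {
    paste0("ZT", design$timepoints)
  } else {
    paste0("ZT", rep(design$timepoints, each = design$replicates),
           "_r", rep(seq_len(design$replicates), length(design$timepoints)))
  }
  list(zt = zt, labels = labels)
}

# ---- time-course tables -----------------------------------------------------

#' Build a time-course table
#'
#' The unit every layer is reduced to: one row per feature, one column per
#' sample, columns named `ZT<t>` (plus `_r<k>` for replicates). The
#' measurement unit (RPKM, RPKTM, activity, ratio, ...) travels in the
#' `"unit"` attribute and is preserved by [write_matrix()]/[read_matrix()].
#' Values in abundance units must be non-negative; ratio-type matrices may
#' contain `NA` where the denominator was below the quantification floor.
#'
#' @param features Character vector of feature ids.
#' @param values Numeric matrix, one row per feature, one column per sample.
#' @param design The [sampling_design()] the columns follow.
#' @param unit Measurement unit recorded as metadata.
#' @return A tibble of class `tc_tbl`.
#' @export
timecourse <- function(features, values, design = sampling_design(),
                       unit = "abundance") {
  st <- sample_times(design)
  values <- as.matrix(values)
  if (length(features) != nrow(values)) {
    stop("`features` length must match rows of `values`", call. = FALSE)
  }
  if (ncol(values) != length(st$labels)) {
    stop("`values` must have one column per sample of `design` (",
         length(st$labels), ")", call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  colnames(values) <- st$labels
  out <- dplyr::bind_cols(tibble::tibble(feature = as.character(features)),
                          tibble::as_tibble(values))
  as_timecourse(out, unit = unit)
}

#' Mark a tibble as a time-course table
#'
#' @param x A data frame with a `feature` column and `ZT*` value columns.
#' @param unit Measurement unit; kept if already present and `unit` is `NULL`.
#' @return `x` as a `tc_tbl` tibble.
#' @export
as_timecourse <- function(x, unit = NULL) {
  x <- tibble::as_tibble(x)
  if (!"feature" %in% names(x)) {
    stop("a time-course table needs a `feature` column", call. = FALSE)
  }
  if (length(tc_cols(x)) == 0) {
    stop("a time-course table needs at least one ZT* value column",
         call. = FALSE)
  }
  attr(x, "unit") <- unit %||% attr(x, "unit") %||% "abundance"
  class(x) <- unique(c("tc_tbl", class(x)))
  x
}

tc_cols <- function(x) grep("^ZT[0-9]", names(x), value = TRUE)

#' Numeric value matrix of a time-course table
#'
#' @param x A `tc_tbl` (or any data frame with `feature` and `ZT*` columns).
#' @return Numeric matrix with feature ids as rownames.
#' @export
tc_values <- function(x) {
  cols <- tc_cols(x)
  m <- as.matrix(x[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature
  m
}

#' ZT hours of the value columns of a time-course table
#'
#' Parsed from the column names, so the grid survives any dplyr manipulation.
#'
#' @param x A `tc_tbl`.
#' @return Numeric vector of ZT hours, one per value column.
#' @export
tc_zt <- function(x) {
  cols <- tc_cols(x)
  as.numeric(stringr::str_match(cols, "^ZT([0-9]+\\.?[0-9]*)")[, 2])
}

#' Measurement unit of a time-course table
#' @param x A `tc_tbl`.
#' @return Character scalar.
#' @export
tc_unit <- function(x) attr(x, "unit") %||% "abundance"

#' @export
print.tc_tbl <- function(x, ...) {
  cat("# time course:", nrow(x), "features x", length(tc_cols(x)),
      "samples; unit:", tc_unit(x), "\n")
  NextMethod()
}
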