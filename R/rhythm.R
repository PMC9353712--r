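# JTK_CYCLE-style rhythm detection: rank correlation of a series against a
# grid of cosine reference waveforms spanning periods 20-28 h, exact
# tie-aware permutation null per reference, Bonferroni adjustment across the
# distinct references tested.

#' Cosine reference waveforms over a period and phase grid
#'
#' One waveform per (period, lag) pair, evaluated at the actual sample times
#' of the design, so periods need not be multiples of the sampling interval.
#' Waveforms whose rank pattern duplicates an earlier one are flagged; only
#' distinct rank patterns count toward the Bonferroni factor, since duplicate
#' patterns give identical tests.
#'
#' @param design A [sampling_design()], or a numeric vector of sample ZT
#'   hours.
#' @param periods Numeric vector of test periods in hours, within `[20, 28]`.
#' @param lag_step Phase-grid resolution in hours; must divide each period's
#'   lag range.
#' @return A tibble of class `jtk_refs`: `period`, `lag`, `values` (list),
#'   `tie_pattern` (list of tie-group sizes), `pattern` (rank signature),
#'   `distinct` (logical); attribute `n_distinct`.
#' @examples
#' refs <- reference_waveforms(sampling_design(), periods = 24)
#' attr(refs, "n_distinct")
#' @export
reference_waveforms <- function(design = sampling_design(),
                                periods = 20:28, lag_step = 1) {
  zt <- if (inherits(design, "sampling_design")) sample_times(design)$zt
        else as.numeric(design)
  if (length(unique(zt)) < 2) {
    stop("design must have at least two distinct timepoints", call. = FALSE)
  }
  if (length(periods) == 0) stop("empty period grid", call. = FALSE)
  if (any(periods < 20 | periods > 28)) {
    stop("`periods` must lie within [20, 28] hours", call. = FALSE)
  }
  if (lag_step <= 0) stop("`lag_step` must be positive", call. = FALSE)

  grid <- dplyr::bind_rows(lapply(periods, function(p) {
    tibble::tibble(period = p, lag = seq(0, p - lag_step, by = lag_step))
  }))
  vals <- lapply(seq_len(nrow(grid)), function(i) {
    round(cos(2 * pi * (zt - grid$lag[i]) / grid$period[i]), 9)
  })
  pattern <- vapply(vals, function(v) {
    paste(rank(v, ties.method = "average"), collapse = ",")
  }, character(1))
  out <- grid
  out$values <- vals
  out$tie_pattern <- lapply(vals, tie_pattern_of)
  out$pattern <- pattern
  out$distinct <- !duplicated(pattern)
  structure(tibble::as_tibble(out),
            n_distinct = sum(out$distinct), zt = zt,
            class = c("jtk_refs", class(out)))
}

#' Kendall-tau rank correlation statistic S
#'
#' `S = sum over i < j of sign(series[j] - series[i]) * sign(ref[j] - ref[i])`.
#' Pairs tied in either vector, or involving a missing data value, contribute
#' zero.
#'
#' @param series Numeric data series.
#' @param ref Reference values of the same length (numeric vector, or one row
#'   of [reference_waveforms()]).
#' @return Integer statistic.
#' @export
jtk_statistic <- function(series, ref) {
  if (is.list(ref)) ref <- ref$values[[1]]
  if (length(series) != length(ref)) {
    stop("series and reference lengths differ (", length(series), " vs ",
         length(ref), ")", call. = FALSE)
  }
  keep <- !is.na(series)
  # round so analytically tied values compare equal, as in the tie patterns
  s <- round(series[keep], 9)
  r <- round(ref[keep], 9)
  n <- length(s)
  if (n < 2) return(0L)
  ds <- sign(outer(s, s, "-"))
  dr <- sign(outer(r, r, "-"))
  as.integer(sum((ds * dr)[upper.tri(ds)]))
}

# pair index helper: rows of all i < j pairs for n samples
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# signs of ref[j] - ref[i] over the pair index, one row per ref
ref_sign_matrix <- function(refs, pairs) {
  t(vapply(refs$values, function(v) {
    sign(v[pairs[, 2]] - v[pairs[, 1]])
  }, numeric(nrow(pairs))))
}

# cached upper-tail functions per (ref pattern, data tie pattern)
null_cache_get <- function(cache, ref_ties, data_ties, n, exact_limit) {
  key <- paste(paste(ref_ties, collapse = "."),
               paste(data_ties, collapse = "."), n, sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  null <- exact_null_distribution(ref_ties, data_ties, n, exact_limit)
  val <- if (attr(null, "approx")) {
    list(approx = TRUE, null = null)
  } else {
    max_s <- n * (n - 1) / 2
    tail <- rep(1, 2 * max_s + 2)
    pr <- rep(0, 2 * max_s + 1)
    pr[null$s + max_s + 1] <- null$prob
    tail[seq_len(2 * max_s + 1)] <- rev(cumsum(rev(pr)))
    # tail[k] = P(S >= k - 1 - max_s); index with s + max_s + 1
    list(approx = FALSE, tail = tail, max_s = max_s)
  }
  cache[[key]] <- val
  val
}

tail_p <- function(entry, s_obs) {
  if (entry$approx) return(null_pvalue(entry$null, s_obs))
  entry$tail[s_obs + entry$max_s + 1]
}

#' JTK test of a single series
#'
#' Tests one series against every reference waveform: per distinct reference,
#' the one-sided upper-tail exact p of the observed S (antiphase alternatives
#' are covered by the phase grid); the raw p is the minimum across
#' references, and the adjusted p Bonferroni-multiplies it by the number of
#' distinct references. Among references attaining the minimum, ties are
#' broken toward the longer period, then the smaller lag. The amplitude is
#' the least-squares cosinor half-amplitude at the best (period, lag).
#' Missing values drop their pairs from S and from the null.
#'
#' @param series Numeric series (at least 4 non-missing values).
#' @param design A [sampling_design()] or numeric ZT vector matching
#'   `series`.
#' @param periods,lag_step Reference grid, see [reference_waveforms()].
#' @param threshold Adjusted-p cutoff for the `rhythmic` flag.
#' @param exact_limit Passed to [exact_null_distribution()].
#' @param refs Optional precomputed [reference_waveforms()] for `design`.
#' @return One-row tibble: `best_period`, `best_lag`, `amplitude`, `raw_p`,
#'   `adj_p`, `rhythmic`, `n_refs`, `approx`.
#' @examples
#' zt <- seq(0, 21, 3)
#' x <- 5 + 2 * cos(2 * pi * (zt - 6) / 24)
#' jtk_test(x, zt)
#' @export
jtk_test <- function(series, design = sampling_design(), periods = 20:28,
                     lag_step = 1, threshold = 0.05, exact_limit = 25,
                     refs = NULL) {
  zt <- if (inherits(design, "sampling_design")) sample_times(design)$zt
        else as.numeric(design)
  if (length(series) != length(zt)) {
    stop("series length must match the design", call. = FALSE)
  }
  keep <- !is.na(series)
  if (sum(keep) < 4) {
    stop("need at least 4 non-missing values", call. = FALSE)
  }
  refs <- refs %||% reference_waveforms(zt, periods, lag_step)
  if (!all(keep)) {
    # re-derive the grid on the observed timepoints only
    refs <- reference_waveforms(zt[keep],
                                periods = sort(unique(refs$period)),
                                lag_step = lag_step)
    series <- series[keep]
    zt <- zt[keep]
  }
  n <- length(series)
  fit <- jtk_core(matrix(series, nrow = 1), zt, refs, exact_limit)
  out <- fit$results
  out$rhythmic <- out$adj_p < threshold
  out$n_refs <- attr(refs, "n_distinct")
  out[, c("best_period", "best_lag", "amplitude", "raw_p", "adj_p",
          "rhythmic", "n_refs", "approx")]
}

# shared engine: series in rows, no missing values
jtk_core <- function(x, zt, refs, exact_limit) {
  # round so analytically tied values (e.g. exact cosines) compare equal,
  # consistently with the reference tie patterns
  x <- round(x, 9)
  n <- ncol(x)
  nf <- nrow(x)
  pairs <- pair_index(n)
  dref <- refs[refs$distinct, ]
  rs <- ref_sign_matrix(dref, pairs)
  ds <- matrix(sign(x[, pairs[, 2], drop = FALSE] -
                      x[, pairs[, 1], drop = FALSE]), nrow = nf)
  smat <- ds %*% t(rs)  # features x distinct refs

  cache <- new.env(parent = emptyenv())
  data_sig <- apply(x, 1, function(r) paste(tie_pattern_of(r), collapse = "."))
  pmat <- matrix(1, nf, nrow(dref))
  approx_used <- logical(nf)
  for (sig in unique(data_sig)) {
    rows <- which(data_sig == sig)
    dt <- as.integer(strsplit(sig, ".", fixed = TRUE)[[1]])
    for (j in seq_len(nrow(dref))) {
      entry <- null_cache_get(cache, dref$tie_pattern[[j]], dt, n, exact_limit)
      if (entry$approx) {
        approx_used[rows] <- TRUE
        pmat[rows, j] <- vapply(smat[rows, j], function(s) tail_p(entry, s),
                                numeric(1))
      } else {
        pmat[rows, j] <- entry$tail[smat[rows, j] + entry$max_s + 1]
      }
    }
  }

  n_distinct <- attr(refs, "n_distinct")
  raw_p <- apply(pmat, 1, min)
  adj_p <- pmin(1, raw_p * n_distinct)

  # constant series: every pair tied, S = 0 against everything, p must be 1
  const <- apply(x, 1, function(r) length(unique(r)) == 1)
  raw_p[const] <- 1
  adj_p[const] <- 1

  # best reference among all (period, lag) whose pattern attains the minimum
  # p; ties broken by longer period, then smaller lag
  best_period <- best_lag <- amplitude <- numeric(nf)
  pattern_of_distinct <- dref$pattern
  for (i in seq_len(nf)) {
    if (const[i]) {
      best_period[i] <- NA_real_
      best_lag[i] <- NA_real_
      amplitude[i] <- 0
      next
    }
    hit_patterns <- pattern_of_distinct[pmat[i, ] <= raw_p[i]]
    cand <- refs[refs$pattern %in% hit_patterns,
                 c("period", "lag")]
    cand <- cand[order(-cand$period, cand$lag), ]
    best_period[i] <- cand$period[1]
    best_lag[i] <- cand$lag[1]
    cref <- cos(2 * pi * (zt - best_lag[i]) / best_period[i])
    cc <- cref - mean(cref)
    amplitude[i] <- sum((x[i, ] - mean(x[i, ])) * cc) / sum(cc^2)
  }

  results <- tibble::tibble(
    feature = rownames(x) %||% as.character(seq_len(nf)),
    best_period = best_period,
    best_lag = best_lag,
    amplitude = amplitude,
    raw_p = raw_p,
    adj_p = adj_p,
    approx = approx_used
  )
  list(results = results, n_distinct = n_distinct)
}

#' Rhythm detection across a whole time-course table
#'
#' Runs the JTK test of [jtk_test()] on every feature of a time-course
#' table. Features with missing values are handled individually (their pairs
#' and null adapt to the observed timepoints); features with fewer than 4
#' observed values get `adj_p = 1` and a message.
#'
#' @param tc A `tc_tbl` time-course table (see [timecourse()]).
#' @param periods,lag_step Reference grid, see [reference_waveforms()].
#' @param threshold Adjusted-p cutoff for the `rhythmic` flag (layer
#'   dependent: 0.05 for RNA-based layers, 0.1 for protein/DBP).
#' @param exact_limit Passed to [exact_null_distribution()].
#' @param feature_adjust `"none"` (default: Bonferroni across references
#'   only, per feature) or `"bonferroni"` to additionally correct across
#'   features.
#' @return An object of class `jtk_fit`; use [tidy()] for the per-feature
#'   table and [glance()] for the one-row summary.
#' @examples
#' p <- cosinor_params(c("a", "b"), baseline = c(10, 10),
#'                     amplitude = c(5, 0), phase = 3, noise_sd = 0.5)
#' tc <- generate_timecourse(p, seed = 1)
#' tidy(jtk(tc))
#' @export
jtk <- function(tc, periods = 20:28, lag_step = 1, threshold = 0.05,
                exact_limit = 25, feature_adjust = c("none", "bonferroni")) {
  feature_adjust <- match.arg(feature_adjust)
  zt <- tc_zt(tc)
  x <- tc_values(tc)
  if (nrow(x) == 0) stop("empty time-course table", call. = FALSE)
  refs <- reference_waveforms(zt, periods, lag_step)

  has_na <- apply(x, 1, anyNA)
  results <- vector("list", 2)
  if (any(!has_na)) {
    results[[1]] <- jtk_core(x[!has_na, , drop = FALSE], zt, refs,
                             exact_limit)$results
  }
  if (any(has_na)) {
    rows <- which(has_na)
    res_na <- lapply(rows, function(i) {
      if (sum(!is.na(x[i, ])) < 4) {
        return(tibble::tibble(feature = rownames(x)[i],
                              best_period = NA_real_, best_lag = NA_real_,
                              amplitude = NA_real_, raw_p = 1, adj_p = 1,
                              approx = FALSE))
      }
      r <- jtk_test(x[i, ], zt, periods = periods, lag_step = lag_step,
                    threshold = threshold, exact_limit = exact_limit)
      tibble::tibble(feature = rownames(x)[i],
                     best_period = r$best_period, best_lag = r$best_lag,
                     amplitude = r$amplitude, raw_p = r$raw_p,
                     adj_p = r$adj_p, approx = r$approx)
    })
    if (any(vapply(res_na, function(r) r$adj_p == 1 && is.na(r$best_period),
                   logical(1)))) {
      rlang::inform("some features had fewer than 4 observed values; adj_p set to 1")
    }
    results[[2]] <- dplyr::bind_rows(res_na)
  }
  res <- dplyr::bind_rows(results)
  res <- res[match(rownames(x), res$feature), ]
  if (feature_adjust == "bonferroni") {
    res$adj_p <- pmin(1, res$adj_p * nrow(res))
  }
  res$rhythmic <- res$adj_p < threshold

  structure(
    list(results = res,
         refs = refs,
         n_refs = attr(refs, "n_distinct"),
         threshold = threshold,
         zt = zt,
         unit = tc_unit(tc),
         feature_adjust = feature_adjust,
         exact_limit = exact_limit),
    class = "jtk_fit"
  )
}

#' Apply a rhythmicity threshold to JTK results
#'
#' The flag uses a strictly-less comparison: `rhythmic = adj_p < threshold`.
#'
#' @param results A `jtk_fit` or a tibble with an `adj_p` column.
#' @param threshold Probability cutoff in (0, 1).
#' @return The input with its `rhythmic` column recomputed (for a `jtk_fit`,
#'   the stored threshold is updated too).
#' @export
call_rhythmic <- function(results, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  if (inherits(results, "jtk_fit")) {
    results$threshold <- threshold
    results$results$rhythmic <- results$results$adj_p < threshold
    return(results)
  }
  if (!"adj_p" %in% names(results)) {
    stop("`results` must have an `adj_p` column", call. = FALSE)
  }
  results$rhythmic <- results$adj_p < threshold
  results
}

#' @export
print.jtk_fit <- function(x, ...) {
  cat("<jtk_fit> ", nrow(x$results), " features, ", x$n_refs,
      " distinct reference waveforms, threshold ", x$threshold, "\n",
      "  rhythmic: ", sum(x$results$rhythmic), "\n", sep = "")
  invisible(x)
}

#' @rdname jtk
#' @param x A `jtk_fit`.
#' @param ... Unused.
#' @export
tidy.jtk_fit <- function(x, ...) x$results

#' @rdname jtk
#' @export
glance.jtk_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_rhythmic = sum(x$results$rhythmic),
    n_refs = x$n_refs,
    threshold = x$threshold,
    feature_adjust = x$feature_adjust,
    any_approx = any(x$results$approx)
  )
}

#' @rdname jtk
#' @param object A `jtk_fit`.
#' @param type `"phase"` (amplitude vs peak time) or `"pvalue"` (adjusted-p
#'   histogram).
#' @export
autoplot.jtk_fit <- function(object, type = c("phase", "pvalue"), ...) {
  type <- match.arg(type)
  d <- object$results
  if (type == "phase") {
    ggplot2::ggplot(d[!is.na(d$best_lag), ],
                    ggplot2::aes(x = .data$best_lag, y = .data$amplitude,
                                 colour = .data$rhythmic)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
      ggplot2::labs(x = "peak time (ZT h)", y = "cosinor amplitude",
                    colour = paste0("adj p < ", object$threshold))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$adj_p)) +
      ggplot2::geom_histogram(bins = 40, boundary = 0) +
      ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
      ggplot2::labs(x = "Bonferroni-adjusted p", y = "features")
  }
}
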