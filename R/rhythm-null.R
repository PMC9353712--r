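# Exact null distribution of the Jonckheere-Terpstra / Kendall-tau statistic
#   S = sum_{i<j} sign(x_j - x_i) * sign(r_j - r_i)
# under random permutation of the data values against a fixed reference,
# conditional on the tie patterns of both vectors.
#
# Two exact routes:
#  * one ranking untied: S = 2*J - T where J is the classic Jonckheere-
#    Terpstra count, which decomposes into independent Mann-Whitney counts
#    between each reference tie group and its predecessors; each factor is a
#    Gaussian-binomial polynomial built by convolution.
#  * both rankings tied: dynamic programme over the multiset of data values,
#    filling reference tie groups one at a time and tracking how many copies
#    of each distinct value have been placed.
# Permutation enumeration is never used here; it lives in the test suite as
# the independent oracle.

#' Exact null distribution of the rank-correlation statistic S
#'
#' Distribution of `S` over all distinct permutations of the data values
#' against a fixed reference waveform, conditional on the tie patterns of
#' both rankings. The distribution is symmetric about zero and depends on the
#' patterns only through the group sizes.
#'
#' @param ref_ties Integer vector of tie-group sizes of the reference values
#'   (order irrelevant); must sum to `n`.
#' @param data_ties Integer vector of tie-group sizes of the data values;
#'   must sum to `n`.
#' @param n Number of samples.
#' @param exact_limit Largest `n` for which the exact distribution is
#'   computed; above it a normal approximation with the tie-corrected
#'   variance and a continuity correction is used and the result is flagged
#'   `approx = TRUE`.
#' @return An object of class `jtk_null`: a tibble with columns `s` and
#'   `prob` (empty for the approximate case) and attributes `approx`, `n`,
#'   and `sd` (the null standard deviation, for the approximate tail).
#' @examples
#' exact_null_distribution(rep(1, 4), rep(1, 4)) # P(S = 6) = 1/24
#' @export
exact_null_distribution <- function(ref_ties, data_ties, n = sum(ref_ties),
                                    exact_limit = 25) {
  ref_ties <- as.integer(ref_ties[ref_ties > 0])
  data_ties <- as.integer(data_ties[data_ties > 0])
  if (sum(ref_ties) != n || sum(data_ties) != n) {
    stop("tie patterns must sum to n = ", n, call. = FALSE)
  }
  if (n < 2) stop("need at least two samples", call. = FALSE)

  ref_untied <- all(ref_ties == 1)
  data_untied <- all(data_ties == 1)

  if (n <= exact_limit) {
    if (data_untied || ref_untied) {
      # S is symmetric in the two rankings; make the untied one the data
      groups <- if (data_untied) ref_ties else data_ties
      counts <- jt_untied_counts(groups)
    } else {
      counts <- jt_tied_counts(ref_ties, data_ties)
    }
    if (!is.null(counts)) {
      total <- sum(counts$weight)
      keep <- counts$weight > 0
      out <- tibble::tibble(s = counts$s[keep],
                            prob = counts$weight[keep] / total)
      return(structure(out, approx = FALSE, n = n,
                       sd = sqrt(jt_null_var(ref_ties, data_ties, n)),
                       class = c("jtk_null", class(out))))
    }
    # fall through to the approximation when the tied-tied DP is infeasible
  }
  out <- tibble::tibble(s = numeric(), prob = numeric())
  structure(out, approx = TRUE, n = n,
            sd = sqrt(jt_null_var(ref_ties, data_ties, n)),
            class = c("jtk_null", class(out)))
}

#' Upper-tail p-value from a null distribution of S
#'
#' `P(S >= s_obs)` — exact when the null is exact, otherwise a normal tail
#' with continuity correction.
#'
#' @param null A `jtk_null` from [exact_null_distribution()].
#' @param s_obs Observed statistic.
#' @return Probability in (0, 1].
#' @export
null_pvalue <- function(null, s_obs) {
  stopifnot(inherits(null, "jtk_null"))
  if (attr(null, "approx")) {
    sd <- attr(null, "sd")
    if (sd == 0) return(1)
    return(stats::pnorm((s_obs - 0.5) / sd, lower.tail = FALSE))
  }
  p <- sum(null$prob[null$s >= s_obs])
  min(max(p, 0), 1)
}

# ---- untied-data route: independent Mann-Whitney convolution ---------------

# Polynomial (coefficients over u = 0..m*g) of the number of interleavings of
# g new elements into m old ones by inversion count: the Gaussian binomial
# [m+g choose g]_q, built by the append-smallest-first recursion.
gauss_binom_poly <- function(m, g) {
  # Build the merged ranking smallest-rank first. Appending a NEW element
  # after o old ones makes it larger than all of them: +o to the
  # Mann-Whitney count U. Appending an OLD element adds nothing to U.
  # f[[o+1]] = coefficient vector over u for (o old, j new) placed.
  f <- vector("list", m + 1)
  for (o in 0:m) f[[o + 1]] <- 1  # j = 0: one arrangement, u = 0
  for (j in seq_len(g)) {
    fn <- vector("list", m + 1)
    fn[[1]] <- 1  # o = 0: only new elements so far, u = 0
    for (o in seq_len(m)) {
      a <- fn[[o]]                     # last element old: no shift
      b <- c(rep(0, o), f[[o + 1]])    # last element new: shift by o
      len <- max(length(a), length(b))
      fn[[o + 1]] <- c(a, rep(0, len - length(a))) +
        c(b, rep(0, len - length(b)))
    }
    f <- fn
  }
  poly <- f[[m + 1]]
  c(poly, rep(0, max(0, m * g + 1 - length(poly))))
}

poly_mult <- function(a, b) {
  if (length(a) == 1) return(a[1] * b)
  if (length(b) == 1) return(b[1] * a)
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

# counts of S for untied data against reference tie groups `groups`
jt_untied_counts <- function(groups) {
  n <- sum(groups)
  # J = sum of independent Mann-Whitney counts: group b vs all predecessors
  poly <- 1
  m <- 0
  for (g in groups) {
    if (m > 0) poly <- poly_mult(poly, gauss_binom_poly(m, g))
    m <- m + g
  }
  t_pairs <- (n^2 - sum(groups^2)) / 2  # pairs untied in the reference
  j_vals <- seq_along(poly) - 1
  list(s = 2 * j_vals - t_pairs, weight = poly)
}

# ---- tied-tied route: used-counts dynamic programme ------------------------

# counts of S when both rankings are tied; returns NULL if the state space
# is too large to be practical (caller falls back to the approximation)
jt_tied_counts <- function(ref_ties, data_ties, max_states = 2e5) {
  # group sizes are taken in increasing-value order on both sides
  dm <- as.integer(data_ties)
  if (prod(dm + 1) > max_states) return(NULL)
  n <- sum(dm)
  nv <- length(dm)
  max_s <- n * (n - 1) / 2
  width <- 2 * max_s + 1

  # states keyed by used-count vector; each holds a weight vector over S
  states <- new.env(parent = emptyenv())
  key <- function(u) paste(u, collapse = ",")
  u0 <- rep(0L, nv)
  e <- new.env(parent = emptyenv())
  e$used <- u0
  e$w <- {
    w <- rep(0, width); w[max_s + 1] <- 1; w
  }
  assign(key(u0), e, envir = states)

  compositions <- function(total, caps) {
    # all ways to split `total` over length(caps) slots with slot caps
    if (length(caps) == 1) {
      if (total <= caps[1]) return(matrix(total, 1, 1))
      return(matrix(0L, 0, 1))
    }
    out <- list()
    for (c1 in 0:min(total, caps[1])) {
      rest <- compositions(total - c1, caps[-1])
      if (nrow(rest) > 0) out[[length(out) + 1]] <- cbind(c1, rest)
    }
    if (length(out) == 0) return(matrix(0L, 0, length(caps)))
    do.call(rbind, out)
  }

  for (g in ref_ties) {
    new_states <- new.env(parent = emptyenv())
    for (k in ls(states)) {
      st <- get(k, envir = states)
      remaining <- dm - st$used
      comps <- compositions(g, remaining)
      if (!nrow(comps)) next
      below <- cumsum(c(0, st$used))[seq_len(nv)]        # used with value < v
      above <- rev(cumsum(c(0, rev(st$used))))[-1]       # used with value > v
      for (r in seq_len(nrow(comps))) {
        cc <- comps[r, ]
        delta <- sum(cc * (below - above))
        ways <- exp(lgamma(g + 1) - sum(lgamma(cc + 1)))
        u_new <- st$used + as.integer(cc)
        kk <- key(u_new)
        tgt <- if (exists(kk, envir = new_states)) {
          get(kk, envir = new_states)
        } else {
          t <- new.env(parent = emptyenv())
          t$used <- u_new
          t$w <- rep(0, width)
          assign(kk, t, envir = new_states)
          t
        }
        if (delta >= 0) {
          idx <- (delta + 1):width
          tgt$w[idx] <- tgt$w[idx] + ways * st$w[seq_len(width - delta)]
        } else {
          idx <- seq_len(width + delta)
          tgt$w[idx] <- tgt$w[idx] + ways * st$w[(1 - delta):width]
        }
      }
    }
    states <- new_states
  }
  final <- get(key(dm), envir = states)
  list(s = seq(-max_s, max_s), weight = final$w)
}

# tie-corrected null variance of S (Kendall); used for the normal tail
jt_null_var <- function(ref_ties, data_ties, n) {
  t1 <- function(x) sum(x * (x - 1) * (2 * x + 5))
  t2 <- function(x) sum(x * (x - 1) * (x - 2))
  t3 <- function(x) sum(x * (x - 1))
  v <- (n * (n - 1) * (2 * n + 5) - t1(ref_ties) - t1(data_ties)) / 18
  if (n > 2) {
    v <- v + t2(ref_ties) * t2(data_ties) / (9 * n * (n - 1) * (n - 2))
  }
  v + t3(ref_ties) * t3(data_ties) / (2 * n * (n - 1))
}

tie_pattern_of <- function(values) {
  as.integer(table(factor(round(values, 9))))
}
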