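# Independent oracles and small fixture builders used across the suite.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(p >= i, p + 1L, p)))
  }
  out
}

# brute-force null distribution of S by enumerating every permutation of the
# data values against the reference (the independent oracle for the DP)
enum_null <- function(ref_values, data_values) {
  n <- length(ref_values)
  P <- all_perms(n)
  pr <- t(utils::combn(n, 2))
  rs <- sign(ref_values[pr[, 2]] - ref_values[pr[, 1]])
  S <- rep(0, nrow(P))
  x <- matrix(data_values[P], nrow(P), n)
  for (k in seq_len(nrow(pr))) {
    S <- S + rs[k] * sign(x[, pr[k, 2]] - x[, pr[k, 1]])
  }
  tb <- table(S) / nrow(P)
  tibble::tibble(s = as.numeric(names(tb)), prob = as.numeric(tb))
}

# upper-tail p from an enumerated null
enum_tail <- function(null_tbl, s_obs) sum(null_tbl$prob[null_tbl$s >= s_obs])

default_zt <- seq(0, 21, 3)

# circular distance between two ZT hours
circ_hours <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# one strongly rhythmic + one flat gene, deterministic
tiny_params <- function() {
  cosinor_params(c("osc", "flat"), baseline = c(10, 10),
                 amplitude = c(5, 0), phase = c(6, 0), noise_sd = 0)
}

# toy gene set spanning all three window branches on both strands
toy_genes <- function() {
  gene_model(
    id = c("long_p", "mid_p", "short_p", "long_m"),
    chrom = "chrT",
    strand = c("+", "+", "+", "-"),
    tss = c(1000, 100000, 200000, 316000),
    tes = c(16000, 105000, 201500, 301000)
  )
}
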