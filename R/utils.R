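#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# circular difference in hours, result in [0, period)
circ_mod <- function(x, period) ((x %% period) + period) %% period

# smallest circular distance between two ZT hours
circ_dist <- function(a, b, period = 24) {
  d <- circ_mod(a - b, period)
  pmin(d, period - d)
}
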