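#' @importFrom rlang %||% .data
#' @importFrom stats setNames
NULL

# Quantile of a Normal(mean, sd) truncated to [lower, upper]; closed form via
# the inverse CDF, exact and monotone in p.
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# Draw from a truncated normal by inverse-CDF sampling.
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}
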