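# Internal numeric helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile function of a normal distribution truncated to [lower, upper]
#' @noRd
qtruncn <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + p * (pu - pl), mean, sd)
}

#' Draw from a truncated normal by inversion (vectorised over n)
#' @noRd
rtruncn <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  qtruncn(stats::runif(n), mean, sd, lower, upper)
}

#' Stratified (systematic) uniforms: one draw per 1/n stratum, in random order.
#' Keeps the empirical mean of any monotone transform close to its expectation
#' while every draw remains random. Used by cohort simulation for variance
#' control of calibration quantities.
#' @noRd
stratified_unif <- function(n) {
  (sample.int(n) - stats::runif(n)) / n
}

#' Allocate a group total of K successes over n units of size m each,
#' as evenly as possible; the remainder is assigned to random units.
#' Returns an integer vector of length n summing to K, entries in [0, m].
#' @noRd
allocate_counts <- function(K, n, m) {
  K <- min(max(K, 0L), n * m)
  base <- K %/% n
  rem <- K - base * n
  out <- rep.int(base, n)
  if (rem > 0) out[sample.int(n, rem)] <- base + 1L
  stopifnot(all(out <= m))
  out
}

#' Robust scale estimate (MAD, consistent with sd for Gaussians)
#' @noRd
robust_sd <- function(x) {
  s <- stats::mad(x)
  if (s == 0) stats::sd(x) else s
}

#' Derive a 32-bit-safe child seed from a base seed and a stream index
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}
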