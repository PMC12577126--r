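# Beta-binomial distribution in the (pi, rho) mean/intra-class-correlation
# parameterisation used throughout the allele-specific testing machinery:
#   shape1 = pi  * (1 - rho) / rho
#   shape2 = (1-pi) * (1 - rho) / rho
# rho -> 0 recovers the plain binomial.

#' Beta-binomial density
#'
#' Density of the beta-binomial distribution parameterised by the mean
#' success probability \code{pi} and the intra-class overdispersion
#' \code{rho} in \code{[0, 1)}. \code{rho = 0} is the binomial limit.
#'
#' @param x Number of successes (vectorised).
#' @param size Number of trials (vectorised).
#' @param pi Mean marginal probability of success, in (0, 1).
#' @param rho Overdispersion, in [0, 1).
#' @param log Return log density?
#' @return Numeric vector of (log-)densities.
#' @export
dbetabinom <- function(x, size, pi, rho, log = FALSE) {
  stopifnot_scalar_prob(pi, "pi")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  if (rho == 0) return(stats::dbinom(x, size, pi, log = log))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  ll[x < 0 | x > size | x != round(x)] <- -Inf
  if (log) ll else exp(ll)
}

#' Beta-binomial cumulative distribution
#'
#' @inheritParams dbetabinom
#' @param q Quantile (number of successes).
#' @return P(X <= q) for each element.
#' @export
pbetabinom <- function(q, size, pi, rho) {
  if (rho == 0) return(stats::pbinom(q, size, pi))
  n <- max(length(q), length(size))
  q <- rep_len(q, n); size <- rep_len(size, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    qi <- floor(q[i])
    if (qi < 0) { out[i] <- 0; next }
    if (qi >= size[i]) { out[i] <- 1; next }
    out[i] <- sum(dbetabinom(0:qi, size[i], pi, rho))
  }
  pmin(out, 1)
}

#' Beta-binomial random draws
#'
#' @inheritParams dbetabinom
#' @param n Number of draws.
#' @param size Number of trials (recycled).
#' @return Integer vector of draws.
#' @export
rbetabinom <- function(n, size, pi, rho) {
  stopifnot_scalar_prob(pi, "pi")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  size <- rep_len(size, n)
  if (rho == 0) return(stats::rbinom(n, size, pi))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}
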