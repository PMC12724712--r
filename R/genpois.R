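## Generalized Poisson distribution (Consul-Jain parameterization).
##
## P(Y = y) = theta (theta + alpha y)^(y-1) exp(-(theta + alpha y)) / y!
## with mean theta/(1-alpha) and variance theta/(1-alpha)^3 for |alpha| < 1.
## For alpha < 0 the support is truncated where theta + alpha y <= 0 and the
## pmf no longer sums to one; it is renormalized over the truncated support.

genpois_support_max <- function(theta, alpha) {
  if (alpha >= 0) return(Inf)
  # largest y with theta + alpha*y > 0
  m <- ceiling(-theta / alpha) - 1
  max(0, floor(m + 1e-12))
}

genpois_raw_logpmf <- function(y, theta, alpha) {
  lp <- rep(-Inf, length(y))
  ok <- y >= 0 & (theta + alpha * y) > 0
  yy <- y[ok]
  lp[ok] <- log(theta) + (yy - 1) * log(theta + alpha * yy) -
    (theta + alpha * yy) - lgamma(yy + 1)
  lp
}

## summation cap: the truncated support can be enormous for alpha near 0-,
## but mass beyond mean + 20 sd is negligible
genpois_sum_cap <- function(theta, alpha) {
  mu <- theta / (1 - alpha)
  sdv <- sqrt(theta) / (1 - alpha)^1.5
  min(genpois_support_max(theta, alpha), ceiling(mu + 20 * sdv + 100))
}

genpois_lognorm <- function(theta, alpha) {
  # log of the raw-pmf total mass (0 for alpha >= 0)
  if (alpha >= 0) return(0)
  ymax <- genpois_sum_cap(theta, alpha)
  lp <- genpois_raw_logpmf(0:ymax, theta, alpha)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

## vectorized total-mass computation for alpha < 0: one lgamma/log matrix
## over the common support instead of a per-theta loop
genpois_lognorm_vec <- function(theta, alpha) {
  ymax <- max(vapply(theta, genpois_sum_cap, 0, alpha = alpha))
  yy <- 0:ymax
  M <- outer(theta, yy, function(th, y) {
    z <- th + alpha * y
    ifelse(z > 0,
           log(th) + (y - 1) * log(pmax(z, 1e-300)) - z - lgamma(y + 1),
           -Inf)
  })
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Generalized Poisson probability mass function
#'
#' Two-parameter count distribution used as the observation model for binned
#' ongoing spike counts. The dispersion parameter \code{alpha} gives variance
#' above (\code{alpha > 0}) or below (\code{alpha < 0}) the Poisson level;
#' \code{alpha = 0} recovers the Poisson distribution with mean \code{theta}.
#' For \code{alpha < 0} the support is finite and the mass function is
#' renormalized over it.
#'
#' @param y nonnegative integer count(s).
#' @param theta positive rate-like parameter; the mean is
#'   \code{theta / (1 - alpha)}.
#' @param alpha dispersion in (-1, 1).
#' @param log logical; return log-probability.
#' @return Probability (or log-probability) of \code{y}.
#' @examples
#' dgenpois(0, theta = 2, alpha = 0, log = TRUE)  # -2, Poisson reduction
#' @export
dgenpois <- function(y, theta, alpha, log = FALSE) {
  if (abs(alpha) >= 1) stop("|alpha| must be < 1")
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(y != floor(y) | y < 0)) stop("y must be nonnegative integers")
  if (length(theta) == 1L) {
    lp <- genpois_raw_logpmf(y, theta, alpha) - genpois_lognorm(theta, alpha)
  } else {
    stopifnot(length(theta) == length(y))
    lp <- genpois_raw_logpmf(y, theta, alpha)
    if (alpha < 0)
      lp <- lp - genpois_lognorm_vec(theta, alpha)
  }
  if (log) lp else exp(lp)
}

#' Sample from the generalized Poisson distribution
#'
#' Inversion sampling from the (renormalized) pmf. Randomness comes from R's
#' global RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param n number of draws.
#' @param theta positive parameter (scalar or length-n vector).
#' @param alpha dispersion in (-1, 1).
#' @return Integer vector of draws.
#' @export
rgenpois <- function(n, theta, alpha) {
  if (abs(alpha) >= 1) stop("|alpha| must be < 1")
  if (alpha == 0) {
    return(rpois(n, if (length(theta) == 1L) rep(theta, n) else theta))
  }
  th <- if (length(theta) == 1L) rep(theta, n) else theta
  stopifnot(length(th) == n)
  u <- runif(n)
  out <- integer(n)
  # group identical theta values so the cdf is built once per value
  for (tv in unique(th)) {
    sel <- which(th == tv)
    mu <- tv / (1 - alpha)
    sdv <- sqrt(tv) / (1 - alpha)^1.5
    cap <- if (alpha < 0) genpois_sum_cap(tv, alpha)
           else ceiling(mu + 12 * sdv + 20)
    p <- dgenpois(0:cap, tv, alpha)
    cdf <- pmin(cumsum(p), 1)  # guard against floating drift above 1
    cdf[length(cdf)] <- 1
    out[sel] <- findInterval(u[sel], cdf) # counts strictly-below entries
  }
  out
}

#' Contaminated generalized Poisson log-likelihood
#'
#' Mixture of the generalized Poisson pmf (mean parameterization,
#' \code{theta = mu * (1 - alpha)}) with a small uniform contamination over
#' \code{0..yMax}, giving robustness to rare outlier bins:
#' \deqn{p(y) = (1 - p_{noise})\,\mathrm{GPois}(y;\mu(1-\alpha),\alpha) +
#'   p_{noise}/(y_{max}+1).}
#'
#' @param y observed count(s).
#' @param mu mean count(s) per bin (> 0), same length as \code{y} or scalar.
#' @param alpha dispersion in (-1, 1).
#' @param pNoise contamination weight; default 0.001.
#' @param yMax maximum representable count (at least \code{max(y)}).
#' @return Log-probability vector; never below
#'   \code{log(pNoise / (yMax + 1))}.
#' @export
contaminatedLogLik <- function(y, mu, alpha, pNoise = 0.001, yMax = max(y)) {
  if (pNoise < 0 || pNoise >= 1) stop("pNoise must be in [0, 1)")
  if (any(yMax < y)) stop("yMax must be >= all observed counts")
  theta <- mu * (1 - alpha)
  lg <- dgenpois(y, pmax(theta, 1e-12), alpha, log = TRUE)
  if (pNoise == 0) return(lg)
  lu <- log(pNoise) - log(yMax + 1)
  lm <- log1p(-pNoise) + lg
  pmax(lm, lu) + log1p(exp(pmin(lm, lu) - pmax(lm, lu)))
}
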