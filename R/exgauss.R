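#' The ex-Gaussian distribution
#'
#' Density, distribution function, survival function and random generation
#' for the ex-Gaussian distribution: the convolution of a Normal(mu, sigma)
#' and an Exponential(rate = 1/tau). It is the standard skewed model for
#' reaction-time data and is the finishing-time distribution of every
#' runner in the race model. The mean is `mu + tau` and the variance
#' `sigma^2 + tau^2`.
#'
#' The density is
#' \deqn{f(t) = \frac{1}{\tau}\exp\!\left(\frac{\mu-t}{\tau} +
#'   \frac{\sigma^2}{2\tau^2}\right)
#'   \Phi\!\left(\frac{t-\mu}{\sigma} - \frac{\sigma}{\tau}\right)}
#' evaluated in log space (the exponential factor can overflow long before
#' the product does).
#'
#' @param t Numeric vector of quantiles (seconds).
#' @param mu,sigma,tau Ex-Gaussian parameters; `sigma > 0`, `tau > 0`.
#' @param n Number of random draws.
#' @param log,log.p Return log density / log probability.
#' @return `dexgauss` the density, `pexgauss` the CDF, `sexgauss` the
#'   survival function `1 - CDF`, `rexgauss` a vector of `n` draws.
#' @examples
#' integrate(dexgauss, -Inf, Inf, mu = 0.5, sigma = 0.05, tau = 0.1)
#' mean(rexgauss(1e4, 0.5, 0.05, 0.1))  # ~ 0.6
#' @name exgauss
NULL

check_exg <- function(mu, sigma, tau) {
  if (any(!is.finite(c(mu, sigma, tau))) || any(sigma <= 0) || any(tau <= 0)) {
    rlang::abort(sprintf(
      "invalid ex-Gaussian parameters (mu=%s, sigma=%s, tau=%s)",
      toString(mu), toString(sigma), toString(tau)))
  }
}

#' @rdname exgauss
#' @export
dexgauss <- function(t, mu, sigma, tau, log = FALSE) {
  check_exg(mu, sigma, tau)
  k <- (mu - t) / tau + sigma^2 / (2 * tau^2)
  lf <- -base::log(tau) + k +
    pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
  lf[!is.finite(t)] <- -Inf
  if (log) lf else exp(lf)
}

#' @rdname exgauss
#' @export
pexgauss <- function(t, mu, sigma, tau, log.p = FALSE) {
  check_exg(mu, sigma, tau)
  p <- 1 - sexgauss(t, mu, sigma, tau)
  if (log.p) base::log(p) else p
}

#' @rdname exgauss
#' @export
sexgauss <- function(t, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  u <- (t - mu) / sigma
  k <- (mu - t) / tau + sigma^2 / (2 * tau^2)
  # S(t) = Phi(-u) + exp(k) * Phi(u - sigma/tau); the second term is kept in
  # log space because k grows linearly as t -> -Inf while log Phi offsets it.
  s <- pnorm(-u) + exp(k + pnorm(u - sigma / tau, log.p = TRUE))
  s[t == -Inf] <- 1
  s[t == Inf] <- 0
  pmin(pmax(s, 0), 1)
}

#' @rdname exgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}
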