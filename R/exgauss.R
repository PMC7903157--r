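#' The ex-Gaussian distribution
#'
#' Density, distribution function and random generation for the ex-Gaussian
#' (exponentially modified Gaussian) distribution: the sum of a
#' Normal(mu, sigma) and an independent Exponential with mean tau. Its mean is
#' `mu + tau` and its variance `sigma^2 + tau^2`. Response-time and
#' stop-signal reaction time (SSRT) distributions are conventionally
#' positively skewed and well described by this family, with `tau` capturing
#' the slow tail.
#'
#' All computations are carried out on the log scale where cancellation is a
#' risk, so densities are finite for any finite `x`.
#'
#' @param x,q numeric vector of quantiles (ms in this package's usage).
#' @param n number of draws.
#' @param mu mean of the Gaussian component.
#' @param sigma standard deviation of the Gaussian component (> 0).
#' @param tau mean of the exponential component (> 0).
#' @param log,log.p logical; return log-density / log-probability.
#' @param lower.tail logical; if `FALSE` return the survival function.
#' @return `dexgauss` the (log) density, `pexgauss` the (log) distribution or
#'   survival function, `rexgauss` a numeric vector of draws.
#' @examples
#' dexgauss(450, mu = 400, sigma = 50, tau = 100)
#' pexgauss(450, mu = 400, sigma = 50, tau = 100)
#' mean(rexgauss(1e4, 400, 50, 100))  # ~ mu + tau = 500
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(sigma, tau)
  z <- (x - mu) / sigma
  lf <- -log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, lower.tail = TRUE, log.p = FALSE) {
  check_exgauss_params(sigma, tau)
  z <- (q - mu) / sigma
  # survival is a sum of two positive terms -> always stable in log space
  la <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  lb <- (mu - q) / tau + sigma^2 / (2 * tau^2) +
    pnorm(z - sigma / tau, log.p = TRUE)
  lsurv <- pmax(la, lb) + log1p(exp(-abs(la - lb)))
  lsurv <- pmin(lsurv, 0)
  if (lower.tail) {
    p <- -expm1(lsurv)
    if (log.p) log(p) else p
  } else {
    if (log.p) lsurv else exp(lsurv)
  }
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exgauss_params(sigma, tau)
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

check_exgauss_params <- function(sigma, tau) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("ex-Gaussian 'sigma' must be strictly positive", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("ex-Gaussian 'tau' must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

#' Race-model parameter set
#'
#' Bundles the go-process and stop-process ex-Gaussian parameters and the
#' trigger-failure probability `p_tf` (probability that the stop process never
#' launches on a stop trial, so the go response is emitted regardless of the
#' stop-signal delay).
#'
#' @param mu_go,sigma_go,tau_go go-process ex-Gaussian parameters (ms).
#' @param mu_stop,sigma_stop,tau_stop stop-process (SSRT) parameters (ms).
#' @param p_tf trigger-failure probability in `[0, 1]`.
#' @return an object of class `race_params` (a named list).
#' @examples
#' race_params(400, 50, 100, 200, 30, 50, p_tf = 0.02)
#' @export
race_params <- function(mu_go, sigma_go, tau_go,
                        mu_stop, sigma_stop, tau_stop, p_tf = 0) {
  check_exgauss_params(sigma_go, tau_go)
  check_exgauss_params(sigma_stop, tau_stop)
  stopifnot(is.finite(mu_go), is.finite(mu_stop))
  if (!is.finite(p_tf) || p_tf < 0 || p_tf > 1)
    stop("'p_tf' must lie in [0, 1]", call. = FALSE)
  structure(list(mu_go = mu_go, sigma_go = sigma_go, tau_go = tau_go,
                 mu_stop = mu_stop, sigma_stop = sigma_stop,
                 tau_stop = tau_stop, p_tf = p_tf),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters (ms):\n")
  cat(sprintf("  go:   mu = %.1f, sigma = %.1f, tau = %.1f  (mean %.1f)\n",
              x$mu_go, x$sigma_go, x$tau_go, x$mu_go + x$tau_go))
  cat(sprintf("  stop: mu = %.1f, sigma = %.1f, tau = %.1f  (mean %.1f)\n",
              x$mu_stop, x$sigma_stop, x$tau_stop, x$mu_stop + x$tau_stop))
  cat(sprintf("  trigger-failure probability: %.3f\n", x$p_tf))
  invisible(x)
}
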