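#' Zero-inflated truncated-normal log-likelihood of a family's curve
#'
#' The observation model behind the hierarchical fit, exposed for testing
#' and for posterior-predictive checks. A plant's growth rate is an exact
#' zero with probability \eqn{\pi = \mathrm{logit}^{-1}(\gamma_0 +
#' \gamma_1\mu)} and otherwise Normal(\eqn{\mu}, \eqn{\sigma}) truncated to
#' \eqn{(0,\infty)}, with \eqn{\mu} the expected curve value at the plant's
#' temperature. The total log-likelihood is
#' \deqn{\sum_i \log[\pi_i 1(y_i = 0) + (1-\pi_i)\,
#'   \mathrm{TN}(y_i; \mu_i, \sigma)\, 1(y_i > 0)].}
#'
#' @param params a [tpc_params()] object (curve, noise and zero-inflation
#'   parameters).
#' @param temp_c temperatures of the observations.
#' @param rgr non-negative growth rates.
#' @return the summed log-likelihood (a single finite number for valid
#'   inputs).
#' @export
tpc_loglik <- function(params, temp_c, rgr) {
  validate_tpc_params(params)
  if (length(temp_c) != length(rgr))
    stop("'temp_c' and 'rgr' must have the same length", call. = FALSE)
  if (any(!is.finite(rgr)) || any(rgr < 0))
    stop("growth rates must be finite and non-negative", call. = FALSE)
  mu <- tpc_evaluate(params, temp_c)
  zi_truncnorm_loglik(rgr, mu, params$noise_sd, params$zi_intercept,
                      params$zi_slope)
}

# vectorised core; sigma is guarded away from 0 to avoid density spikes
zi_truncnorm_loglik <- function(y, mu, sigma, gamma0, gamma1) {
  sigma <- max(sigma, 1e-6)
  eta <- gamma0 + gamma1 * mu
  zero <- y == 0
  ll <- numeric(length(y))
  ll[zero] <- stats::plogis(eta[zero], log.p = TRUE)
  if (any(!zero)) {
    i <- !zero
    ll[i] <- stats::plogis(-eta[i], log.p = TRUE) +
      stats::dnorm(y[i], mu[i], sigma, log = TRUE) -
      stats::pnorm(0, mu[i], sigma, lower.tail = FALSE, log.p = TRUE)
  }
  sum(ll)
}

# moments of Normal(mu, sigma) truncated to (0, Inf); used for Pearson
# residuals in the posterior-predictive discrepancy
truncnorm_moments <- function(mu, sigma) {
  alpha <- -mu / sigma
  lz <- stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE)
  lam <- exp(stats::dnorm(alpha, log = TRUE) - lz)   # hazard phi/Z
  m <- mu + sigma * lam
  v <- sigma^2 * pmax(1 + alpha * lam - lam^2, 1e-12)
  list(mean = m, sd = sqrt(v))
}
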