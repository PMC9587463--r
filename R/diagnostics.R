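# Split-R-hat and effective sample size, computed per parameter from the
# per-chain draw matrices (standard Gelman-et-al definitions; each chain is
# split in half so within-chain drift also inflates R-hat).

split_chains <- function(mats) {
  out <- list()
  for (m in mats) {
    n <- nrow(m)
    h <- n %/% 2L
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[(n - h + 1L):n, , drop = FALSE]))
  }
  out
}

rhat_one <- function(x) {                      # x: iterations x chains
  m <- ncol(x); n <- nrow(x)
  if (n < 4L) return(NA_real_)
  cm <- colMeans(x)
  cv <- apply(x, 2L, stats::var)
  w <- mean(cv)
  b <- n * stats::var(cm)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_one <- function(x) {                       # Geyer initial monotone
  m <- ncol(x); n <- nrow(x)
  if (n < 4L) return(NA_real_)
  if (stats::sd(as.vector(x)) == 0) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  acfs <- vapply(seq_len(m), function(j) {
    v <- x[, j]
    if (stats::sd(v) == 0) return(rep(0, max_lag + 1L))
    stats::acf(v, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1L, 1L]
  }, numeric(max_lag + 1L))
  rho <- rowMeans(acfs)
  # sum paired autocorrelations while positive and decreasing
  s <- 0
  prev <- Inf
  t <- 1L
  while (t + 1L <= length(rho) - 1L) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

mcmc_diagnostics <- function(chain_mats) {
  pars <- colnames(chain_mats[[1L]])
  halves <- split_chains(chain_mats)
  data.frame(
    parameter = pars,
    rhat = vapply(seq_along(pars), function(j)
      rhat_one(sapply(halves, function(m) m[, j])), numeric(1)),
    ess = vapply(seq_along(pars), function(j)
      ess_one(sapply(chain_mats, function(m) m[, j])), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Posterior-predictive Bayesian p-value
#'
#' Goodness-of-fit check of a fitted hierarchical curve model: for a subset
#' of posterior draws, a replicate data set is simulated from the fitted
#' model at the observed temperatures and a chi-square-type discrepancy is
#' compared between replicate and observed data. The discrepancy is the sum
#' of squared Pearson residuals of the positive (non-zero) observations,
#' using the truncated-normal mean and standard deviation, plus the squared
#' standardised differences between observed and expected exact-zero counts
#' within each temperature regime (so misplaced zeros are penalised, not
#' just a wrong total).
#' The p-value is the fraction of draws whose replicate discrepancy is at
#' least the observed one (ties count as exceedances); values near 0.5
#' indicate adequate fit, values near 0 or 1 indicate misfit.
#'
#' @param fit a [fit_tpc()] result.
#' @param n_rep number of posterior draws used (thinned evenly).
#' @return a single value in \code{[0, 1]}.
#' @export
bayesian_p <- function(fit, n_rep = 400L) {
  stopifnot(inherits(fit, "tpc_fit"))
  ndraw <- nrow(fit$draws)
  if (ndraw == 0L) stop("fit contains no retained draws", call. = FALSE)
  idx <- unique(round(seq(1L, ndraw, length.out = min(n_rep, ndraw))))
  set.seed(fit$config$seed + 104729L)

  pre <- tpc_preprocess(fit$observations, fit$window)
  sobs <- pre$observations
  families <- fit$families
  fam_idx <- match(as.character(sobs$family), families)
  x <- sobs$temp_c
  y <- sobs$rgr
  grp <- match(x, sort(unique(x)))

  exceed <- logical(length(idx))
  for (k in seq_along(idx)) {
    d <- idx[k]
    op <- obs_pars_from_w(c(fit$draws[d, "log_sigma"],
                            fit$draws[d, "gamma0"],
                            fit$draws[d, "log_neg_gamma1"]))
    mu <- numeric(length(x))
    for (f in seq_along(families)) {
      i <- fam_idx == f
      zf <- fit$draws[d, z_cols(f)]
      mu[i] <- eval_mu_z(zf, x[i])
    }
    y_rep <- rzi_truncnorm(mu, op$sigma, op$gamma0, op$gamma1)
    t_obs <- discrepancy(y, mu, op, grp)
    t_rep <- discrepancy(y_rep, mu, op, grp)
    exceed[k] <- t_rep >= t_obs
  }
  mean(exceed)
}

# chi-square-type discrepancy: Pearson residuals of the positive part plus
# standardised squared errors in the per-regime zero counts
discrepancy <- function(y, mu, op, group) {
  pi0 <- stats::plogis(op$gamma0 + op$gamma1 * mu)
  pos <- y > 0
  t1 <- 0
  if (any(pos)) {
    mom <- truncnorm_moments(mu[pos], op$sigma)
    t1 <- sum(((y[pos] - mom$mean) / mom$sd)^2)
  }
  n0 <- as.numeric(rowsum((y == 0) + 0, group))
  ez <- as.numeric(rowsum(pi0, group))
  vz <- pmax(as.numeric(rowsum(pi0 * (1 - pi0), group)), 1e-8)
  t1 + sum((n0 - ez)^2 / vz)
}
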