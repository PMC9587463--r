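#' @export
print.tpc_fit <- function(x, ...) {
  cfg <- x$config
  cat("Hierarchical zero-inflated thermal performance fit\n")
  cat(sprintf("  population %s (pair %s): %d families, %d plants\n",
              x$population, x$pair, length(x$families), x$n_obs))
  cat(sprintf("  %d chains x %d iterations (%d warmup): %d retained draws\n",
              cfg$chains, cfg$iterations, cfg$warmup, nrow(x$draws)))
  cat(sprintf("  max split-R-hat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              if (x$convergence_ok) "" else "  [convergence warnings]"))
  invisible(x)
}

#' Posterior-mean curve parameters per family
#'
#' @param object a [fit_tpc()] result.
#' @param ... unused.
#' @return matrix (families x parameters) of posterior means in natural
#'   units (degrees C, raw growth-rate units).
#' @export
coef.tpc_fit <- function(object, ...) {
  apply(object$family_draws, c(2L, 3L), mean)
}

#' Posterior-mean expected performance curves
#'
#' @param object a [fit_tpc()] result.
#' @param newdata optional data.frame with column \code{temp_c} (and
#'   optionally \code{family}); defaults to a fine temperature grid over
#'   the measurement window for every family.
#' @param ... unused.
#' @return data.frame with columns family, temp_c, rgr_hat (posterior mean
#'   of the expected curve).
#' @export
predict.tpc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    grid <- seq(object$window$t_min, object$window$t_max, length.out = 101L)
    newdata <- expand.grid(family = object$families, temp_c = grid,
                           stringsAsFactors = FALSE)
  }
  if (is.null(newdata$family))
    newdata <- merge(newdata, data.frame(family = object$families))
  nd <- nrow(object$draws)
  idx <- unique(round(seq(1L, nd, length.out = min(200L, nd))))
  out <- newdata
  out$rgr_hat <- NA_real_
  for (f in seq_along(object$families)) {
    rows <- which(newdata$family == object$families[f])
    if (!length(rows)) next
    x <- newdata$temp_c[rows]
    acc <- numeric(length(x))
    for (d in idx) {
      p <- object$family_draws[d, f, ]
      acc <- acc + kuma_eval_nat(p, x)
    }
    out$rgr_hat[rows] <- acc / length(idx)
  }
  out
}

# evaluate a natural-unit parameter vector (lower, upper, shape_a, shape_b,
# height) without constructor overhead
kuma_eval_nat <- function(p, x) {
  t <- (x - p[["lower"]]) / (p[["upper"]] - p[["lower"]])
  mu <- numeric(length(x))
  inside <- t > 0 & t < 1
  if (any(inside)) {
    a <- p[["shape_a"]]; b <- p[["shape_b"]]
    tm <- kuma_mode(a, b)
    mu[inside] <- p[["height"]] *
      exp(kuma_log_kernel(t[inside], a, b) - kuma_log_kernel(tm, a, b))
  }
  mu
}

#' Pearson residuals at posterior-mean parameters
#'
#' For positive observations, residuals use the truncated-normal mean and
#' standard deviation at the posterior-mean curve; exact zeros get the
#' standardised residual of the zero indicator against its fitted
#' probability.
#'
#' @param object a [fit_tpc()] result.
#' @param ... unused.
#' @return numeric vector aligned with \code{object$observations}.
#' @export
residuals.tpc_fit <- function(object, ...) {
  cf <- coef(object)
  op <- colMeans(object$obs_draws)
  obs <- object$observations
  fidx <- match(as.character(obs$family), object$families)
  mu <- numeric(nrow(obs))
  for (f in seq_along(object$families))
    mu[fidx == f] <- kuma_eval_nat(cf[f, ], obs$temp_c[fidx == f])
  pi0 <- stats::plogis(op[["gamma0"]] + op[["gamma1"]] * mu)
  r <- numeric(nrow(obs))
  pos <- obs$rgr > 0
  if (any(pos)) {
    mom <- truncnorm_moments(mu[pos], op[["sigma"]])
    r[pos] <- (obs$rgr[pos] - mom$mean) / mom$sd
  }
  r[!pos] <- (1 - pi0[!pos]) / sqrt(pmax(pi0[!pos] * (1 - pi0[!pos]), 1e-12))
  r
}

#' Simulate posterior-predictive data sets
#'
#' Draws replicate observation tables from the fitted model at the
#' observed design points, one posterior draw per simulation.
#'
#' @param object a [fit_tpc()] result.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{nsim} observation tables (same layout as the
#'   fitted data).
#' @export
simulate.tpc_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$observations
  fidx <- match(as.character(obs$family), object$families)
  nd <- nrow(object$draws)
  picks <- sample.int(nd, nsim, replace = nsim > nd)
  lapply(picks, function(d) {
    mu <- numeric(nrow(obs))
    for (f in seq_along(object$families))
      mu[fidx == f] <- kuma_eval_nat(object$family_draws[d, f, ],
                                     obs$temp_c[fidx == f])
    out <- obs
    out$rgr <- rzi_truncnorm(mu, object$obs_draws$sigma[d],
                             object$obs_draws$gamma0[d],
                             object$obs_draws$gamma1[d])
    out
  })
}

#' Plot fitted family curves
#'
#' Posterior-mean thermal performance curve of every family over the
#' measurement window, with the observed growth rates overlaid and the
#' population envelope breadth marked on the temperature axis.
#'
#' @param x a [fit_tpc()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tpc_fit <- function(x, ...) {
  pr <- predict(x)
  obs <- x$observations
  graphics::plot(NA, xlim = range(pr$temp_c), ylim = range(c(obs$rgr, pr$rgr_hat)),
                 xlab = "Daytime temperature (°C)",
                 ylab = "Relative growth rate",
                 main = sprintf("%s: family thermal performance curves",
                                x$population), ...)
  graphics::points(obs$temp_c, obs$rgr, pch = 16,
                   col = grDevices::adjustcolor("grey40", 0.4))
  cols <- grDevices::hcl.colors(length(x$families), "Dark 3")
  for (f in seq_along(x$families)) {
    i <- pr$family == x$families[f]
    graphics::lines(pr$temp_c[i], pr$rgr_hat[i], col = cols[f])
  }
  dd <- tpc_derived_draws(x)
  env <- c(mean(apply(dd$lower, 1L, min)), mean(apply(dd$upper, 1L, max)))
  graphics::abline(v = env, lty = 2)
  invisible(x)
}
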