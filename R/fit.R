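#' Sampler configuration for hierarchical curve fitting
#'
#' Controls for [fit_tpc()]. Defaults follow the published analysis: 6000
#' iterations per chain (half discarded as warmup), 4 chains, priors whose
#' back-transformed centres sit at 16 C (critical thermal minimum) and
#' 51 C (critical thermal maximum). \code{adapt_delta} and
#' \code{max_tree_depth} are Hamiltonian-sampler controls; the
#' Metropolis-within-Gibbs backend used here records them in the fit's
#' notes but does not use them.
#'
#' @param iterations MCMC iterations per chain, including warmup.
#' @param warmup warmup (adaptation) iterations per chain; draws from the
#'   warmup phase are discarded, so each fit retains
#'   \code{chains * (iterations - warmup)} draws.
#' @param chains number of independent chains.
#' @param adapt_delta,max_tree_depth recorded for compatibility with
#'   Hamiltonian backends; unused by the Metropolis backend.
#' @param prior_ctmin_center,prior_ctmax_center prior centres (degrees C)
#'   for the population-level critical thermal limits.
#' @param seed integer seed; fits are deterministic given (seed, config,
#'   data).
#' @return a list of class \code{"tpc_fit_config"}.
#' @export
tpc_fit_config <- function(iterations = 6000L, warmup = iterations %/% 2L,
                           chains = 4L, adapt_delta = 0.95,
                           max_tree_depth = 12L,
                           prior_ctmin_center = 16,
                           prior_ctmax_center = 51,
                           seed = 1L) {
  stopifnot(iterations > warmup, warmup >= 1, chains >= 1,
            adapt_delta > 0, adapt_delta < 1,
            prior_ctmin_center < prior_ctmax_center)
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup), chains = as.integer(chains),
                 adapt_delta = adapt_delta,
                 max_tree_depth = as.integer(max_tree_depth),
                 prior_ctmin_center = prior_ctmin_center,
                 prior_ctmax_center = prior_ctmax_center,
                 seed = as.integer(seed)),
            class = "tpc_fit_config")
}

#' Reduced sampler settings
#'
#' A smaller configuration (2 chains of 3000 iterations) for simulation
#' studies and continuous testing; effective sample sizes are accordingly
#' smaller than the full configuration's.
#' @inheritParams tpc_fit_config
#' @param ... passed on to [tpc_fit_config()].
#' @export
tpc_fit_config_reduced <- function(seed = 1L, ...) {
  tpc_fit_config(iterations = 3000L, warmup = 1500L, chains = 2L,
                 seed = seed, ...)
}

#' Fit a hierarchical zero-inflated thermal performance model
#'
#' Fits one population's family-structured growth data. Every family gets
#' its own Kumaraswamy-shaped performance curve; family-level parameters
#' are exchangeable draws from population-level normal distributions on an
#' unconstrained scale (critical minimum, log span, log(shape-1), log
#' height), and observations follow the zero-inflated truncated-normal
#' model of [tpc_loglik()]. Temperatures are centred and growth rates
#' scaled internally (see [tpc_preprocess()]); all reported draws are
#' back-transformed to degrees C and raw growth-rate units.
#'
#' Sampling uses blockwise adaptive random-walk Metropolis (one block per
#' family, plus blocks for population means, among-family scales, and the
#' observation parameters), with proposal scales and covariances adapted
#' during warmup only and frozen afterwards. Convergence is summarised by
#' split-R-hat and effective sample size per parameter; the fit warns (but
#' does not fail) when any R-hat exceeds 1.01 or any family-level
#' effective sample size falls below 700.
#'
#' @param obs observation table for a single population (columns
#'   population, pair, family, temp_c, rgr).
#' @param config a [tpc_fit_config()].
#' @param window a [tpc_window()]; used for centring and for breadth
#'   truncation in [summary.tpc_fit()].
#' @return an object of class \code{"tpc_fit"}; see
#'   [summary.tpc_fit()], [coef.tpc_fit()], [predict.tpc_fit()],
#'   [bayesian_p()].
#' @examples
#' sim <- simulate_tpc_population(n_families = 3,
#'   design = tpc_design(families_range = c(3, 3), reps_range = c(2, 2)),
#'   seed = 7)
#' fit <- suppressWarnings(fit_tpc(sim$observations,
#'   config = tpc_fit_config(iterations = 200, warmup = 100, chains = 2)))
#' fit
#' @export
fit_tpc <- function(obs, config = tpc_fit_config(), window = tpc_window()) {
  check_observations(obs)
  if (length(unique(obs$population)) != 1L)
    stop("'obs' must contain a single population; fit populations ",
         "separately (see run_pipeline)", call. = FALSE)
  if (length(unique(obs$temp_c)) < 3L)
    stop("need at least 3 distinct temperatures to identify a curve",
         call. = FALSE)

  pre <- tpc_preprocess(obs, window)
  sobs <- pre$observations
  scaling <- pre$scaling
  population <- obs$population[1L]
  pair <- as.character(obs$pair[1L])

  families <- sort(unique(as.character(sobs$family)))
  nf <- length(families)
  fam_idx <- match(as.character(sobs$family), families)
  fam_data <- lapply(seq_len(nf), function(f) {
    i <- fam_idx == f
    list(x = sobs$temp_c[i], y = sobs$rgr[i])
  })
  y_all <- sobs$rgr
  ord <- order(fam_idx)           # observations grouped by family for the
  y_ord <- y_all[ord]             # observation-block likelihood
  fam_ord <- fam_idx[ord]

  prior <- list(ctmin = config$prior_ctmin_center - scaling$temp_center,
                ctmax = config$prior_ctmax_center - scaling$temp_center)

  chains <- lapply(seq_len(config$chains), function(ch) {
    run_chain(fam_data, y_ord, fam_ord, nf, prior, config,
              chain_seed = config$seed * 1000L + ch)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$chains),
                  each = config$iterations - config$warmup)

  diag <- mcmc_diagnostics(lapply(chains, `[[`, "draws"))
  fam_pars <- grepl("\\[", diag$parameter)
  convergence_ok <- TRUE
  if (max(diag$rhat, na.rm = TRUE) > 1.01) {
    convergence_ok <- FALSE
    warning(sprintf("convergence: max split-R-hat = %.3f (> 1.01)",
                    max(diag$rhat, na.rm = TRUE)), call. = FALSE)
  }
  if (min(diag$ess[fam_pars], na.rm = TRUE) < 700) {
    convergence_ok <- FALSE
    warning(sprintf(
      "sampling reliability: min family-level effective sample size = %.0f (< 700)",
      min(diag$ess[fam_pars], na.rm = TRUE)), call. = FALSE)
  }

  # back-transform family-level draws to natural units
  ndraw <- nrow(draws)
  family_draws <- array(NA_real_, dim = c(ndraw, nf, 5L),
                        dimnames = list(NULL, families,
                                        c("lower", "upper", "shape_a",
                                          "shape_b", "height")))
  s <- scaling$rgr_scale[[population]]
  for (f in seq_len(nf)) {
    z <- draws[, z_cols(f), drop = FALSE]
    family_draws[, f, "lower"] <- z[, 1L] + scaling$temp_center
    family_draws[, f, "upper"] <- z[, 1L] + exp(z[, 2L]) + scaling$temp_center
    family_draws[, f, "shape_a"] <- 1 + exp(z[, 3L])
    family_draws[, f, "shape_b"] <- 1 + exp(z[, 4L])
    family_draws[, f, "height"] <- exp(z[, 5L]) * s
  }
  obs_draws <- data.frame(
    sigma = (1e-3 + exp(draws[, "log_sigma"])) * s,
    gamma0 = draws[, "gamma0"],
    gamma1 = -exp(draws[, "log_neg_gamma1"]) / s)

  structure(list(population = population, pair = pair,
                 families = families, n_obs = nrow(obs),
                 draws = draws, chain_id = chain_id,
                 family_draws = family_draws, obs_draws = obs_draws,
                 diagnostics = diag, convergence_ok = convergence_ok,
                 scaling = scaling, window = window, config = config,
                 observations = obs,
                 notes = paste0("backend: adaptive Metropolis-within-Gibbs; ",
                                "adapt_delta = ", config$adapt_delta,
                                " and max_tree_depth = ",
                                config$max_tree_depth,
                                " recorded but not used by this backend"),
                 call = match.call()),
            class = "tpc_fit")
}

z_cols <- function(f) sprintf("%s[%d]", tpc_z_names, f)

# fast expected-curve evaluation from an unconstrained family vector
eval_mu_z <- function(zf, x) {
  L <- zf[1L]; U <- L + exp(zf[2L])
  a <- 1 + exp(zf[3L]); b <- 1 + exp(zf[4L]); h <- exp(zf[5L])
  t <- (x - L) / (U - L)
  mu <- numeric(length(x))
  inside <- t > 0 & t < 1
  if (any(inside)) {
    tm <- kuma_mode(a, b)
    lk <- kuma_log_kernel(t[inside], a, b) - kuma_log_kernel(tm, a, b)
    mu[inside] <- h * exp(lk)
  }
  mu
}

# per-observation log-likelihood (same model as zi_truncnorm_loglik)
zi_ll_vec <- function(y, mu, sigma, gamma0, gamma1) {
  sigma <- max(sigma, 1e-6)
  eta <- gamma0 + gamma1 * mu
  zero <- y == 0
  ll <- stats::plogis(eta, log.p = TRUE)
  if (any(!zero)) {
    i <- !zero
    ll[i] <- stats::plogis(-eta[i], log.p = TRUE) +
      stats::dnorm(y[i], mu[i], sigma, log = TRUE) -
      stats::pnorm(0, mu[i], sigma, lower.tail = FALSE, log.p = TRUE)
  }
  ll
}

obs_pars_from_w <- function(w) {
  list(sigma = 1e-3 + exp(w[1L]), gamma0 = w[2L], gamma1 = -exp(w[3L]))
}

# log-priors --------------------------------------------------------------

lp_prior_mu <- function(mu, prior) {
  stats::dnorm(mu[1L], prior$ctmin, 3, log = TRUE) +
    stats::dnorm(mu[1L] + exp(mu[2L]), prior$ctmax, 3, log = TRUE) +
    mu[2L] +                                        # Jacobian d(ctmax)/d(log span)
    stats::dnorm(mu[3L], log(1.5), 1.5, log = TRUE) +
    stats::dnorm(mu[4L], log(1.5), 1.5, log = TRUE) +
    stats::dnorm(mu[5L], 0, 1.5, log = TRUE)
}

lp_prior_tau <- function(ltau) {
  tau <- exp(ltau)
  sum(stats::dnorm(tau, 0, 1, log = TRUE) + log(2) + ltau)
}

lp_prior_w <- function(w) {
  op <- obs_pars_from_w(w)
  stats::dnorm(op$sigma, 0, 1, log = TRUE) + log(2) + w[1L] +
    stats::dnorm(op$gamma0, 0, 2, log = TRUE) +
    stats::dnorm(-op$gamma1, 0, 2, log = TRUE) + log(2) + w[3L]
}

lp_hier <- function(zmat, mu, tau) {
  sum(stats::dnorm(zmat, matrix(mu, nrow(zmat), 5L, byrow = TRUE),
                   matrix(tau, nrow(zmat), 5L, byrow = TRUE), log = TRUE))
}

# one MCMC chain ----------------------------------------------------------
#
# Blockwise adaptive random-walk Metropolis. Per iteration: two sweeps over
# the family blocks, three sweeps over the population-mean and
# among-family-scale blocks (cheap, no likelihood), one joint translation
# move that shifts the population means and every family's parameters
# together (decouples the hierarchical location from the group mean, which
# otherwise mixes very slowly), and two sweeps of the observation block.
# Proposal scales adapt by Robbins-Monro toward 25% acceptance and proposal
# covariances are estimated from warmup history; both are frozen after
# warmup.

run_chain <- function(fam_data, y_ord, fam_ord, nf, prior, config,
                      chain_seed) {
  set.seed(chain_seed)
  n_iter <- config$iterations
  n_warm <- config$warmup

  # data-informed initial values, jittered per chain
  x_all <- unlist(lapply(fam_data, `[[`, "x"))
  L0 <- min(x_all) - 3
  U0 <- max(x_all) + 3
  zmat <- t(vapply(fam_data, function(fd) {
    h0 <- max(c(fd$y, 0.2))
    tpc_to_z(L0, U0, 2, 2, h0) + stats::rnorm(5, 0, 0.05)
  }, numeric(5)))
  mu <- colMeans(zmat) + stats::rnorm(5, 0, 0.02)
  ltau <- rep(log(0.3), 5) + stats::rnorm(5, 0, 0.02)
  w <- c(log(0.3), 2, log(5)) + stats::rnorm(3, 0, 0.02)
  tau <- exp(ltau)
  op <- obs_pars_from_w(w)

  mu_cache <- lapply(seq_len(nf), function(f) eval_mu_z(zmat[f, ], fam_data[[f]]$x))
  ll_fam <- vapply(seq_len(nf), function(f)
    sum(zi_ll_vec(fam_data[[f]]$y, mu_cache[[f]], op$sigma, op$gamma0,
                  op$gamma1)), numeric(1))

  n_blocks <- nf + 3L
  dims <- c(rep(5L, nf), 5L, 5L, 3L)
  lsc <- c(rep(log(0.08), nf), log(0.05), log(0.15), log(0.08))
  chol_list <- lapply(dims, diag)
  hist_list <- lapply(dims, function(d)
    matrix(NA_real_, nrow = n_warm, ncol = d))

  keep <- matrix(NA_real_, nrow = n_iter - n_warm, ncol = 5L * nf + 13L)
  colnames(keep) <- c(unlist(lapply(seq_len(nf), z_cols)),
                      paste0("mu_", tpc_z_names),
                      paste0("log_tau_", tpc_z_names),
                      "log_sigma", "gamma0", "log_neg_gamma1")

  cnt <- numeric(n_blocks + 1L)        # per-block update counter
  ls_shift <- log(0.1)
  shift_sd <- c(0.5, 0.05, 0.1, 0.1, 0.05)

  prop <- function(b, cur) {
    cur + exp(lsc[b]) * drop(chol_list[[b]] %*% stats::rnorm(dims[b]))
  }
  tune_scale <- function(b, acc) {
    cnt[b] <<- cnt[b] + 1
    gam <- min(0.25, 2 / sqrt(cnt[b]))
    lsc[b] <<- lsc[b] + gam * (acc - 0.25)
  }
  tune_cov <- function(b, it) {
    if (it >= 150L && it %% 50L == 0L) {
      hh <- hist_list[[b]][max(1L, it %/% 3L):it, , drop = FALSE]
      cv <- stats::cov(hh) + diag(1e-8, dims[b])
      ch <- tryCatch(t(chol(cv)), error = function(e) NULL)
      if (!is.null(ch)) chol_list[[b]] <<- ch
    }
  }

  update_family <- function(f) {
    zc <- zmat[f, ]
    zp <- prop(f, zc)
    mup <- eval_mu_z(zp, fam_data[[f]]$x)
    llp <- sum(zi_ll_vec(fam_data[[f]]$y, mup, op$sigma, op$gamma0,
                         op$gamma1))
    dlp <- llp - ll_fam[f] +
      sum(stats::dnorm(zp, mu, tau, log = TRUE)) -
      sum(stats::dnorm(zc, mu, tau, log = TRUE))
    acc <- is.finite(dlp) && log(stats::runif(1)) < dlp
    if (acc) {
      zmat[f, ] <<- zp; mu_cache[[f]] <<- mup; ll_fam[f] <<- llp
    }
    acc
  }
  update_mu <- function() {
    mup_ <- prop(nf + 1L, mu)
    dlp <- lp_hier(zmat, mup_, tau) + lp_prior_mu(mup_, prior) -
      lp_hier(zmat, mu, tau) - lp_prior_mu(mu, prior)
    acc <- is.finite(dlp) && log(stats::runif(1)) < dlp
    if (acc) mu <<- mup_
    acc
  }
  update_tau <- function() {
    ltaup <- prop(nf + 2L, ltau)
    taup <- exp(ltaup)
    dlp <- lp_hier(zmat, mu, taup) + lp_prior_tau(ltaup) -
      lp_hier(zmat, mu, tau) - lp_prior_tau(ltau)
    acc <- is.finite(dlp) && log(stats::runif(1)) < dlp
    if (acc) { ltau <<- ltaup; tau <<- taup }
    acc
  }
  update_obs <- function() {
    wp <- prop(nf + 3L, w)
    opp <- obs_pars_from_w(wp)
    mu_all <- unlist(mu_cache)
    llvec_p <- zi_ll_vec(y_ord, mu_all, opp$sigma, opp$gamma0, opp$gamma1)
    dlp <- sum(llvec_p) + lp_prior_w(wp) - sum(ll_fam) - lp_prior_w(w)
    acc <- is.finite(dlp) && log(stats::runif(1)) < dlp
    if (acc) {
      w <<- wp; op <<- opp
      ll_fam <<- as.numeric(rowsum(llvec_p, fam_ord))
    }
    acc
  }
  # translate the population means and every family's parameters jointly;
  # the hierarchical prior is invariant, only the likelihood and the
  # population-level priors move
  update_shift <- function() {
    delta <- exp(ls_shift) * shift_sd * stats::rnorm(5L)
    mup_ <- mu + delta
    zp <- sweep(zmat, 2L, delta, "+")
    mu_new <- vector("list", nf)
    ll_new <- numeric(nf)
    for (f in seq_len(nf)) {
      mu_new[[f]] <- eval_mu_z(zp[f, ], fam_data[[f]]$x)
      ll_new[f] <- sum(zi_ll_vec(fam_data[[f]]$y, mu_new[[f]], op$sigma,
                                 op$gamma0, op$gamma1))
    }
    dlp <- sum(ll_new) - sum(ll_fam) +
      lp_prior_mu(mup_, prior) - lp_prior_mu(mu, prior)
    acc <- is.finite(dlp) && log(stats::runif(1)) < dlp
    if (acc) {
      mu <<- mup_; zmat <<- zp; mu_cache <<- mu_new; ll_fam <<- ll_new
    }
    acc
  }

  b_shift <- n_blocks + 1L
  for (it in seq_len(n_iter)) {
    warm <- it <= n_warm
    for (rep in 1:4)
      for (f in seq_len(nf)) {
        acc <- update_family(f)
        if (warm) tune_scale(f, as.numeric(acc))
      }
    for (rep in 1:3) {
      if (warm) tune_scale(nf + 1L, as.numeric(update_mu())) else update_mu()
      if (warm) tune_scale(nf + 2L, as.numeric(update_tau())) else update_tau()
    }
    acc <- update_shift()
    if (warm) {
      cnt[b_shift] <- cnt[b_shift] + 1
      ls_shift <- ls_shift +
        min(0.25, 2 / sqrt(cnt[b_shift])) * (as.numeric(acc) - 0.25)
    }
    for (rep in 1:2) {
      if (warm) tune_scale(nf + 3L, as.numeric(update_obs())) else update_obs()
    }
    if (warm) {
      for (f in seq_len(nf)) hist_list[[f]][it, ] <- zmat[f, ]
      hist_list[[nf + 1L]][it, ] <- mu
      hist_list[[nf + 2L]][it, ] <- ltau
      hist_list[[nf + 3L]][it, ] <- w
      for (b in seq_len(n_blocks)) tune_cov(b, it)
      if (it >= 150L) {
        mh <- hist_list[[nf + 1L]][max(1L, it - 600L):it, , drop = FALSE]
        shift_sd <- pmax(apply(mh, 2L, stats::sd), 1e-3)
      }
    } else {
      keep[it - n_warm, ] <- c(t(zmat), mu, ltau, w)
    }
  }
  list(draws = keep)
}
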