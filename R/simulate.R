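#' Design of a simulated thermal performance experiment
#'
#' Describes the layout of a growth-chamber study: paired populations,
#' full-sibling families nested in populations, and replicate plants per
#' family at each daytime temperature regime. The defaults emulate the
#' published monkeyflower design: 5 species pairs (10 populations), 11--50
#' families per population, 8 temperature regimes spanning 15--50 C, and
#' 3--6 replicates per family per regime, which yields well over 5000
#' individuals in total.
#'
#' @param n_pairs number of species pairs (each contributes 2 populations).
#' @param families_range integer range (min, max); each population's family
#'   count is drawn uniformly from it.
#' @param reps_range integer range; replicates per family x temperature are
#'   drawn uniformly from it (unbalanced, as in real data).
#' @param regime_temps daytime temperatures (degrees C) of the regimes.
#' @return an object of class \code{"tpc_design"}.
#' @export
tpc_design <- function(n_pairs = 5L, families_range = c(11L, 50L),
                       reps_range = c(3L, 6L),
                       regime_temps = seq(15, 50, by = 5)) {
  stopifnot(n_pairs >= 1, length(families_range) == 2L,
            all(families_range >= 1), length(reps_range) == 2L,
            all(reps_range >= 1))
  window <- tpc_window(regime_temps)
  structure(list(n_pairs = as.integer(n_pairs),
                 families_range = as.integer(sort(families_range)),
                 reps_range = as.integer(sort(reps_range)),
                 regime_temps = regime_temps, window = window),
            class = "tpc_design")
}

# default population-level generating curve (natural units): a mid-range
# Mimulus-like growth curve peaking near 31 C with RGR ~ 0.25 per day
default_pop_means <- function() {
  tpc_params(lower = 8, upper = 48, shape_a = 2.2, shape_b = 2.2,
             height = 0.25, noise_sd = 0.05, zi_intercept = 2,
             zi_slope = -40)
}

# baseline among-family standard deviations on the unconstrained z scale;
# optimum variation enters mostly through curve shape (skew) rather than
# location, as families within a population share habitat but differ in
# curve form
default_among_sds <- function() {
  c(ctmin = 0.3, log_span = 0.1, log_shape_a = 0.28, log_shape_b = 0.28,
    log_height = 0.2)
}

#' Simulate one population of family-structured performance data
#'
#' Draws each family's curve parameters as population mean + Normal(0, sd)
#' deviations on the unconstrained scale (critical minimum, log span,
#' log(shape-1), log height), so every simulated family is a valid curve.
#' Each plant's relative growth rate is a structural zero with probability
#' \eqn{\mathrm{logit}^{-1}(\gamma_0 + \gamma_1\mu)} and otherwise a
#' Normal(\eqn{\mu}, \eqn{\sigma}) draw truncated to \eqn{(0, \infty)},
#' where \eqn{\mu} is the family curve evaluated at the plant's temperature.
#'
#' @param pop_means a [tpc_params()] object of population-level means
#'   (curve parameters plus noise and zero-inflation parameters).
#' @param among_sds named non-negative vector of among-family standard
#'   deviations on the unconstrained scale, names
#'   \code{c("ctmin","log_span","log_shape_a","log_shape_b","log_height")}.
#' @param n_families number of full-sibling families; if \code{NULL}, drawn
#'   from \code{design$families_range}.
#' @param design a [tpc_design()].
#' @param population,pair identifier labels.
#' @param seed integer seed; the simulation is bitwise reproducible given
#'   the seed and design.
#' @return list with \code{observations} (long-format data.frame:
#'   population, pair, family, temp_c, rgr) and \code{truth} (per-family
#'   true parameters and derived optimum/breadth, with the population-level
#'   generating means and sds as attribute \code{"population_truth"}).
#' @export
simulate_tpc_population <- function(pop_means = default_pop_means(),
                                    among_sds = default_among_sds(),
                                    n_families = NULL,
                                    design = tpc_design(),
                                    population = "pop1", pair = "a",
                                    seed = NULL) {
  validate_tpc_params(pop_means)
  among_sds <- check_among_sds(among_sds)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_families))
    n_families <- sample_int_range(design$families_range, 1L)
  sim_population_core(pop_means, among_sds, n_families, design,
                      population, pair)
}

check_among_sds <- function(among_sds) {
  if (length(among_sds) == 1L && is.null(names(among_sds)))
    among_sds <- stats::setNames(rep(among_sds, 5L), tpc_z_names)
  if (!all(tpc_z_names %in% names(among_sds)))
    stop("'among_sds' must be named: ", paste(tpc_z_names, collapse = ", "),
         call. = FALSE)
  among_sds <- among_sds[tpc_z_names]
  if (any(!is.finite(among_sds)) || any(among_sds < 0))
    stop("'among_sds' must be finite and non-negative", call. = FALSE)
  among_sds
}

sample_int_range <- function(rng, n) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n)
  else sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
}

# core generator; assumes RNG state already set by the caller
sim_population_core <- function(pop_means, among_sds, n_families, design,
                                population, pair) {
  z_mean <- tpc_to_z(pop_means$lower, pop_means$upper, pop_means$shape_a,
                     pop_means$shape_b, pop_means$height)
  fam_z <- matrix(stats::rnorm(n_families * 5L, mean = rep(z_mean, each = n_families),
                               sd = rep(among_sds, each = n_families)),
                  nrow = n_families, ncol = 5L)
  # a family's span deviation widens or narrows its curve about the
  # population optimum (tolerance variation at similar optima) instead of
  # being anchored at the lower limit, so the ctmin deviation alone sets
  # the family's optimum location
  tstar0 <- kuma_mode(pop_means$shape_a, pop_means$shape_b)
  fam_z[, 1L] <- fam_z[, 1L] - tstar0 * (exp(fam_z[, 2L]) - exp(z_mean[2L]))
  fam_ids <- sprintf("%s_f%02d", population, seq_len(n_families))

  truth <- vector("list", n_families)
  obs <- vector("list", n_families)
  temps <- design$regime_temps
  n_temps <- length(temps)
  for (f in seq_len(n_families)) {
    cp <- tpc_from_z(fam_z[f, ])
    fp <- tpc_params(cp$lower, cp$upper, cp$shape_a, cp$shape_b, cp$height,
                     noise_sd = pop_means$noise_sd,
                     zi_intercept = pop_means$zi_intercept,
                     zi_slope = pop_means$zi_slope)
    br <- tpc_breadth(fp, threshold = 0.5, window = design$window)
    truth[[f]] <- data.frame(
      population = population, pair = pair, family = fam_ids[f],
      lower = fp$lower, upper = fp$upper, shape_a = fp$shape_a,
      shape_b = fp$shape_b, height = fp$height,
      topt = tpc_optimum(fp), breadth_lower = br$lower,
      breadth_upper = br$upper, breadth = br$breadth,
      stringsAsFactors = FALSE)
    reps <- sample_int_range(design$reps_range, n_temps)
    temp_c <- rep(temps, times = reps)
    mu <- tpc_evaluate(fp, temp_c)
    rgr <- rzi_truncnorm(mu, pop_means$noise_sd, pop_means$zi_intercept,
                         pop_means$zi_slope)
    obs[[f]] <- data.frame(population = population, pair = pair,
                           family = fam_ids[f], temp_c = temp_c, rgr = rgr,
                           stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  observations <- do.call(rbind, obs)
  rownames(truth) <- rownames(observations) <- NULL

  pop_truth <- data.frame(
    population = population, pair = pair, n_families = n_families,
    n_individuals = nrow(observations),
    pop_breadth = max(truth$breadth_upper) - min(truth$breadth_lower),
    family_breadth_mean = mean(truth$breadth),
    var_topt = stats::var(truth$topt),
    var_breadth = stats::var(truth$breadth),
    stringsAsFactors = FALSE)
  for (k in seq_along(tpc_z_names)) {
    pop_truth[[paste0("mean_", tpc_z_names[k])]] <- z_mean[k]
    pop_truth[[paste0("sd_", tpc_z_names[k])]] <- among_sds[[k]]
  }
  attr(truth, "population_truth") <- pop_truth
  list(observations = observations, truth = truth)
}

# zero-inflated truncated-normal observation draws (vectorised)
rzi_truncnorm <- function(mu, sd, zi_intercept, zi_slope) {
  n <- length(mu)
  pi0 <- stats::plogis(zi_intercept + zi_slope * mu)
  zero <- stats::runif(n) < pi0
  p_lo <- stats::pnorm(0, mean = mu, sd = sd)
  y <- stats::qnorm(stats::runif(n, p_lo, 1), mean = mu, sd = sd)
  y[zero] <- 0
  pmax(y, 0)
}

#' Simulate a paired-population niche-breadth study
#'
#' Generates a full multi-population experiment with known truth under one
#' of four scenarios that mirror the hypotheses about how populations
#' accrue niche breadth:
#' \describe{
#'   \item{\code{"null"}}{populations are exchangeable: all share the same
#'     generating means and among-family standard deviations, with
#'     pair-level shifts only (absorbed by the random intercept), so the
#'     expected envelope breadth is identical across populations and every
#'     generating slope between population breadth and a predictor is 0.
#'     Realised summaries still co-fluctuate mechanically (see the
#'     vignette), which bounds how cleanly type-I behaviour can be
#'     demonstrated at the study's own scale.}
#'   \item{\code{"generalist"}}{population mean curve span (hence family
#'     breadth) increases systematically across populations; among-family
#'     variation constant (general-purpose genotypes).}
#'   \item{\code{"divergent-optima"}}{among-family variation in the curve
#'     location (hence in thermal optimum) increases across populations;
#'     family breadths held constant (specialists with divergent optima).}
#'   \item{\code{"variable-breadth"}}{among-family variation in log curve
#'     span increases across populations; optimum variation constant.}
#' }
#' Each pair additionally receives shared random shifts in curve location
#' and span, giving the species-pair structure the hypothesis models absorb
#' with a random intercept.
#'
#' @param design a [tpc_design()].
#' @param scenario one of \code{"null"}, \code{"generalist"},
#'   \code{"divergent-optima"}, \code{"variable-breadth"}.
#' @param seed integer seed.
#' @param pop_means baseline population-level parameters.
#' @param among_sds baseline among-family standard deviations (z scale).
#' @return an object of class \code{"tpc_study"}: list with
#'   \code{observations} (all populations stacked), \code{truth}
#'   (per-family), \code{population_truth} (one row per population),
#'   \code{design}, \code{scenario}, \code{seed}.
#' @export
simulate_tpc_study <- function(design = tpc_design(),
                               scenario = c("null", "generalist",
                                            "divergent-optima",
                                            "variable-breadth"),
                               seed = 1L,
                               pop_means = default_pop_means(),
                               among_sds = default_among_sds()) {
  scenario <- match.arg(scenario)
  among_sds <- check_among_sds(among_sds)
  set.seed(seed)
  n_pop <- 2L * design$n_pairs
  pair_ids <- letters[seq_len(design$n_pairs)]

  # pair-level shared deviations (shared evolutionary history)
  pair_ctmin <- stats::rnorm(design$n_pairs, 0, 1)
  pair_span <- stats::rnorm(design$n_pairs, 0, 0.2)

  # scenario-specific population-level settings
  span_shift <- numeric(n_pop)
  ctmin_sd <- rep(among_sds[["ctmin"]], n_pop)
  span_sd <- rep(among_sds[["log_span"]], n_pop)
  if (scenario == "generalist") {
    span_shift <- seq(-0.25, 0.25, length.out = n_pop)[sample.int(n_pop)]
  } else if (scenario == "divergent-optima") {
    ctmin_sd <- seq(0.5, 4, length.out = n_pop)[sample.int(n_pop)]
    span_sd <- rep(0.02, n_pop)
  } else if (scenario == "variable-breadth") {
    span_sd <- seq(0.01, 0.28, length.out = n_pop)[sample.int(n_pop)]
    ctmin_sd <- rep(0.6, n_pop)
  }

  obs <- truth <- pop_truth <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    p <- (i + 1L) %/% 2L
    pm <- pop_means
    nf <- sample_int_range(design$families_range, 1L)
    sds <- among_sds
    sds[["ctmin"]] <- ctmin_sd[i]
    sds[["log_span"]] <- span_sd[i]
    pm$lower <- pm$lower + pair_ctmin[p]
    span <- (pop_means$upper - pop_means$lower) *
      exp(pair_span[p] + span_shift[i])
    pm$upper <- pm$lower + span
    sim <- sim_population_core(pm, sds, nf, design,
                               population = sprintf("pop%02d", i),
                               pair = pair_ids[p])
    obs[[i]] <- sim$observations
    pop_truth[[i]] <- attr(sim$truth, "population_truth")
    attr(sim$truth, "population_truth") <- NULL
    truth[[i]] <- sim$truth
  }
  structure(list(observations = do.call(rbind, obs),
                 truth = do.call(rbind, truth),
                 population_truth = do.call(rbind, pop_truth),
                 design = design, scenario = scenario, seed = seed),
            class = "tpc_study")
}

#' @export
print.tpc_study <- function(x, ...) {
  cat(sprintf("Simulated niche-breadth study ('%s' scenario, seed %d)\n",
              x$scenario, x$seed))
  cat(sprintf("  %d populations in %d pairs, %d families, %d plants\n",
              nrow(x$population_truth), x$design$n_pairs,
              nrow(x$truth), nrow(x$observations)))
  invisible(x)
}
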