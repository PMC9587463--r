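#' Per-draw family optima and breadth bounds from a fitted model
#'
#' For every retained posterior draw and every family, computes the thermal
#' optimum analytically and the 50%-performance breadth bounds by a
#' vectorised bisection on the relative curve scale, then truncates bounds
#' to the measurement window (each bound independently clipped to the
#' nearest measured temperature).
#'
#' @param fit a [fit_tpc()] result.
#' @param threshold fraction of peak performance defining breadth.
#' @return list with draws-by-families matrices \code{topt}, \code{lower},
#'   \code{upper}, \code{breadth}, logical matrices
#'   \code{truncated_lower}, \code{truncated_upper}, and the window.
#' @export
tpc_derived_draws <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "tpc_fit"))
  fd <- fit$family_draws
  nd <- dim(fd)[1L]; nf <- dim(fd)[2L]
  L <- fd[, , "lower", drop = FALSE]; dim(L) <- c(nd, nf)
  U <- fd[, , "upper", drop = FALSE]; dim(U) <- c(nd, nf)
  a <- fd[, , "shape_a", drop = FALSE]; dim(a) <- c(nd, nf)
  b <- fd[, , "shape_b", drop = FALSE]; dim(b) <- c(nd, nf)

  tstar <- ((a - 1) / (a * b - 1))^(1 / a)
  topt <- L + tstar * (U - L)
  t_lo <- kuma_rel_root(a, b, tstar, threshold, lower = TRUE)
  t_hi <- kuma_rel_root(a, b, tstar, threshold, lower = FALSE)
  lo <- L + t_lo * (U - L)
  hi <- L + t_hi * (U - L)
  w <- fit$window
  trunc_lo <- lo < w$t_min
  trunc_hi <- hi > w$t_max
  lo[trunc_lo] <- w$t_min
  hi[trunc_hi] <- w$t_max
  cn <- list(NULL, fit$families)
  dimnames(topt) <- dimnames(lo) <- dimnames(hi) <- cn
  list(topt = topt, lower = lo, upper = hi, breadth = hi - lo,
       truncated_lower = trunc_lo, truncated_upper = trunc_hi,
       window = w)
}

# vectorised bisection for g(t)/g(t*) = threshold on one side of the mode;
# a, b, tstar and the return value are arrays of identical shape
kuma_rel_root <- function(a, b, tstar, threshold, lower, tol = 1e-9) {
  la <- if (lower) 0 * a else tstar
  lb <- if (lower) tstar else 0 * a + 1
  lg_mode <- kuma_log_kernel(tstar, a, b)
  lthr <- log(threshold)
  for (i in seq_len(60L)) {
    m <- (la + lb) / 2
    val <- kuma_log_kernel(m, a, b) - lg_mode
    below <- val < lthr      # still outside the breadth region
    if (lower) {
      la[below] <- m[below]; lb[!below] <- m[!below]
    } else {
      lb[below] <- m[below]; la[!below] <- m[!below]
    }
    if (max(lb - la) < tol) break
  }
  (la + lb) / 2
}

#' Population envelope breadth per posterior draw
#'
#' The population-level thermal breadth of one draw is the envelope of its
#' family curves: the highest upper breadth bound minus the smallest lower
#' breadth bound across families (bounds already truncated to the
#' measurement window).
#'
#' @param x a [tpc_derived_draws()] result or a [fit_tpc()] object.
#' @param ... passed to [tpc_derived_draws()] when \code{x} is a fit.
#' @return numeric vector, one envelope breadth (degrees C) per draw.
#' @export
population_breadth_draws <- function(x, ...) {
  if (inherits(x, "tpc_fit")) x <- tpc_derived_draws(x, ...)
  apply(x$upper, 1L, max) - apply(x$lower, 1L, min)
}

#' Summarise a fitted population as one breadth-partitioning row
#'
#' Derives, per posterior draw, each family's optimum and breadth, the
#' population envelope breadth, the across-family mean breadth, and the
#' among-family variances (denominator n-1) of optimum and breadth; then
#' reports the posterior mean and central 95% credible interval of each,
#' together with the posterior-predictive Bayesian p-value and the bound
#' truncation rate.
#'
#' @param object a [fit_tpc()] result.
#' @param threshold fraction of peak performance defining breadth.
#' @param level credible-interval level (central, equal-tailed).
#' @param n_rep posterior draws used for the Bayesian p-value; set to 0 to
#'   skip that check.
#' @param ... unused.
#' @return a one-row data.frame of class \code{"tpc_breadth_summary"}.
#' @export
summary.tpc_fit <- function(object, threshold = 0.5, level = 0.95,
                            n_rep = 400L, ...) {
  dd <- tpc_derived_draws(object, threshold)
  nf <- length(object$families)
  pop <- population_breadth_draws(dd)
  fam_mean <- rowMeans(dd$breadth)
  if (nf < 2L) {
    warning("single family: among-family variances are undefined",
            call. = FALSE)
    v_topt <- v_breadth <- rep(NA_real_, length(pop))
  } else {
    v_topt <- apply(dd$topt, 1L, stats::var)
    v_breadth <- apply(dd$breadth, 1L, stats::var)
  }
  alpha <- (1 - level) / 2
  smy <- function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(v), stats::quantile(v, c(alpha, 1 - alpha), names = FALSE))
  }
  sp <- smy(pop); sf <- smy(fam_mean); st <- smy(v_topt); sb <- smy(v_breadth)
  out <- data.frame(
    population = object$population, pair = object$pair,
    n_families = nf, n_individuals = object$n_obs,
    pop_breadth = sp[1L], pop_breadth_lo = sp[2L], pop_breadth_hi = sp[3L],
    family_breadth = sf[1L], family_breadth_lo = sf[2L],
    family_breadth_hi = sf[3L],
    var_topt = st[1L], var_topt_lo = st[2L], var_topt_hi = st[3L],
    var_breadth = sb[1L], var_breadth_lo = sb[2L], var_breadth_hi = sb[3L],
    bayesian_p = if (n_rep > 0L) bayesian_p(object, n_rep) else NA_real_,
    truncation_rate = mean(c(dd$truncated_lower, dd$truncated_upper)),
    stringsAsFactors = FALSE)
  class(out) <- c("tpc_breadth_summary", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "level") <- level
  out
}

#' @export
print.tpc_breadth_summary <- function(x, digits = 2, ...) {
  cat("Breadth partitioning summary (posterior mean [95% CI])\n")
  fmt <- function(m, l, h) sprintf("%.*f [%.*f, %.*f]", digits, m,
                                   digits, l, digits, h)
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "  %s (pair %s, %d families, n = %d)\n    population breadth %s C; family breadth %s C\n    var(T_opt) %s; var(T_breadth) %s; Bayesian p = %.2f\n",
      x$population[i], x$pair[i], x$n_families[i], x$n_individuals[i],
      fmt(x$pop_breadth[i], x$pop_breadth_lo[i], x$pop_breadth_hi[i]),
      fmt(x$family_breadth[i], x$family_breadth_lo[i], x$family_breadth_hi[i]),
      fmt(x$var_topt[i], x$var_topt_lo[i], x$var_topt_hi[i]),
      fmt(x$var_breadth[i], x$var_breadth_lo[i], x$var_breadth_hi[i]),
      x$bayesian_p[i]))
  invisible(x)
}

#' Published monkeyflower breadth-partitioning estimates
#'
#' The packaged per-population summary for the 10 monkeyflower
#' (\emph{Mimulus}) populations: posterior means and 95% credible intervals
#' of population- and family-level thermal breadth and of the among-family
#' variances in thermal optimum and breadth, with species-pair membership
#' (pairs a-e) and sample sizes. These are the published point estimates,
#' shipped as a plain-text fixture; they are the inputs to the three
#' hypothesis models of [niche_partition()].
#'
#' @return data.frame of class \code{"tpc_breadth_summary"} with one row
#'   per population.
#' @examples
#' tab <- mimulus_breadths()
#' round(breadth_ratio(tab), 2)
#' @export
mimulus_breadths <- function() {
  path <- system.file("extdata", "mimulus_table1.csv",
                      package = "nichebreadth", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("tpc_breadth_summary", "data.frame")
  out
}

#' Ratio of family-level to population-level thermal breadth
#'
#' What fraction of a population's thermal breadth a typical genotype
#' covers: mean family breadth divided by population envelope breadth.
#'
#' @param summary a breadth summary (from [summary.tpc_fit()] or
#'   [mimulus_breadths()]).
#' @return numeric vector of fractions, named by population.
#' @export
breadth_ratio <- function(summary) {
  if (any(!is.finite(summary$pop_breadth)) || any(summary$pop_breadth <= 0))
    stop("population breadth must be positive", call. = FALSE)
  stats::setNames(summary$family_breadth / summary$pop_breadth,
                  summary$population)
}

#' Among-family standard deviation from a variance
#'
#' @param x non-negative variances (numeric), or a breadth summary, in
#'   which case the among-family variance in thermal optimum column is
#'   used.
#' @return element-wise square roots (degrees C).
#' @export
sd_from_variance <- function(x) {
  if (is.data.frame(x)) x <- x$var_topt
  if (any(x < 0, na.rm = TRUE))
    stop("variances must be non-negative", call. = FALSE)
  sqrt(x)
}
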