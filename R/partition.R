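#' Mixed-effects regression with a species-pair random intercept
#'
#' Fits \code{y ~ x + (1 | pair)} by REML, the workhorse of the three
#' niche-breadth hypothesis tests: each species pair gets its own
#' intercept (absorbing shared evolutionary history) while the slope is
#' common to all pairs. The p-value is a two-sided Wald t-test with
#' Satterthwaite degrees of freedom; variance explained is reported as
#' Nakagawa marginal R-squared, \eqn{\mathrm{var}(X\beta) /
#' (\mathrm{var}(X\beta) + \tau^2 + \sigma^2)}, and conditional R-squared,
#' which adds the pair variance \eqn{\tau^2} to the numerator. Singular
#' fits (pair variance estimated at zero) are allowed and reported as
#' such.
#'
#' @param y response vector (population-level thermal breadth, degrees C).
#' @param x predictor vector.
#' @param pair grouping labels (species pair per observation).
#' @param model character label carried into the result.
#' @return list of class \code{"lmm_result"}: \code{slope},
#'   \code{slope_se}, \code{p_value}, \code{df}, \code{marginal_r2},
#'   \code{conditional_r2}, \code{intercept}, \code{tau2}, \code{sigma2},
#'   \code{n_obs}, \code{n_groups}, \code{singular}, \code{model}.
#' @examples
#' tab <- mimulus_breadths()
#' fit_pair_lmm(tab$pop_breadth, tab$var_topt, tab$pair)
#' @export
fit_pair_lmm <- function(y, x, pair, model = "lmm") {
  if (length(y) != length(x) || length(y) != length(pair))
    stop("'y', 'x' and 'pair' must have equal length", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(x)))
    stop("'y' and 'x' must be finite", call. = FALSE)
  if (length(unique(pair)) < 2L)
    stop("need at least 2 species pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate input: predictor is constant", call. = FALSE)
  dat <- data.frame(y = y, x = x, pair = factor(pair))
  fit <- suppressMessages(lmerTest::lmer(
    y ~ x + (1 | pair), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  ct <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "pair"]
  sigma2 <- stats::sigma(fit)^2
  vfix <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  denom <- vfix + tau2 + sigma2
  structure(list(
    model = model,
    slope = unname(ct["x", "Estimate"]),
    slope_se = unname(ct["x", "Std. Error"]),
    df = unname(ct["x", "df"]),
    p_value = unname(ct["x", "Pr(>|t|)"]),
    intercept = unname(ct["(Intercept)", "Estimate"]),
    marginal_r2 = vfix / denom,
    conditional_r2 = (vfix + tau2) / denom,
    tau2 = tau2, sigma2 = sigma2,
    n_obs = nrow(dat), n_groups = nlevels(dat$pair),
    singular = lme4::isSingular(fit)),
    class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Pair-random-intercept LMM [%s]%s\n", x$model,
              if (isTRUE(x$singular)) " (singular: pair variance = 0)" else ""))
  cat(sprintf("  slope = %.4g (SE %.4g), t df = %.2f, p = %.4g\n",
              x$slope, x$slope_se, x$df, x$p_value))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f  (n = %d, %d pairs)\n",
              x$marginal_r2, x$conditional_r2, x$n_obs, x$n_groups))
  invisible(x)
}

#' Standardised mixed-effects regression
#'
#' As [fit_pair_lmm()], after z-scoring the response and the predictor
#' across all observations, so that slopes are comparable across the three
#' hypothesis models.
#'
#' @inheritParams fit_pair_lmm
#' @return an \code{"lmm_result"} for the standardised variables.
#' @export
standardize_and_fit <- function(y, x, pair, model = "lmm_std") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cannot standardise a zero-variance variable", call. = FALSE)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  fit_pair_lmm(zs(y), zs(x), pair, model = model)
}

#' Test how populations accrue thermal niche breadth
#'
#' Runs the three hypothesis models relating population-level thermal
#' breadth to properties of the families it contains, each as a
#' pair-random-intercept LMM in raw and standardised form:
#' \describe{
#'   \item{H1_generalist}{population breadth on family-level breadth (one
#'     observation per family; response is the family's population
#'     breadth): general-purpose genotypes.}
#'   \item{H2_divergent_optima}{population breadth on among-family
#'     variance in thermal optimum (one observation per population):
#'     specialised genotypes with divergent optima.}
#'   \item{H3_breadth_variation}{population breadth on among-family
#'     variance in thermal breadth (one observation per population):
#'     genetic variation in the degree of generalisation.}
#' }
#' A slope is flagged significant when it is positive and its one-sided
#' test clears \code{alpha} (two-sided Satterthwaite p divided by 2).
#'
#' @param summaries a breadth summary with one row per population
#'   ([summary.tpc_fit()] rows bound together, or [mimulus_breadths()]).
#' @param family_breadths optional per-family data.frame with columns
#'   \code{population}, \code{pair}, \code{breadth} (posterior-mean family
#'   breadth); without it the family-level model H1 is skipped with a
#'   warning.
#' @param alpha one-sided significance level for the slope decision rule.
#' @return object of class \code{"niche_partition"}: a data.frame with one
#'   row per hypothesis model (slope, SE, df, p, marginal and conditional
#'   R-squared, standardised slope and SE, significance flag).
#' @examples
#' niche_partition(mimulus_breadths())
#' @export
niche_partition <- function(summaries, family_breadths = NULL, alpha = 0.1) {
  stopifnot(is.data.frame(summaries))
  need <- c("population", "pair", "pop_breadth", "var_topt", "var_breadth")
  if (!all(need %in% names(summaries)))
    stop("'summaries' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)

  fits <- list()
  if (!is.null(family_breadths)) {
    fb <- family_breadths
    if (!all(c("population", "pair", "breadth") %in% names(fb)))
      stop("'family_breadths' must have columns population, pair, breadth",
           call. = FALSE)
    yb <- summaries$pop_breadth[match(fb$population, summaries$population)]
    if (any(is.na(yb)))
      stop("family_breadths contains populations absent from 'summaries'",
           call. = FALSE)
    fits$H1_generalist <- list(
      raw = fit_pair_lmm(yb, fb$breadth, fb$pair, "H1_generalist"),
      std = standardize_and_fit(yb, fb$breadth, fb$pair, "H1_generalist"))
  } else {
    warning("no per-family breadths supplied: family-level model ",
            "H1_generalist skipped", call. = FALSE)
  }
  fits$H2_divergent_optima <- list(
    raw = fit_pair_lmm(summaries$pop_breadth, summaries$var_topt,
                       summaries$pair, "H2_divergent_optima"),
    std = standardize_and_fit(summaries$pop_breadth, summaries$var_topt,
                              summaries$pair, "H2_divergent_optima"))
  fits$H3_breadth_variation <- list(
    raw = fit_pair_lmm(summaries$pop_breadth, summaries$var_breadth,
                       summaries$pair, "H3_breadth_variation"),
    std = standardize_and_fit(summaries$pop_breadth, summaries$var_breadth,
                              summaries$pair, "H3_breadth_variation"))

  out <- do.call(rbind, lapply(names(fits), function(nm) {
    r <- fits[[nm]]$raw; s <- fits[[nm]]$std
    data.frame(model = nm, slope = r$slope, slope_se = r$slope_se,
               df = r$df, p_value = r$p_value,
               marginal_r2 = r$marginal_r2,
               conditional_r2 = r$conditional_r2,
               std_slope = s$slope, std_slope_se = s$slope_se,
               n_obs = r$n_obs, n_groups = r$n_groups,
               significant = r$slope > 0 & r$p_value / 2 < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "fits") <- fits
  class(out) <- c("niche_partition", "data.frame")
  out
}

#' @export
print.niche_partition <- function(x, ...) {
  cat("Niche-breadth partitioning tests (pair-random-intercept LMMs)\n")
  cat(sprintf("One-sided slope > 0 rule at alpha = %.2g\n\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  df$slope <- sprintf("%.3f +/- %.3f", df$slope, df$slope_se)
  df$std_slope <- sprintf("%.3f +/- %.3f", df$std_slope, df$std_slope_se)
  df$p_value <- signif(df$p_value, 3)
  df$marginal_r2 <- round(df$marginal_r2, 3)
  df$conditional_r2 <- round(df$conditional_r2, 3)
  print(df[, c("model", "slope", "p_value", "marginal_r2",
               "conditional_r2", "std_slope", "significant")],
        row.names = FALSE)
  invisible(x)
}
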