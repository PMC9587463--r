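#' Thermal performance curve parameters
#'
#' Construct and validate the parameter set of a single genotype's thermal
#' performance curve (TPC) together with its observation-model parameters.
#' The curve is a mode-normalised Kumaraswamy kernel: with
#' \eqn{t = (x - L)/(U - L)} the kernel is
#' \eqn{g(t) = a b t^{a-1} (1 - t^a)^{b-1}}, and expected performance is
#' \eqn{P(x) = h \, g(t) / g(t^*)} on \eqn{(L, U)} and 0 outside, where
#' \eqn{t^* = ((a-1)/(ab-1))^{1/a}} is the kernel mode. Normalising by the
#' mode makes \code{height} directly interpretable as peak performance.
#'
#' @param lower critical thermal minimum \eqn{L} (degrees C); performance is
#'   exactly 0 at and below it.
#' @param upper critical thermal maximum \eqn{U} (degrees C); must exceed
#'   \code{lower}.
#' @param shape_a,shape_b dimensionless Kumaraswamy shapes; both must exceed
#'   1 so that an interior optimum exists.
#' @param height peak expected performance \eqn{h} (performance units, > 0).
#' @param noise_sd residual standard deviation of the truncated-normal
#'   observation noise (> 0).
#' @param zi_intercept,zi_slope zero-inflation parameters: an observation is
#'   a structural zero with probability
#'   \eqn{\mathrm{logit}^{-1}(\gamma_0 + \gamma_1 \mu)} where \eqn{\mu} is
#'   the expected performance at that temperature. \code{zi_slope} must be
#'   \eqn{\le 0} so zeros concentrate near the critical limits.
#' @return an object of class \code{"tpc_params"} (a named list).
#' @examples
#' p <- tpc_params(lower = 10, upper = 45, shape_a = 2, shape_b = 2,
#'                 height = 0.25)
#' tpc_optimum(p)
#' tpc_evaluate(p, seq(5, 50, 5))
#' @export
tpc_params <- function(lower, upper, shape_a, shape_b, height,
                       noise_sd = 0.05, zi_intercept = 2, zi_slope = -40) {
  p <- list(lower = lower, upper = upper, shape_a = shape_a,
            shape_b = shape_b, height = height, noise_sd = noise_sd,
            zi_intercept = zi_intercept, zi_slope = zi_slope)
  validate_tpc_params(p)
  structure(p, class = "tpc_params")
}

validate_tpc_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("lower", "upper", "shape_a", "shape_b", "height",
               "noise_sd", "zi_intercept", "zi_slope"))
    if (!num1(p[[nm]]))
      stop("'", nm, "' must be a single finite numeric value", call. = FALSE)
  if (p$lower >= p$upper)
    stop("invalid curve parameters: lower limit must be below upper limit",
         call. = FALSE)
  if (p$shape_a <= 1 || p$shape_a * p$shape_b <= 1)
    stop("invalid curve parameters: need shape_a > 1 and shape_a*shape_b > 1 ",
         "for an interior optimum", call. = FALSE)
  if (p$height <= 0)
    stop("invalid curve parameters: height must be positive", call. = FALSE)
  if (p$noise_sd <= 0)
    stop("invalid curve parameters: noise_sd must be positive", call. = FALSE)
  if (p$zi_slope > 0)
    stop("invalid curve parameters: zi_slope must be <= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.tpc_params <- function(x, ...) {
  cat("Thermal performance curve parameters\n")
  cat(sprintf("  limits: %.2f to %.2f C   optimum: %.2f C\n",
              x$lower, x$upper, tpc_optimum(x)))
  cat(sprintf("  shapes: a = %.3f, b = %.3f   height: %.4g\n",
              x$shape_a, x$shape_b, x$height))
  cat(sprintf("  noise sd: %.4g   zero-inflation: logit^-1(%.2f %+.2f mu)\n",
              x$noise_sd, x$zi_intercept, x$zi_slope))
  invisible(x)
}

# log of the Kumaraswamy kernel at relative position t in (0,1)
kuma_log_kernel <- function(t, a, b) {
  log(a) + log(b) + (a - 1) * log(t) + (b - 1) * log1p(-t^a)
}

# kernel mode on the relative (0,1) scale; requires a > 1, a*b > 1
kuma_mode <- function(a, b) ((a - 1) / (a * b - 1))^(1 / a)

#' Evaluate a thermal performance curve
#'
#' Expected performance at temperature \code{x}: zero at and outside the
#' critical limits, unimodal on \code{(lower, upper)} with maximum exactly
#' \code{height} at [tpc_optimum()].
#'
#' @param params a [tpc_params()] object.
#' @param x numeric vector of temperatures (degrees C).
#' @return numeric vector of expected performance values in
#'   \code{[0, height]}.
#' @export
tpc_evaluate <- function(params, x) {
  validate_tpc_params(params)
  a <- params$shape_a; b <- params$shape_b
  t <- (x - params$lower) / (params$upper - params$lower)
  out <- numeric(length(x))
  inside <- is.finite(t) & t > 0 & t < 1
  if (any(inside)) {
    lk <- kuma_log_kernel(t[inside], a, b) -
      kuma_log_kernel(kuma_mode(a, b), a, b)
    out[inside] <- params$height * exp(lk)
  }
  out
}

#' Thermal optimum of a performance curve
#'
#' The temperature at which expected performance is maximised, computed
#' analytically from the kernel mode:
#' \eqn{T_{opt} = L + t^* (U - L)} with
#' \eqn{t^* = ((a-1)/(ab-1))^{1/a}}.
#'
#' @inheritParams tpc_evaluate
#' @return a single temperature in \code{(lower, upper)}.
#' @export
tpc_optimum <- function(params) {
  validate_tpc_params(params)
  params$lower + kuma_mode(params$shape_a, params$shape_b) *
    (params$upper - params$lower)
}

#' Temperature measurement window
#'
#' The set of daytime temperature regimes of the growth-chamber experiment.
#' Breadth bounds that fall outside the window are truncated to the nearest
#' measured temperature, so population and family breadths never extrapolate
#' beyond the measured range.
#'
#' @param regime_temps strictly increasing temperatures (degrees C) of the
#'   experimental regimes. The default is the eight regimes spanning
#'   15--50 C.
#' @return an object of class \code{"tpc_window"} with elements
#'   \code{t_min}, \code{t_max} and \code{regime_temps}.
#' @export
tpc_window <- function(regime_temps = seq(15, 50, by = 5)) {
  if (!is.numeric(regime_temps) || length(regime_temps) < 2L ||
      any(!is.finite(regime_temps)) || any(diff(regime_temps) <= 0))
    stop("'regime_temps' must be a strictly increasing numeric vector",
         call. = FALSE)
  structure(list(t_min = min(regime_temps), t_max = max(regime_temps),
                 regime_temps = regime_temps), class = "tpc_window")
}

#' Thermal breadth of a performance curve
#'
#' The span of temperatures across which the curve achieves at least
#' \code{threshold} (default 50%, giving the usual B50) of its maximum.
#' Each bound solves \eqn{P(x) = \mathrm{threshold} \cdot h}; unimodality
#' guarantees one root in \code{(lower, optimum)} and one in
#' \code{(optimum, upper)}, found by bisection to 1e-6 degrees C. A bound
#' falling outside the measurement window is truncated to the nearest
#' measured temperature (the window edge), and the truncation is flagged.
#'
#' @inheritParams tpc_evaluate
#' @param threshold fraction of peak performance in (0, 1); 0.5 gives B50.
#' @param window a [tpc_window()].
#' @return list with \code{lower}, \code{upper}, \code{breadth} (degrees C,
#'   \code{upper - lower} after truncation), and logicals
#'   \code{truncated_lower}, \code{truncated_upper}.
#' @export
tpc_breadth <- function(params, threshold = 0.5, window = tpc_window()) {
  validate_tpc_params(params)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single number strictly between 0 and 1",
         call. = FALSE)
  topt <- tpc_optimum(params)
  target <- threshold * params$height
  f <- function(x) tpc_evaluate(params, x) - target
  lo <- bisect_root(f, params$lower, topt, tol = 1e-6)
  hi <- bisect_root(f, topt, params$upper, tol = 1e-6)
  trunc_lo <- lo < window$t_min
  trunc_hi <- hi > window$t_max
  lo <- max(lo, window$t_min)
  hi <- min(hi, window$t_max)
  list(lower = lo, upper = hi, breadth = hi - lo,
       truncated_lower = trunc_lo, truncated_upper = trunc_hi)
}

# scalar bisection; assumes f changes sign on [a, b]
bisect_root <- function(f, a, b, tol = 1e-6) {
  fa <- f(a)
  for (i in seq_len(200L)) {
    if (b - a < tol) break
    m <- (a + b) / 2
    fm <- f(m)
    if (sign(fm) == sign(fa)) {
      a <- m; fa <- fm
    } else {
      b <- m
    }
  }
  (a + b) / 2
}
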