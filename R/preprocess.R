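#' Centre temperatures and scale growth rates before model fitting
#'
#' Temperatures are centred on the grand mean of the regime temperatures
#' (shared across populations, so fitted parameters are comparable), and
#' relative growth rates are divided by the population-specific mean of the
#' positive observations, putting every population's performance on a
#' common unit scale. The returned scaling record is sufficient to map all
#' fitted parameters back to degrees C and raw growth-rate units.
#'
#' @param obs observation table (columns population, pair, family, temp_c,
#'   rgr) as from [read_observations()] or [simulate_tpc_study()].
#' @param window a [tpc_window()] giving the regime temperatures whose mean
#'   is the centring constant.
#' @return list of class \code{"tpc_scaled"}: \code{observations} (with
#'   \code{temp_c} centred and \code{rgr} scaled) and \code{scaling} (class
#'   \code{"tpc_scaling"}: \code{temp_center}, named vector
#'   \code{rgr_scale} per population).
#' @export
tpc_preprocess <- function(obs, window = tpc_window()) {
  check_observations(obs)
  temp_center <- mean(window$regime_temps)
  pops <- unique(obs$population)
  rgr_scale <- vapply(pops, function(p) {
    y <- obs$rgr[obs$population == p]
    mean(y[y > 0])
  }, numeric(1))
  names(rgr_scale) <- pops
  if (any(!is.finite(rgr_scale)) || any(rgr_scale <= 0))
    stop("degenerate input: a population has no positive growth-rate ",
         "observations, so its mean cannot be used as a scale",
         call. = FALSE)
  scaled <- obs
  scaled$temp_c <- obs$temp_c - temp_center
  scaled$rgr <- obs$rgr / rgr_scale[obs$population]
  structure(list(observations = scaled,
                 scaling = structure(list(temp_center = temp_center,
                                          rgr_scale = rgr_scale),
                                     class = "tpc_scaling")),
            class = "tpc_scaled")
}

#' Undo the preprocessing transform
#'
#' @param scaled a \code{"tpc_scaled"} object, or an observation table that
#'   was transformed with the given \code{scaling}.
#' @param scaling a \code{"tpc_scaling"} record (taken from \code{scaled}
#'   when omitted).
#' @return the observation table in original degrees C / raw RGR units.
#' @export
tpc_backtransform <- function(scaled, scaling = NULL) {
  if (inherits(scaled, "tpc_scaled")) {
    scaling <- scaled$scaling
    obs <- scaled$observations
  } else {
    obs <- scaled
    if (is.null(scaling)) stop("'scaling' record required", call. = FALSE)
  }
  obs$temp_c <- obs$temp_c + scaling$temp_center
  obs$rgr <- obs$rgr * scaling$rgr_scale[obs$population]
  obs
}

# map a matrix of natural-unit curve draws (columns lower, upper, ..,
# height, noise_sd, zi_slope treated per caller) from the centred/scaled
# fitting scale back to raw units
unscale_curve_draws <- function(draws, scaling, population) {
  s <- scaling$rgr_scale[[population]]
  draws[, "lower"] <- draws[, "lower"] + scaling$temp_center
  draws[, "upper"] <- draws[, "upper"] + scaling$temp_center
  draws[, "height"] <- draws[, "height"] * s
  draws
}

check_observations <- function(obs) {
  need <- c("population", "pair", "family", "temp_c", "rgr")
  if (!is.data.frame(obs) || !all(need %in% names(obs)))
    stop("observation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(obs) == 0L) stop("observation table is empty", call. = FALSE)
  if (any(!is.finite(obs$rgr)) || any(obs$rgr < 0))
    stop("growth rates must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(obs$temp_c)))
    stop("temperatures must be finite", call. = FALSE)
  invisible(obs)
}
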