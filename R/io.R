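#' Read a long-format observation table
#'
#' Reads and validates a CSV of individual plant records with columns
#' \code{population, pair, family, temp_c, rgr}. Validation rejects
#' missing columns, non-numeric or negative growth rates, temperatures
#' outside a sanity range, and families mapped to more than one
#' population, reporting the offending rows.
#'
#' @param path CSV file path.
#' @param temp_range permissible temperature range (degrees C).
#' @return validated data.frame.
#' @export
read_observations <- function(path, temp_range = c(-10, 60)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "pair", "family", "temp_c", "rgr")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop("invalid observations (", what, ") at rows: ",
           paste(utils::head(rows, 10L), collapse = ", "),
           if (length(rows) > 10L) " ..." else "", call. = FALSE)
    }
  }
  bad_row(!is.finite(obs$rgr) | obs$rgr < 0, "rgr must be >= 0")
  bad_row(!is.finite(obs$temp_c) | obs$temp_c < temp_range[1L] |
            obs$temp_c > temp_range[2L], "temp_c outside sanity range")
  pop_per_fam <- tapply(obs$population, obs$family,
                        function(p) length(unique(p)))
  if (any(pop_per_fam > 1L))
    stop("families mapped to multiple populations: ",
         paste(names(pop_per_fam)[pop_per_fam > 1L], collapse = ", "),
         call. = FALSE)
  obs
}

#' Write an observation table as CSV
#'
#' @param obs observation table.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(obs, path) {
  check_observations(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles and validates everything one reproducible end-to-end run needs:
#' input path (or a simulation design), output directory, sampler
#' configuration, breadth threshold, measurement window and significance
#' level. The configuration is echoed (with a content hash) into the
#' output directory by [run_pipeline()].
#'
#' @param out_dir output directory (created if needed).
#' @param input optional CSV path of observations; if \code{NULL}, data
#'   are simulated from \code{design} and \code{scenario}.
#' @param design a [tpc_design()] used when simulating.
#' @param scenario generator scenario, see [simulate_tpc_study()].
#' @param fit_config a [tpc_fit_config()].
#' @param threshold breadth threshold (fraction of peak performance).
#' @param window a [tpc_window()].
#' @param alpha one-sided significance level for slope tests.
#' @param seed integer master seed for the run.
#' @return validated list of class \code{"tpc_run_config"}.
#' @export
run_config <- function(out_dir, input = NULL, design = tpc_design(),
                       scenario = "divergent-optima",
                       fit_config = tpc_fit_config_reduced(),
                       threshold = 0.5, window = tpc_window(),
                       alpha = 0.1, seed = 1L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            threshold > 0, threshold < 1, alpha > 0, alpha < 1)
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input, call. = FALSE)
  structure(list(out_dir = out_dir, input = input, design = design,
                 scenario = scenario, fit_config = fit_config,
                 threshold = threshold, window = window, alpha = alpha,
                 seed = as.integer(seed)),
            class = "tpc_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (\code{out_dir}, \code{input}, \code{scenario},
#' \code{threshold}, \code{alpha}, \code{seed}) plus nested \code{design}
#' (fields of [tpc_design()]) and \code{fit} (fields of
#' [tpc_fit_config()]) blocks.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(tpc_design, cfg$design %||% list())
  fit_config <- do.call(tpc_fit_config, cfg$fit %||% list())
  run_config(out_dir = cfg$out_dir %||% "results",
             input = cfg$input,
             design = design,
             scenario = cfg$scenario %||% "divergent-optima",
             fit_config = fit_config,
             threshold = cfg$threshold %||% 0.5,
             window = tpc_window(design$regime_temps),
             alpha = cfg$alpha %||% 0.1,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full niche-breadth partitioning pipeline
#'
#' Orchestrates the analysis end to end: load (or simulate) observations,
#' fit the hierarchical curve model to each population, derive the
#' per-population breadth summaries, run the three hypothesis models, and
#' write everything to the output directory: \code{observations.csv},
#' per-population draw summaries and diagnostics
#' (\code{fits/<population>_*.csv/.json}), \code{breadth_summary.csv},
#' \code{partition_tests.csv}, \code{config.json} (with an MD5 content
#' hash) and \code{log.txt} capturing seeds and any sampler warnings. A
#' re-run with the same configuration reproduces the same summaries.
#'
#' @param config a [run_config()].
#' @return list with \code{summaries}, \code{partition}, \code{fits}
#'   (invisibly also written to \code{config$out_dir}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tpc_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "fits"), showWarnings = FALSE)
  log_lines <- c(sprintf("nichebreadth run, seed %d", config$seed),
                 sprintf("R %s", getRversion()))

  if (is.null(config$input)) {
    study <- simulate_tpc_study(design = config$design,
                                scenario = config$scenario,
                                seed = config$seed)
    obs <- study$observations
    log_lines <- c(log_lines,
                   sprintf("simulated scenario '%s'", config$scenario))
  } else {
    obs <- read_observations(config$input)
    log_lines <- c(log_lines, sprintf("read %d rows from %s", nrow(obs),
                                      config$input))
  }
  write_observations(obs, file.path(config$out_dir, "observations.csv"))

  pops <- unique(obs$population)
  fits <- list()
  summaries <- vector("list", length(pops))
  fam_breadths <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    p <- pops[i]
    cfg_i <- config$fit_config
    cfg_i$seed <- cfg_i$seed + i
    fit <- withCallingHandlers(
      tryCatch(fit_tpc(obs[obs$population == p, , drop = FALSE],
                       config = cfg_i, window = config$window),
               error = function(e)
                 stop("stage 'fit' failed for population ", p, ": ",
                      conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("[%s] %s", p,
                                           conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fits[[p]] <- fit
    summaries[[i]] <- summary(fit, threshold = config$threshold)
    dd <- tpc_derived_draws(fit, config$threshold)
    fam_breadths[[i]] <- data.frame(population = p, pair = fit$pair,
                                    family = fit$families,
                                    breadth = colMeans(dd$breadth),
                                    topt = colMeans(dd$topt),
                                    stringsAsFactors = FALSE)
    utils::write.csv(coef(fit),
                     file.path(config$out_dir, "fits",
                               paste0(p, "_coef.csv")))
    jsonlite::write_json(
      list(diagnostics = fit$diagnostics,
           convergence_ok = fit$convergence_ok,
           scaling = list(temp_center = fit$scaling$temp_center,
                          rgr_scale = as.list(fit$scaling$rgr_scale)),
           notes = fit$notes),
      file.path(config$out_dir, "fits", paste0(p, "_diagnostics.json")),
      auto_unbox = TRUE, digits = NA)
  }
  summaries <- do.call(rbind, summaries)
  fam_breadths <- do.call(rbind, fam_breadths)

  partition <- niche_partition(summaries, fam_breadths,
                               alpha = config$alpha)
  utils::write.csv(summaries,
                   file.path(config$out_dir, "breadth_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(partition),
                   file.path(config$out_dir, "partition_tests.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_out <- config
  cfg_out$window <- unclass(cfg_out$window)
  cfg_out$design$window <- NULL
  jsonlite::write_json(lapply(unclass(cfg_out), unclass), cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  hash <- unname(tools::md5sum(cfg_path))
  log_lines <- c(log_lines, sprintf("config hash %s", hash))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(summaries = summaries, partition = partition,
                 fits = fits, config_hash = hash))
}
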