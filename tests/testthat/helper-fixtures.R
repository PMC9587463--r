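# shared fixture builders; everything is generated in code at test time

zsd <- function(ctmin = 0, log_span = 0, log_shape_a = 0, log_shape_b = 0,
                log_height = 0) {
  c(ctmin = ctmin, log_span = log_span, log_shape_a = log_shape_a,
    log_shape_b = log_shape_b, log_height = log_height)
}

# random valid curve parameter sets spanning a wide but realistic range
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lower <- runif(1, -5, 20)
    tpc_params(lower = lower, upper = lower + runif(1, 10, 45),
               shape_a = 1 + exp(runif(1, -1.5, 1.5)),
               shape_b = 1 + exp(runif(1, -1.5, 1.5)),
               height = exp(runif(1, -2, 1)))
  })
}

tiny_design <- function(n_families = 3L, reps = 2L, n_pairs = 1L) {
  tpc_design(n_pairs = n_pairs, families_range = c(n_families, n_families),
             reps_range = c(reps, reps))
}

tiny_fit_config <- function(seed = 1L, iterations = 400L, chains = 2L) {
  tpc_fit_config(iterations = iterations, warmup = iterations %/% 2L,
                 chains = chains, seed = seed)
}

# a small shared fit, built once per test run
cached_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_tpc_population(
        n_families = 6, design = tiny_design(6L, 3L), seed = 42)
      cache <<- list(
        sim = sim,
        fit = suppressWarnings(fit_tpc(
          sim$observations,
          config = tpc_fit_config(iterations = 1200L, warmup = 600L,
                                  chains = 2L, seed = 9L))))
    }
    cache
  }
})

# hand-constructed fit-shaped object with known family draws, for exact
# checks of the derived statistics
fake_fit <- function(lower, upper, population = "popX", pair = "a") {
  # lower, upper: draws x families matrices of breadth-bound positions;
  # curves are symmetric triangles-ish via fixed shapes, so breadth bounds
  # are deterministic transforms. We instead build family_draws whose
  # derived bounds are directly controllable by span.
  stopifnot(all(dim(lower) == dim(upper)))
  nd <- nrow(lower); nf <- ncol(lower)
  fd <- array(NA_real_, c(nd, nf, 5L),
              dimnames = list(NULL, paste0("f", seq_len(nf)),
                              c("lower", "upper", "shape_a", "shape_b",
                                "height")))
  fd[, , "lower"] <- lower
  fd[, , "upper"] <- upper
  fd[, , "shape_a"] <- 2
  fd[, , "shape_b"] <- 2
  fd[, , "height"] <- 1
  structure(list(population = population, pair = pair,
                 families = paste0("f", seq_len(nf)), n_obs = 0L,
                 draws = matrix(0, nd, 1L), family_draws = fd,
                 window = tpc_window(c(-1000, 1000)),
                 config = tpc_fit_config(iterations = 2L, warmup = 1L,
                                         chains = 1L)),
            class = "tpc_fit")
}
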