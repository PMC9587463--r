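# contracts and statistical behaviour of the hierarchical sampler

test_that("the fit honours the draw-count contract and reports diagnostics", {
  sim <- simulate_tpc_population(n_families = 5,
                                 design = tiny_design(5L, 2L), seed = 1)
  cfg <- tpc_fit_config(iterations = 300L, warmup = 150L, chains = 2L,
                        seed = 2L)
  fit <- suppressWarnings(fit_tpc(sim$observations, config = cfg))
  expect_s3_class(fit, "tpc_fit")
  expect_equal(nrow(fit$draws), 2L * (300L - 150L))
  expect_equal(dim(fit$family_draws), c(300L, 5L, 5L))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(is.finite(fit$diagnostics$ess)))
  expect_setequal(
    fit$families, unique(as.character(sim$observations$family)))
  # natural-unit draws respect the parameter constraints
  expect_true(all(fit$family_draws[, , "upper"] >
                    fit$family_draws[, , "lower"]))
  expect_true(all(fit$family_draws[, , "shape_a"] > 1))
  expect_true(all(fit$family_draws[, , "height"] > 0))
  expect_true(all(fit$obs_draws$gamma1 <= 0))
})

test_that("fits are deterministic given seed, config and data", {
  sim <- simulate_tpc_population(n_families = 3,
                                 design = tiny_design(3L, 2L), seed = 4)
  cfg <- tiny_fit_config(seed = 11L)
  f1 <- suppressWarnings(fit_tpc(sim$observations, config = cfg))
  f2 <- suppressWarnings(fit_tpc(sim$observations, config = cfg))
  expect_identical(f1$draws, f2$draws)
  cfg2 <- tiny_fit_config(seed = 12L)
  f3 <- suppressWarnings(fit_tpc(sim$observations, config = cfg2))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("invalid inputs are rejected up front", {
  sim <- simulate_tpc_study(tiny_design(3L, 2L, n_pairs = 1L), "null",
                            seed = 6)
  expect_error(fit_tpc(sim$observations), "single population")
  one <- sim$observations[sim$observations$population == "pop01", ]
  one$temp_c <- 20
  expect_error(fit_tpc(one), "distinct temperatures")
  expect_error(tpc_fit_config(iterations = 100, warmup = 100), "iterations")
})

test_that("posterior means track the truth and relabeling only permutes families", {
  cs <- cached_small_fit()
  fit <- cs$fit
  truth <- cs$sim$truth
  dd <- tpc_derived_draws(fit)
  est <- colMeans(dd$topt)
  expect_identical(fit$families, truth$family)
  expect_gt(stats::cor(est, truth$topt), 0.7)

  # swap two family labels: matched-by-label posteriors agree within
  # Monte-Carlo error and population summaries are unchanged
  obs2 <- cs$sim$observations
  swap <- c(pop1_f01 = "pop1_f02", pop1_f02 = "pop1_f01")
  obs2$family <- ifelse(obs2$family %in% names(swap),
                        swap[obs2$family], obs2$family)
  fit2 <- suppressWarnings(fit_tpc(obs2, config = fit$config))
  dd2 <- tpc_derived_draws(fit2)
  est2 <- colMeans(dd2$topt)[fit$families]
  est2[c("pop1_f01", "pop1_f02")] <- est2[c("pop1_f02", "pop1_f01")]
  expect_equal(unname(est2), unname(est), tolerance = 0.05)
  expect_equal(mean(population_breadth_draws(dd2)),
               mean(population_breadth_draws(dd)), tolerance = 0.02)
})

test_that("a single-family population is fit and matches its own envelope", {
  sim <- simulate_tpc_population(n_families = 1, among_sds = zsd(),
                                 design = tiny_design(1L, 4L), seed = 8)
  fit <- suppressWarnings(fit_tpc(sim$observations,
                                  config = tiny_fit_config(seed = 3L)))
  dd <- tpc_derived_draws(fit)
  expect_equal(population_breadth_draws(dd), dd$breadth[, 1])
})

test_that("no among-family signal concentrates the variance posterior near zero", {
  sim <- simulate_tpc_population(n_families = 6, among_sds = zsd(),
                                 design = tiny_design(6L, 4L), seed = 17)
  fit <- suppressWarnings(fit_tpc(
    sim$observations,
    config = tpc_fit_config(iterations = 1200L, warmup = 600L,
                            chains = 2L, seed = 5L)))
  dd <- tpc_derived_draws(fit)
  v <- apply(dd$topt, 1L, stats::var)
  expect_lt(stats::median(v), 1.5)
})

test_that("model methods are coherent with each other", {
  fit <- cached_small_fit()$fit
  cf <- coef(fit)
  expect_equal(dim(cf), c(6L, 5L))
  pr <- predict(fit, data.frame(family = fit$families[1],
                                temp_c = c(10, 30, 55)))
  expect_true(all(pr$rgr_hat >= 0))
  expect_gt(pr$rgr_hat[pr$temp_c == 30], pr$rgr_hat[pr$temp_c == 10])
  r <- residuals(fit)
  expect_equal(length(r), fit$n_obs)
  expect_true(all(is.finite(r)))
  ysim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(ysim, 2L)
  expect_true(all(ysim[[1]]$rgr >= 0))
  expect_identical(ysim[[1]]$temp_c, fit$observations$temp_c)
})

test_that("the posterior-predictive p-value flags gross misspecification but not self-consistent data", {
  fit <- cached_small_fit()$fit
  p_ok <- bayesian_p(fit, n_rep = 200L)
  expect_gt(p_ok, 0.05)
  expect_lt(p_ok, 0.95)

  # growth high at both thermal extremes with zeros in the middle: no
  # unimodal curve with edge-concentrated zeros can produce this
  bad <- fit$observations
  bad$rgr <- ifelse(bad$temp_c %in% c(25, 30, 35, 40), 0,
                    0.25 + 0.01 * (seq_len(nrow(bad)) %% 5))
  fit_bad <- suppressWarnings(fit_tpc(bad, config = tiny_fit_config(seed = 21L)))
  p_bad <- bayesian_p(fit_bad, n_rep = 200L)
  expect_true(p_bad < 0.05 || p_bad > 0.95)
})
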