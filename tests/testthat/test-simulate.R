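# the synthetic-data generator: reproducibility, truth consistency, and
# the designed scenario contrasts

test_that("zero among-family variation collapses all families to one curve", {
  sim <- simulate_tpc_population(n_families = 5, among_sds = zsd(),
                                 design = tiny_design(5L), seed = 1)
  expect_equal(stats::var(sim$truth$topt), 0)
  expect_equal(stats::var(sim$truth$breadth), 0)
  expect_equal(length(unique(round(sim$truth$lower, 10))), 1L)
})

test_that("zero-inflation can be switched off and increases toward the curve edges", {
  pm_off <- tpc_params(8, 48, 2.2, 2.2, 0.25, noise_sd = 0.05,
                       zi_intercept = -50, zi_slope = 0)
  sim <- simulate_tpc_population(pop_means = pm_off, among_sds = zsd(),
                                 n_families = 4,
                                 design = tiny_design(4L, 5L), seed = 2)
  expect_equal(mean(sim$observations$rgr == 0), 0)

  sim2 <- simulate_tpc_population(n_families = 10,
                                  design = tiny_design(10L, 6L), seed = 3)
  obs <- sim2$observations
  edge <- obs$temp_c %in% c(15, 50)
  expect_gt(mean(obs$rgr[edge] == 0), mean(obs$rgr[!edge] == 0))
  expect_true(all(obs$rgr >= 0))
})

test_that("simulation is bitwise reproducible for a fixed seed and design", {
  a <- simulate_tpc_study(tiny_design(4L, 2L, n_pairs = 2L), "null", seed = 7)
  b <- simulate_tpc_study(tiny_design(4L, 2L, n_pairs = 2L), "null", seed = 7)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c <- simulate_tpc_study(tiny_design(4L, 2L, n_pairs = 2L), "null", seed = 8)
  expect_false(identical(a$observations$rgr, c$observations$rgr))
})

test_that("truth-table quantities are consistent with the curve module", {
  sim <- simulate_tpc_population(n_families = 4,
                                 design = tiny_design(4L), seed = 5)
  for (i in seq_len(4L)) {
    tr <- sim$truth[i, ]
    p <- tpc_params(tr$lower, tr$upper, tr$shape_a, tr$shape_b, tr$height)
    expect_equal(tr$topt, tpc_optimum(p))
    br <- tpc_breadth(p, 0.5, tpc_window(seq(15, 50, 5)))
    expect_equal(tr$breadth, br$breadth)
  }
  pt <- attr(sim$truth, "population_truth")
  expect_equal(pt$pop_breadth,
               max(sim$truth$breadth_upper) - min(sim$truth$breadth_lower))
})

test_that("empirical among-family variance of true optima matches the generating variance", {
  # Monte-Carlo oracle: with location-only deviations the generating
  # among-family variance of T_opt is exactly sd^2
  pm <- tpc_params(10, 52, 2.2, 2.2, 0.25)
  des <- tpc_design(n_pairs = 1, families_range = c(30, 30),
                    reps_range = c(1, 1))
  gen_sd <- 2
  set.seed(202)
  vars <- replicate(200, {
    sim <- nichebreadth:::sim_population_core(
      pm, zsd(ctmin = gen_sd), 30, des, "p", "a")
    stats::var(sim$truth$topt)
  })
  mc_se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - gen_sd^2), 3 * mc_se)
})

test_that("scenario contrasts behave as designed", {
  # null: all populations share generating means and sds
  st0 <- simulate_tpc_study(tiny_design(6L, 2L, n_pairs = 2L), "null",
                            seed = 21)
  expect_equal(length(unique(st0$population_truth$sd_ctmin)), 1L)
  expect_equal(length(unique(st0$population_truth$sd_log_span)), 1L)

  # divergent optima: envelope breadth rises with the generating
  # among-family optimum variation
  st1 <- simulate_tpc_study(scenario = "divergent-optima", seed = 7)
  pt <- st1$population_truth
  expect_equal(length(unique(pt$sd_ctmin)), nrow(pt))
  expect_gt(stats::cor(pt$sd_ctmin, pt$pop_breadth, method = "spearman"),
            0.6)

  # variable breadth: among-family breadth variance tracks the span sd
  st2 <- simulate_tpc_study(scenario = "variable-breadth", seed = 7)
  pt2 <- st2$population_truth
  expect_gt(stats::cor(pt2$sd_log_span, pt2$var_breadth,
                       method = "spearman"), 0.6)

  expect_error(simulate_tpc_study(scenario = "no-such"), "arg")
})

test_that("the default design reaches the published study size", {
  st <- simulate_tpc_study(seed = 1)
  expect_equal(nrow(st$population_truth), 10L)
  expect_gte(nrow(st$observations), 5000L)
  nf <- st$population_truth$n_families
  expect_true(all(nf >= 11 & nf <= 50))
})

test_that("negative among-family sds are rejected", {
  expect_error(simulate_tpc_population(among_sds = zsd(ctmin = -1),
                                       n_families = 3,
                                       design = tiny_design()),
               "non-negative")
})
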