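# the pair-random-intercept mixed models and the three hypothesis tests

table1 <- mimulus_breadths()

test_that("a noiseless linear relationship with pair offsets is recovered", {
  set.seed(4)
  pair <- rep(letters[1:5], each = 2)
  x <- rnorm(10, 10, 3)
  offs <- rep(rnorm(5, 0, 4), each = 2)
  y <- 2 + 1.5 * x + offs + rnorm(10, 0, 1e-6)
  r <- suppressWarnings(fit_pair_lmm(y, x, pair))
  expect_equal(r$slope, 1.5, tolerance = 1e-4)
  expect_gt(r$conditional_r2, 0.999)
  expect_gte(r$conditional_r2, r$marginal_r2)
})

test_that("without pair structure the slope collapses to ordinary least squares", {
  set.seed(9)
  pair <- rep(letters[1:5], each = 4)
  x <- rnorm(20)
  y <- 0.7 * x + rnorm(20)          # no pair effects: tau2 ~ 0, singular ok
  r <- fit_pair_lmm(y, x, pair)
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])
  expect_equal(r$slope, ols, tolerance = 1e-8)
  s <- standardize_and_fit(y, x, pair)
  expect_equal(s$slope, stats::cor(x, y), tolerance = 1e-8)
})

test_that("standardising is idempotent for already-scaled inputs", {
  set.seed(2)
  pair <- rep(letters[1:4], each = 3)
  x <- as.vector(scale(rnorm(12)))
  y <- as.vector(scale(0.4 * x + rnorm(12)))
  a <- fit_pair_lmm(y, x, pair)
  b <- standardize_and_fit(y, x, pair)
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("affine rescaling of the predictor rescales the raw slope only", {
  r1 <- fit_pair_lmm(table1$pop_breadth, table1$var_topt, table1$pair)
  r2 <- fit_pair_lmm(table1$pop_breadth, 10 * table1$var_topt, table1$pair)
  expect_equal(r2$slope, r1$slope / 10, tolerance = 1e-6)
  s1 <- standardize_and_fit(table1$pop_breadth, table1$var_topt, table1$pair)
  s2 <- standardize_and_fit(table1$pop_breadth, 10 * table1$var_topt,
                            table1$pair)
  expect_equal(s1$slope, s2$slope, tolerance = 1e-9)
  expect_equal(sign(r1$slope), sign(s1$slope))
})

test_that("results are invariant to relabeling the pairs", {
  relab <- c(a = "q", b = "w", c = "e", d = "r", e = "t")
  r1 <- fit_pair_lmm(table1$pop_breadth, table1$var_topt, table1$pair)
  r2 <- fit_pair_lmm(table1$pop_breadth, table1$var_topt,
                     relab[table1$pair])
  expect_equal(r1$slope, r2$slope, tolerance = 1e-9)
  expect_equal(r1$marginal_r2, r2$marginal_r2, tolerance = 1e-9)
  expect_equal(r1$conditional_r2, r2$conditional_r2, tolerance = 1e-9)
})

test_that("the published mixed-model statistics are reproduced from the packaged estimates", {
  np <- suppressWarnings(niche_partition(table1))
  h2 <- np[np$model == "H2_divergent_optima", ]
  expect_equal(h2$slope, 0.508, tolerance = 0.01)
  expect_equal(h2$slope_se, 0.213, tolerance = 0.01)
  expect_equal(h2$p_value, 0.070, tolerance = 0.01)
  expect_equal(h2$std_slope, 0.291, tolerance = 0.01)
  h3 <- np[np$model == "H3_breadth_variation", ]
  expect_equal(h3$slope, 0.275, tolerance = 0.01)
  expect_equal(h3$p_value, 0.597, tolerance = 0.01)
  expect_false(h3$significant)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_pair_lmm(1:4, rep(1, 4), c("a", "a", "b", "b")),
               "constant")
  expect_error(fit_pair_lmm(1:4, 1:4, rep("a", 4)), "2 species pairs")
  expect_error(standardize_and_fit(rep(1, 4), 1:4, c("a", "a", "b", "b")),
               "zero-variance")
  expect_warning(niche_partition(table1), "H1_generalist skipped")
})

test_that("the family-level model runs when per-family breadths are supplied", {
  st <- simulate_tpc_study(tiny_design(6L, 2L, n_pairs = 3L),
                           "generalist", seed = 13)
  np <- niche_partition(st$population_truth, family_breadths = st$truth)
  expect_equal(np$model,
               c("H1_generalist", "H2_divergent_optima",
                 "H3_breadth_variation"))
  h1 <- np[np$model == "H1_generalist", ]
  expect_equal(h1$n_obs, nrow(st$truth))
  expect_equal(h1$n_groups, 3L)
  expect_true(all(np$conditional_r2 >= np$marginal_r2 - 1e-12))
})

test_that("a strong divergent-optima signal is declared significant at the one-sided rule", {
  st <- simulate_tpc_study(scenario = "divergent-optima", seed = 3)
  np <- niche_partition(st$population_truth, family_breadths = st$truth)
  h2 <- np[np$model == "H2_divergent_optima", ]
  expect_gt(h2$slope, 0)
  expect_true(h2$significant)
})
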