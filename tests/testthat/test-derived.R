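# derived statistics: envelopes, among-family variances, summaries,
# breadth ratios, and the packaged published estimates

test_that("envelope arithmetic: highest upper bound minus smallest lower bound", {
  dd <- list(lower = rbind(c(20, 25)), upper = rbind(c(30, 35)))
  expect_equal(population_breadth_draws(dd), 15)
  # single family: envelope equals the family breadth
  dd1 <- list(lower = rbind(22, 21), upper = rbind(31, 33))
  expect_equal(population_breadth_draws(dd1), c(9, 12))
})

test_that("the envelope dominates every family breadth, per draw", {
  fit <- cached_small_fit()$fit
  dd <- tpc_derived_draws(fit)
  env <- population_breadth_draws(dd)
  # brute force per draw
  expect_true(all(env + 1e-12 >= apply(dd$breadth, 1L, max)))
  expect_true(all(env <= 35 + 1e-12))
  # adding a family never shrinks the envelope
  sub <- list(lower = dd$lower[, -1, drop = FALSE],
              upper = dd$upper[, -1, drop = FALSE])
  expect_true(all(population_breadth_draws(sub) <= env + 1e-12))
})

test_that("among-family variances match spreadsheet arithmetic on a hand-built fixture", {
  lower <- rbind(c(18, 22), c(17, 23), c(19, 21))
  upper <- rbind(c(38, 40), c(37, 43), c(36, 41))
  fit <- fake_fit(lower, upper)
  dd <- tpc_derived_draws(fit)
  # symmetric shapes (a = b = 2): optimum at lower + span/sqrt(3)
  topt_manual <- lower + (upper - lower) / sqrt(3)
  expect_equal(dd$topt, topt_manual, ignore_attr = TRUE)
  s <- suppressWarnings(summary(fit, n_rep = 0))
  v_manual <- apply(topt_manual, 1, function(r) sum((r - mean(r))^2) / 1)
  expect_equal(s$var_topt, mean(v_manual))
  expect_equal(s$var_topt_lo, unname(quantile(v_manual, 0.025)))
  expect_equal(s$pop_breadth,
               mean(apply(dd$upper, 1, max) - apply(dd$lower, 1, min)))
})

test_that("identical families give exactly zero variance with a degenerate interval", {
  lower <- matrix(20, 4, 3)
  upper <- matrix(40, 4, 3)
  s <- summary(fake_fit(lower, upper), n_rep = 0)
  expect_equal(unname(c(s$var_topt, s$var_topt_lo, s$var_topt_hi)), c(0, 0, 0))
  expect_equal(unname(c(s$var_breadth, s$var_breadth_lo, s$var_breadth_hi)),
               c(0, 0, 0))
})

test_that("a single family yields missing variances with a warning and envelope = family breadth", {
  f1 <- fake_fit(matrix(c(20, 21), 2, 1), matrix(c(40, 42), 2, 1))
  expect_warning(s <- summary(f1, n_rep = 0), "single family")
  expect_true(is.na(s$var_topt))
  dd <- tpc_derived_draws(f1)
  expect_equal(population_breadth_draws(dd), dd$breadth[, 1])
})

test_that("summaries are linear and invariant to family relabeling", {
  fit <- cached_small_fit()$fit
  dd <- tpc_derived_draws(fit)
  expect_equal(mean(rowMeans(dd$breadth)), mean(colMeans(dd$breadth)),
               tolerance = 1e-12)
  perm <- c(3, 1, 2, 6, 5, 4)
  fit_p <- fit
  fit_p$family_draws <- fit$family_draws[, perm, ]
  fit_p$families <- fit$families[perm]
  s1 <- summary(fit, n_rep = 0)
  s2 <- summary(fit_p, n_rep = 0)
  expect_equal(s1$var_topt, s2$var_topt)
  expect_equal(s1$pop_breadth, s2$pop_breadth)
  expect_equal(s1$family_breadth, s2$family_breadth)
})

test_that("the packaged published estimates load, round-trip, and have coherent intervals", {
  tab <- mimulus_breadths()
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$pop_breadth[tab$population == "M. cardinalis"], 34.74)
  expect_equal(tab$family_breadth[tab$population == "M. cardinalis"], 29.97)
  expect_equal(sort(unique(tab$pair)), letters[1:5])
  expect_true(all(tab$pop_breadth_lo <= tab$pop_breadth &
                    tab$pop_breadth <= tab$pop_breadth_hi))
  expect_true(all(tab$pop_breadth <= 35))
  expect_true(all(tab$family_breadth <= tab$pop_breadth))
  expect_equal(sum(tab$n_individuals), 5451L)

  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), tmp, row.names = FALSE, quote = FALSE)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(tab), ignore_attr = TRUE)
})

test_that("breadth ratios: unity for a one-curve population, published extremes elsewhere", {
  lower <- matrix(20, 3, 2); upper <- matrix(40, 3, 2)
  s <- summary(fake_fit(lower, upper), n_rep = 0)
  expect_equal(unname(breadth_ratio(s)), 1)

  ratios <- breadth_ratio(mimulus_breadths())
  expect_equal(unname(ratios["M. cardinalis"]), 0.863, tolerance = 1e-3)
  expect_equal(names(which.max(ratios)), "M. cardinalis")
  expect_equal(names(which.min(ratios)), "M. bicolor")
  expect_equal(unname(min(ratios)), 0.60, tolerance = 0.005)
})

test_that("standard deviations derive from variances element-wise", {
  expect_equal(sd_from_variance(0), 0)
  expect_equal(round(sd_from_variance(3.96), 2), 1.99)
  expect_equal(round(sd_from_variance(12.14), 2), 3.48)
  expect_error(sd_from_variance(-1), "non-negative")
  tab <- mimulus_breadths()
  expect_equal(sd_from_variance(tab), sqrt(tab$var_topt))
})
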