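test_that("deviance test matches the chi-squared reference", {
  r <- lrt_deviance(-10, -10)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  # chi-squared(1) 95th percentile
  r2 <- lrt_deviance(-10 - qchisq(0.95, 1) / 2, -10)
  expect_equal(r2$D, qchisq(0.95, 1))
  expect_equal(r2$p, 0.05, tolerance = 1e-10)
  # null fitting better than alternative cannot reject
  r3 <- lrt_deviance(-5, -9)
  expect_lt(r3$D, 0)
  expect_equal(r3$p, 1)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  for (i in 1:10) {
    p <- runif(15)
    adj <- adjust_pvalues(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # the largest p-value is never changed
    expect_equal(adj[which.max(p)], max(p))
    # monotone in the order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the exact test is reproducible and seed-driven", {
  set.seed(10)
  ab <- simulate_community(theta = 8, J = 120, m = 0.9)
  fit <- fit_etienne(ab)
  v1 <- exact_neutrality_test(ab, fit, n_sims = 50, seed = 77)
  v2 <- exact_neutrality_test(ab, fit, n_sims = 50, seed = 77)
  v3 <- exact_neutrality_test(ab, fit, n_sims = 50, seed = 78)
  expect_identical(v1$logL_sims, v2$logL_sims)
  expect_identical(v1$p_value, v2$p_value)
  expect_false(identical(v1$logL_sims, v3$logL_sims))
  expect_true(v1$p_value >= 0 && v1$p_value <= 1)
})

test_that("a sample typical of its own fit passes the exact test", {
  # type-I behavior at desk scale: neutral draws should rarely be rejected
  set.seed(12)
  n_rej <- 0L
  for (i in 1:15) {
    ab <- simulate_community(theta = 10, J = 100, m = 0.9)
    fit <- fit_etienne(ab)
    v <- exact_neutrality_test(ab, fit, n_sims = 50, seed = 400 + i)
    n_rej <- n_rej + (v$p_value <= 0.05)
  }
  expect_lte(n_rej, 3L)
})

test_that("even niche communities are rejected", {
  # niche differentiation produces SADs more even than any neutral
  # expectation; these must fail the test most of the time
  set.seed(13)
  ps <- vapply(1:8, function(i) {
    ab <- niche_community(1500, "geometric", S_pool = 40, ratio = 0.9)
    fit <- fit_etienne(ab)
    exact_neutrality_test(ab, fit, n_sims = 50, seed = 500 + i)$p_value
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.5)
})

test_that("the formula comparison treats Ewens as the null", {
  set.seed(14)
  # near m = 1 the formulas coincide: no significant difference expected
  ab <- simulate_community(theta = 15, J = 400, I = Inf)
  ew <- fit_ewens(ab)
  et <- fit_etienne(ab)
  cmp <- compare_formulae(ew, et)
  expect_gte(cmp$p, 0.05)
  expect_gte(cmp$logL_etienne, cmp$logL_ewens - 1e-6)

  # identical logL gives D = 0, p = 1
  same <- lrt_deviance(et$logL, et$logL)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  # strong dispersal limitation: Etienne strictly better
  ab2 <- simulate_community(theta = 20, J = 1000, m = 0.1)
  ew2 <- fit_ewens(ab2)
  et2 <- fit_etienne(ab2)
  expect_gt(et2$logL, ew2$logL)
})

test_that("verdict tables adjust within the run and call passes on adjusted p", {
  fx <- make_fixture(fixture_spec(n_per_treatment = c(Healthy = 3, BoP = 3),
                                  J_range = c(80, 150),
                                  neutral_fraction = 1), seed = 6)
  cfg <- as_configurations(fx$otu, fx$treatments)
  v <- test_neutrality(cfg, n_sims = 30, seed = 2)
  expect_equal(nrow(v), 6L)
  expect_true(all(v$p_adjusted >= v$p_value))
  expect_identical(v$passes, v$p_adjusted > 0.05)
  expect_identical(v$p_adjusted, adjust_pvalues(v$p_value))
  # reproducible
  v2 <- test_neutrality(cfg, n_sims = 30, seed = 2)
  expect_identical(v$p_value, v2$p_value)
})

test_that("single-simulation edge case yields D = 0, p = 1 when logLs tie", {
  ab <- c(1)  # J = 1: every community has logL 0
  fit <- structure(list(theta = 2, m = 0.5, I = 1, logL = 0, J = 1L, S = 1L,
                        converged = TRUE, n_restarts_used = 1L,
                        weakly_identified = TRUE), class = "etienne_fit")
  v <- exact_neutrality_test(ab, fit, n_sims = 1, seed = 1)
  expect_equal(v$deviance_D, 0)
  expect_equal(v$p_value, 1)
})
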