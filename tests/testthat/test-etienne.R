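test_that("log Stirling rows match the exact triangle and boundary identities", {
  expect_equal(log_stirling_row(1), 0)
  expect_equal(exp(log_stirling_row(3)), c(2, 3, 1))
  for (n in c(2, 5, 8, 12)) {
    expect_equal(exp(log_stirling_row(n)), stirling1_exact(n), tolerance = 1e-12)
  }
  row20 <- log_stirling_row(20)
  expect_equal(row20[1], lgamma(20))  # s(n, 1) = (n-1)!
  expect_equal(row20[20], 0)          # s(n, n) = 1
})

test_that("K(D, A) matches hand and brute-force enumeration oracles", {
  expect_equal(exp(as.numeric(etienne_K(c(2)))), c(1, 1))
  # singleton species force a_i = 1
  K11 <- etienne_K(c(1, 1))
  expect_equal(as.numeric(K11), 0)
  expect_equal(names(K11), "2")
  for (ab in list(c(3, 2), c(4, 2, 1), c(5, 5), c(3, 3, 2, 1))) {
    expect_equal(exp(as.numeric(etienne_K(ab))), K_bruteforce(ab),
                 tolerance = 1e-10)
  }
})

test_that("K is a pure function of the abundance multiset", {
  ab <- c(6, 3, 2, 1, 1)
  K1 <- etienne_K(ab)
  K2 <- etienne_K(sample(ab))
  expect_identical(as.numeric(K1), as.numeric(K2))
})

test_that("Etienne likelihood reproduces the genealogy closed form at J = 2", {
  # D = (2): second individual either copies the first (prob 1/(I+1)) or
  # immigrates and draws the same metacommunity species (I/(I+1) * 1/(theta+1))
  for (theta in c(0.5, 1, 4)) {
    for (m in c(0.2, 0.5, 0.8)) {
      I <- m_to_I(m, 2)
      closed <- 1 / (I + 1) + I / ((I + 1) * (theta + 1))
      expect_equal(exp(etienne_loglik(c(2), theta, m)), closed,
                   tolerance = 1e-10)
    }
  }
  # and the J = 1 sample has probability 1 regardless of parameters
  expect_equal(etienne_loglik(c(1), 3, 0.4), 0)
})

test_that("Etienne likelihood is a probability distribution over partitions", {
  for (J in 2:6) {
    parts <- integer_partitions(J)
    for (theta in c(1, 2)) {
      for (m in c(0.3, 0.7)) {
        total <- sum(vapply(parts, function(p) exp(etienne_loglik(p, theta, m)),
                            numeric(1)))
        expect_equal(total, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("Etienne converges to Ewens as m -> 1 on a panel of configurations", {
  for (ab in panel_configs()) {
    for (theta in c(0.8, 2, 10)) {
      expect_equal(etienne_loglik(ab, theta, 1 - 1e-9),
                   ewens_loglik(ab, theta), tolerance = 1e-4)
    }
  }
})

test_that("likelihood is exchangeable in the abundance vector", {
  ab <- c(9, 4, 4, 2, 1)
  set.seed(3)
  K <- etienne_K(ab)
  for (i in 1:5) {
    expect_equal(etienne_loglik(sample(ab), 3, 0.6),
                 etienne_loglik(ab, 3, 0.6, K = K))
  }
})

test_that("m/I conversions invert each other and hit known points", {
  expect_equal(m_to_I(0.5, 2), 1)
  expect_equal(I_to_m(1, 2), 0.5)
  expect_equal(m_to_I(1, 50), Inf)
  set.seed(8)
  m <- runif(20)
  expect_equal(I_to_m(m_to_I(m, 37), 37), m, tolerance = 1e-12)
})

test_that("the joint MLE agrees with a grid search on a tiny sample", {
  ab <- c(4, 2, 1)
  fit <- fit_etienne(ab)
  K <- etienne_K(ab)
  thetas <- exp(seq(log(0.05), log(50), length.out = 60))
  ms <- seq(0.02, 0.98, length.out = 60)
  grid <- expand.grid(theta = thetas, m = ms)
  ll <- mapply(function(t, m) etienne_loglik(ab, t, m, K = K),
               grid$theta, grid$m)
  expect_gte(fit$logL, max(ll) - 1e-6)
  best <- grid[which.max(ll), ]
  expect_equal(log(fit$theta), log(best$theta), tolerance = 0.15)
})

test_that("Etienne logL at the optimum dominates the Ewens solution", {
  for (ab in panel_configs()[c(1, 3, 5, 6)]) {
    ew <- fit_ewens(ab)
    et <- fit_etienne(ab)
    if (!is.finite(ew$theta)) next
    at_ewens <- etienne_loglik(ab, ew$theta, 1 - 1e-9)
    expect_gte(et$logL, at_ewens - 1e-6)
  }
})

test_that("degenerate and failed fits are reported, not hidden", {
  f1 <- fit_etienne(c(1))
  expect_false(f1$converged)
  expect_equal(f1$logL, 0)
  f2 <- fit_etienne(c(5))  # S = 1: m weakly identified, still attempted
  expect_true(f2$weakly_identified)
  expect_true(is.finite(f2$logL))
  g <- glance(f2)
  expect_equal(g$formula, "etienne")
  expect_equal(tidy(f2)$term, c("theta", "m", "I"))
})
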