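test_that("Fisher 2x2 reproduces the passing-rate comparisons", {
  # pass/fail tables for 3/17, 5/22 and 6/22 passing samples
  expect_equal(fisher_exact_2x2(3, 14, 5, 17), 1)
  expect_equal(fisher_exact_2x2(3, 14, 6, 16), 0.704, tolerance = 5e-4)
  expect_equal(fisher_exact_2x2(5, 17, 6, 16), 1)
  # identical rows are never evidence of a difference
  expect_equal(fisher_exact_2x2(4, 9, 4, 9), 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  # matrix input
  expect_equal(fisher_exact_2x2(matrix(c(3, 5, 14, 17), 2)), 1)
})

test_that("Fisher 2x2 agrees with the independent stats implementation", {
  set.seed(15)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    ours <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }
  # and with exhaustive enumeration over the hypergeometric support
  tab <- c(3, 14, 6, 16)
  m <- tab[1] + tab[2]; n <- tab[3] + tab[4]; k <- tab[1] + tab[3]
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  manual <- sum(probs[probs <= dhyper(tab[1], m, n, k) * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]), manual)
})

test_that("passing-rate summaries count and test correctly", {
  verdicts <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:61),
    treatment = factor(rep(c("Healthy", "BoP", "NonBoP"), times = c(17, 22, 22))),
    theta = rep(10, 61),
    passes = c(rep(TRUE, 3), rep(FALSE, 14),   # 3/17
               rep(TRUE, 5), rep(FALSE, 17),   # 5/22
               rep(TRUE, 6), rep(FALSE, 16)))  # 6/22
  ps <- passing_rate_table(verdicts)
  expect_equal(ps$treatments$n_pass, c(3, 5, 6))
  expect_equal(round(100 * ps$treatments$pass_rate, 2), c(17.65, 22.73, 27.27))
  expect_equal(ps$overall$n_pass, 14)
  expect_equal(ps$overall$rate, 14 / 61, tolerance = 1e-12)
  p <- setNames(ps$pairwise$p,
                paste(ps$pairwise$treatment_1, ps$pairwise$treatment_2))
  expect_equal(unname(p["Healthy BoP"]), 1)
  expect_equal(unname(p["Healthy NonBoP"]), 0.704, tolerance = 5e-4)
  expect_equal(unname(p["BoP NonBoP"]), 1)
  expect_equal(sum(ps$treatments$n_pass), ps$overall$n_pass)
})

test_that("all-pass and degenerate summaries behave", {
  verdicts <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                             treatment = factor(rep(c("Healthy", "BoP"), 2)),
                             theta = c(5, 6, 7, 8),
                             passes = TRUE)
  ps <- passing_rate_table(verdicts)
  expect_equal(ps$treatments$pass_rate, c(1, 1))
  expect_equal(ps$pairwise$p, 1)
})

test_that("theta ANOVA separates groups shaped like the study pattern", {
  set.seed(16)
  # group sizes and theta spreads shaped like the synthetic study defaults:
  # healthy well below the two periodontitis groups, which coincide
  d <- tibble::tibble(
    treatment = rep(c("Healthy", "BoP", "NonBoP"), times = c(17, 22, 22)),
    theta = c(rnorm(17, 15, 5), rnorm(22, 27, 6), rnorm(22, 27, 6)))
  res <- theta_group_comparison(d)
  expect_lt(res$anova_p, 0.01)
  pw <- res$pairwise
  key <- paste(pw$treatment_1, pw$treatment_2)
  expect_lt(pw$p_bonferroni[key == "Healthy BoP"], 0.01)
  expect_lt(pw$p_bonferroni[key == "Healthy NonBoP"], 0.01)
  expect_gt(pw$p_bonferroni[key == "BoP NonBoP"], 0.05)
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
  expect_true(all(pw$p_bonferroni <= 1))
  g <- glance(res)
  expect_equal(g$n, 61)
})

test_that("degenerate theta comparisons are handled explicitly", {
  d <- tibble::tibble(treatment = rep(c("A", "B"), each = 3), theta = 7)
  res <- theta_group_comparison(d)
  expect_equal(res$anova_F, 0)
  expect_equal(res$anova_p, 1)
  expect_equal(res$pairwise$p_bonferroni, 1)
  # two groups only: Bonferroni factor 1
  d2 <- tibble::tibble(treatment = rep(c("A", "B"), each = 4),
                       theta = c(rnorm(4, 5), rnorm(4, 9)))
  res2 <- theta_group_comparison(d2)
  expect_equal(res2$n_pairs, 1)
  expect_equal(res2$pairwise$p_bonferroni, res2$pairwise$p_raw)
  # non-finite theta excluded with a warning
  d3 <- tibble::tibble(treatment = rep(c("A", "B"), each = 3),
                       theta = c(1, 2, Inf, 4, 5, 6))
  expect_warning(res3 <- theta_group_comparison(d3), "non-finite")
  expect_equal(res3$n, 5)
})
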