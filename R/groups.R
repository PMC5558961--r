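#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability ("R convention") two-sided rule: with both margins
#' fixed, the p-value is the sum of hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7). This reproduces p = 1 exactly when
#' the observed cell is the hypergeometric mode, as in the passing-rate
#' comparisons between treatments.
#'
#' @param a,b,c,d Cell counts: rows are the two treatments, columns
#'   pass/fail, so the table is `rbind(c(a, b), c(c, d))`. A 2x2 matrix may
#'   be given as `a`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 14, 5, 17)  # 1
#' fisher_exact_2x2(3, 14, 6, 16)  # 0.704
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stop("all-zero table")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Treatment-level neutrality passing rates
#'
#' Summarizes exact-test verdicts by treatment (counts, rates, mean and sd
#' of the fitted theta) and runs all pairwise Fisher exact tests on the
#' pass/fail fourfold tables. Samples with treatment `Other` are excluded
#' from the group statistics; empty treatments are dropped with a warning.
#'
#' @param verdicts Verdict tibble from [test_neutrality()] (needs
#'   `treatment`, `passes`, `theta`).
#' @return Object of class `passing_summary`: list with `treatments`
#'   (tibble: `treatment`, `n_samples`, `n_pass`, `pass_rate`, `mean_theta`,
#'   `sd_theta`), `pairwise` (tibble: `treatment_1`, `treatment_2`,
#'   fourfold cells, `p`), and `overall` (list: `n`, `n_pass`, `rate`).
#' @export
passing_rate_table <- function(verdicts) {
  v <- verdicts[verdicts$treatment != "Other", , drop = FALSE]
  v$treatment <- order_treatments(v$treatment)
  if (nrow(v) < nrow(verdicts))
    message(nrow(verdicts) - nrow(v), " sample(s) with treatment 'Other' excluded")
  summ <- v |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_pass = sum(.data$passes),
                     pass_rate = .data$n_pass / .data$n_samples,
                     mean_theta = mean(.data$theta[is.finite(.data$theta)]),
                     sd_theta = stats::sd(.data$theta[is.finite(.data$theta)]),
                     .groups = "drop")
  empty <- summ$n_samples == 0
  if (any(empty)) {
    warning("dropping empty treatment(s): ",
            paste(summ$treatment[empty], collapse = ", "))
    summ <- summ[!empty, ]
  }
  pairs <- utils::combn(as.character(summ$treatment), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    s1 <- summ[summ$treatment == pr[1], ]
    s2 <- summ[summ$treatment == pr[2], ]
    a <- s1$n_pass; b <- s1$n_samples - s1$n_pass
    cc <- s2$n_pass; dd <- s2$n_samples - s2$n_pass
    tibble::tibble(treatment_1 = pr[1], treatment_2 = pr[2],
                   pass_1 = a, fail_1 = b, pass_2 = cc, fail_2 = dd,
                   p = fisher_exact_2x2(a, b, cc, dd))
  })
  structure(list(treatments = summ, pairwise = pairwise,
                 overall = list(n = nrow(v), n_pass = sum(v$passes),
                                rate = sum(v$passes) / nrow(v))),
            class = "passing_summary")
}

#' @export
print.passing_summary <- function(x, ...) {
  cat("Neutrality passing rates by treatment\n")
  print(x$treatments)
  cat(sprintf("Overall: %d / %d (%.2f%%)\n", x$overall$n_pass, x$overall$n,
              100 * x$overall$rate))
  cat("Pairwise Fisher exact tests\n")
  print(x$pairwise)
  invisible(x)
}

#' Compare fitted theta across treatments
#'
#' One-way fixed-effects ANOVA on the fitted biodiversity numbers, followed
#' by pairwise two-sample t-tests (pooled variance) with Bonferroni
#' correction (raw p multiplied by the number of pairs, capped at 1).
#' Samples with non-finite theta (degenerate fits) and treatment `Other`
#' are excluded with a warning; treatments with fewer than two samples are
#' skipped in the pairwise stage.
#'
#' @param fits A tibble with columns `treatment` and `theta` — typically
#'   [fit_sad()] output filtered to one formula, or a [test_neutrality()]
#'   verdict table.
#' @return Object of class `theta_anova`: list with `anova_F`, `anova_p`,
#'   `groups` (means/sd tibble), `pairwise` (tibble: pair, difference, t,
#'   `p_raw`, `p_bonferroni`), `n_pairs`.
#' @export
theta_group_comparison <- function(fits) {
  stopifnot(all(c("treatment", "theta") %in% names(fits)))
  d <- fits[fits$treatment != "Other", c("treatment", "theta")]
  bad <- !is.finite(d$theta)
  if (any(bad)) {
    warning("excluding ", sum(bad), " sample(s) with non-finite theta")
    d <- d[!bad, ]
  }
  d$treatment <- order_treatments(d$treatment)
  if (nlevels(d$treatment) < 2) stop("need at least two treatments")
  groups <- d |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(n = dplyr::n(), mean_theta = mean(.data$theta),
                     sd_theta = stats::sd(.data$theta), .groups = "drop")
  fit <- aov(theta ~ treatment, data = d)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]; pv <- an[["Pr(>F)"]][1]
  if (all(tapply(d$theta, d$treatment, var) == 0) &&
      length(unique(d$theta)) == 1L) { Fv <- 0; pv <- 1 }

  pairs <- utils::combn(levels(d$treatment), 2, simplify = FALSE)
  usable <- groups$treatment[groups$n >= 2]
  n_pairs <- sum(vapply(pairs, function(pr) all(pr %in% usable), logical(1)))
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    if (!all(pr %in% usable)) {
      warning("skipping pair ", pr[1], " vs ", pr[2], ": group with < 2 samples")
      return(NULL)
    }
    x <- d$theta[d$treatment == pr[1]]
    y <- d$theta[d$treatment == pr[2]]
    if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
    }
    tibble::tibble(treatment_1 = pr[1], treatment_2 = pr[2],
                   diff = mean(x) - mean(y),
                   t = unname(tt$statistic), p_raw = tt$p.value,
                   p_bonferroni = min(1, tt$p.value * max(n_pairs, 1)))
  })
  structure(list(anova_F = Fv, anova_p = pv, groups = groups,
                 pairwise = pairwise, n_pairs = n_pairs, n = nrow(d)),
            class = "theta_anova")
}

#' @export
print.theta_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on theta: F = %.3f, p = %.4g (n = %d)\n",
              x$anova_F, x$anova_p, x$n))
  print(x$groups)
  cat("Bonferroni pairwise comparisons\n")
  print(x$pairwise)
  invisible(x)
}
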