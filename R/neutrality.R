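#' Log-likelihood ratio deviance against the chi-squared reference
#'
#' `D = -2 (logL0 - logL1)` with the p-value taken from the upper tail of
#' the chi-squared distribution with one degree of freedom at `max(D, 0)`.
#' Negative deviance (null fits better) is clamped to zero, giving p = 1:
#' the test is one-sided against the alternative.
#'
#' @param logL0 Log-likelihood of the null model.
#' @param logL1 Log-likelihood of the alternative model.
#' @return List with elements `D` and `p`.
#' @examples
#' lrt_deviance(-10, -10)       # D = 0, p = 1
#' lrt_deviance(-11.9207, -10)  # D = 3.8415, p ~ 0.05
#' @export
lrt_deviance <- function(logL0, logL1) {
  stopifnot(is.finite(logL0), is.finite(logL1))
  D <- -2 * (logL0 - logL1)
  Dc <- max(D, 0)
  list(D = D, p = pchisq(Dc, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, the adjusted value at rank i is
#' `min over j >= i of min(1, p_(j) * n / j)`, mapped back to input order.
#' Thin wrapper over [stats::p.adjust()] with a domain check.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method Only `"BH"` is offered.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
adjust_pvalues <- function(p, method = c("BH")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Exact neutrality test for one sample
#'
#' The parametric-bootstrap / Monte-Carlo exact test of neutral community
#' assembly. With `(theta, m)` fitted to the observed sample:
#' (i) `n_sims` artificial communities are simulated at the fitted
#' `(theta, I, J)`; (ii) the sampling-formula log-likelihood of each
#' artificial community is evaluated at the same fitted parameters, with
#' its own `K` coefficients; (iii) the observed log-likelihood `logL_obs`
#' is compared with the mean of the simulated log-likelihoods by
#' [lrt_deviance()] (chi-squared, df = 1); (iv) the sample passes when the
#' p-value exceeds `alpha`. The comparison averages *log*-likelihoods: raw
#' likelihoods underflow at `J ~ 1e3`.
#'
#' By default the simulated communities are scored at the observed fit's
#' parameters; `refit_sims = TRUE` re-estimates the parameters on every
#' simulated community before scoring it (slower, sensitivity mode).
#'
#' A rank-based diagnostic is reported alongside: `p_rank` is the fraction
#' of simulated communities with log-likelihood at or below the observed
#' one (small when the observed SAD is atypically improbable). It is a
#' diagnostic column only, not the decision rule.
#'
#' @param abund Positive integer abundance vector (the observed SAD).
#' @param fit An [fit_etienne()] or [fit_ewens()] object for `abund`; the
#'   formula used for simulation and scoring follows the fit's class.
#' @param n_sims Number of artificial communities (paper-scale default 100).
#' @param seed Integer seed for the simulation streams.
#' @param alpha Significance level for the pass/fail call.
#' @param refit_sims Re-estimate parameters on each simulated community.
#' @return Object of class `neutrality_test`: list with `formula`, `theta`,
#'   `m`, `logL_obs`, `logL_sims`, `mean_logL_sims`, `deviance_D`,
#'   `p_value`, `p_rank`, `n_sims`, `alpha`, `passes`, `fit_converged`.
#' @examples
#' set.seed(42)
#' ab <- simulate_community(theta = 5, m = 0.9, J = 80)
#' fit <- fit_etienne(ab)
#' exact_neutrality_test(ab, fit, n_sims = 20, seed = 1)
#' @export
exact_neutrality_test <- function(abund, fit, n_sims = 100, seed = 1,
                                  alpha = 0.05, refit_sims = FALSE) {
  stopifnot(n_sims >= 1, alpha > 0, alpha < 1)
  abund <- as_abundance(abund)
  J <- sum(abund)
  if (inherits(fit, "etienne_fit")) {
    formula <- "etienne"
    theta <- fit$theta; m <- fit$m
    I <- if (is.finite(fit$I)) fit$I else Inf
    score <- function(ab) {
      if (refit_sims) {
        f <- fit_etienne(ab)
        f$logL
      } else {
        etienne_loglik(ab, theta, min(m, 1 - 1e-12))
      }
    }
    logL_obs <- fit$logL
  } else if (inherits(fit, "ewens_fit")) {
    formula <- "ewens"
    theta <- fit$theta; m <- NA_real_
    I <- Inf
    score <- function(ab) {
      if (refit_sims) fit_ewens(ab)$logL else ewens_loglik(ab, theta)
    }
    logL_obs <- fit$logL
  } else stop("fit must be an ewens_fit or etienne_fit")
  if (!is.finite(theta)) stop("cannot test a degenerate fit (theta not finite)")

  sims <- simulate_batch(theta, J, n_reps = n_sims, seed = seed, I = I)
  logL_sims <- vapply(sims$abundances, score, numeric(1))
  mean_sims <- mean(logL_sims)
  lrt <- lrt_deviance(logL_obs, mean_sims)
  structure(list(
    formula = formula, theta = theta, m = m,
    logL_obs = logL_obs, logL_sims = logL_sims, mean_logL_sims = mean_sims,
    deviance_D = lrt$D, p_value = lrt$p,
    p_rank = mean(logL_sims <= logL_obs),
    n_sims = as.integer(n_sims), alpha = alpha,
    passes = lrt$p > alpha,
    fit_converged = isTRUE(fit$converged) || inherits(fit, "ewens_fit")
  ), class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf("Exact neutrality test (%s formula, %d simulations)\n",
              x$formula, x$n_sims))
  cat(sprintf("  logL_obs = %.4f, mean logL_sims = %.4f\n",
              x$logL_obs, x$mean_logL_sims))
  cat(sprintf("  D = %.4f, p = %.4f -> %s at alpha = %g\n",
              x$deviance_D, x$p_value,
              if (x$passes) "neutral (pass)" else "rejected", x$alpha))
  invisible(x)
}

#' Compare the Ewens and Etienne formulae on one sample
#'
#' Likelihood-ratio comparison of the two sampling formulae: the Ewens
#' formula is the null (nested in Etienne at m = 1), so
#' `D = -2 (logL_ewens - logL_etienne)` referred to chi-squared with one
#' degree of freedom, clamped as in [lrt_deviance()].
#'
#' @param ewens An [fit_ewens()] object.
#' @param etienne An [fit_etienne()] object on the same sample.
#' @return Tibble with one row: `logL_ewens`, `logL_etienne`, `D`, `p`.
#' @export
compare_formulae <- function(ewens, etienne) {
  stopifnot(inherits(ewens, "ewens_fit"), inherits(etienne, "etienne_fit"))
  if (ewens$J != etienne$J || ewens$S != etienne$S)
    stop("fits are not on the same configuration")
  lrt <- lrt_deviance(ewens$logL, etienne$logL)
  tibble::tibble(logL_ewens = ewens$logL, logL_etienne = etienne$logL,
                 D = lrt$D, p = lrt$p)
}

#' Fit sampling formulae across a set of configurations
#'
#' Maps [fit_ewens()] and/or [fit_etienne()] over a configurations tibble
#' (from [as_configurations()]), returning one row per sample and formula.
#'
#' @param configs Configurations tibble with `sample_id`, `treatment`, `J`,
#'   `S`, `abundances`.
#' @param formula `"both"` (default), `"ewens"`, or `"etienne"`.
#' @return Tibble with columns `sample_id`, `treatment`, `J`, `S`,
#'   `formula`, `theta`, `m` (`NA` for Ewens), `logL`, `converged`, and a
#'   `fit` list column holding the fit objects.
#' @export
fit_sad <- function(configs, formula = c("both", "ewens", "etienne")) {
  formula <- match.arg(formula)
  want <- if (formula == "both") c("ewens", "etienne") else formula
  purrr::map_dfr(want, function(fm) {
    fits <- purrr::map(configs$abundances,
                       if (fm == "ewens") fit_ewens else fit_etienne)
    tibble::tibble(
      sample_id = configs$sample_id, treatment = configs$treatment,
      J = configs$J, S = configs$S, formula = fm,
      theta = purrr::map_dbl(fits, "theta"),
      m = if (fm == "ewens") NA_real_ else purrr::map_dbl(fits, "m"),
      logL = purrr::map_dbl(fits, "logL"),
      converged = if (fm == "ewens") TRUE else purrr::map_lgl(fits, "converged"),
      fit = fits
    )
  })
}

#' Exact neutrality tests across a set of configurations
#'
#' Runs [exact_neutrality_test()] on every sample, then applies the
#' Benjamini-Hochberg adjustment across all samples tested with the same
#' formula (one family per formula per run). Sample `i` draws its
#' simulations from seed `seed + 1000 * i`, keeping verdicts reproducible
#' and independent of row order.
#'
#' @param configs Configurations tibble from [as_configurations()].
#' @param formula `"etienne"` (default) or `"ewens"`.
#' @param n_sims,alpha,refit_sims Passed to [exact_neutrality_test()].
#' @param seed Integer base seed.
#' @param adjust `"BH"` (default) or `"none"`.
#' @param fits Optional [fit_sad()] output to reuse; rows with the matching
#'   formula are used, anything missing is refitted.
#' @return Verdict tibble with `sample_id`, `treatment`, `J`, `S`,
#'   `formula`, `theta`, `m`, `logL_obs`, `mean_logL_sims`, `deviance_D`,
#'   `p_value`, `p_adjusted`, `p_rank`, `passes` (on adjusted p),
#'   `n_sims`, `converged`.
#' @export
test_neutrality <- function(configs, formula = c("etienne", "ewens"),
                            n_sims = 100, seed = 1, alpha = 0.05,
                            adjust = c("BH", "none"), refit_sims = FALSE,
                            fits = NULL) {
  formula <- match.arg(formula)
  adjust <- match.arg(adjust)
  if (is.null(fits)) fits <- fit_sad(configs, formula = formula)
  fits <- fits[fits$formula == formula, ]
  stopifnot(all(configs$sample_id %in% fits$sample_id))
  rows <- purrr::map(seq_len(nrow(configs)), function(i) {
    fit <- fits$fit[[match(configs$sample_id[i], fits$sample_id)]]
    vt <- exact_neutrality_test(configs$abundances[[i]], fit,
                                n_sims = n_sims,
                                seed = (seed + 1000 * i) %% .Machine$integer.max,
                                alpha = alpha, refit_sims = refit_sims)
    tibble::tibble(
      sample_id = configs$sample_id[i], treatment = configs$treatment[i],
      J = configs$J[i], S = configs$S[i], formula = formula,
      theta = vt$theta, m = vt$m, logL_obs = vt$logL_obs,
      mean_logL_sims = vt$mean_logL_sims, deviance_D = vt$deviance_D,
      p_value = vt$p_value, p_rank = vt$p_rank,
      n_sims = vt$n_sims, converged = vt$fit_converged
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust == "BH") adjust_pvalues(out$p_value) else out$p_value
  out$passes <- out$p_adjusted > alpha
  dplyr::relocate(out, "p_adjusted", .after = "p_value")
}
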