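#' Broom-style tidiers for fitted neutral models
#'
#' `tidy()` returns one row per estimated parameter; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted object (`ewens_fit`, `etienne_fit`,
#'   `neutrality_test`, `theta_anova`, or `passing_summary`).
#' @param ... Ignored.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ewens_fit <- function(x, ...) {
  tibble::tibble(term = "theta", estimate = x$theta)
}

#' @rdname tidiers
#' @export
glance.ewens_fit <- function(x, ...) {
  tibble::tibble(formula = "ewens", theta = x$theta, m = NA_real_,
                 logLik = x$logL, J = x$J, S = x$S, degenerate = x$degenerate)
}

#' @rdname tidiers
#' @export
tidy.etienne_fit <- function(x, ...) {
  tibble::tibble(term = c("theta", "m", "I"),
                 estimate = c(x$theta, x$m, x$I))
}

#' @rdname tidiers
#' @export
glance.etienne_fit <- function(x, ...) {
  tibble::tibble(formula = "etienne", theta = x$theta, m = x$m, I = x$I,
                 logLik = x$logL, J = x$J, S = x$S, converged = x$converged,
                 n_restarts_used = x$n_restarts_used)
}

#' @rdname tidiers
#' @export
tidy.neutrality_test <- function(x, ...) {
  tibble::tibble(formula = x$formula, theta = x$theta, m = x$m,
                 logL_obs = x$logL_obs, mean_logL_sims = x$mean_logL_sims,
                 deviance_D = x$deviance_D, p_value = x$p_value,
                 p_rank = x$p_rank, n_sims = x$n_sims, passes = x$passes)
}

#' @rdname tidiers
#' @export
tidy.theta_anova <- function(x, ...) x$pairwise

#' @rdname tidiers
#' @export
glance.theta_anova <- function(x, ...) {
  tibble::tibble(statistic = x$anova_F, p.value = x$anova_p,
                 n = x$n, n_pairs = x$n_pairs)
}

#' @rdname tidiers
#' @export
tidy.passing_summary <- function(x, ...) x$treatments

#' @rdname tidiers
#' @export
glance.passing_summary <- function(x, ...) {
  tibble::tibble(n = x$overall$n, n_pass = x$overall$n_pass,
                 pass_rate = x$overall$rate)
}
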