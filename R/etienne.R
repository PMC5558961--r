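#' Log-space row of unsigned Stirling numbers of the first kind
#'
#' Returns `log(s(n, a))` for `a = 1..n`, where `s(n, a)` counts permutations
#' of `n` elements with `a` cycles. Computed by the triangle recurrence
#' `s(n+1, a) = s(n, a-1) + n s(n, a)` entirely in log space (log-sum-exp),
#' so rows far beyond the `n = 170` double-precision factorial limit are
#' exact to rounding. Boundary identities: `s(n, 1) = (n-1)!`, `s(n, n) = 1`.
#'
#' @param n Row index, a positive integer.
#' @return Numeric vector of length `n`: `log(s(n, 1:n))`.
#' @examples
#' exp(log_stirling_row(3)) # 2 3 1
#' @export
log_stirling_row <- function(n) {
  stopifnot(length(n) == 1L, n >= 1)
  log_stirling_row_cpp(as.integer(n))
}

#' Etienne K(D, A) coefficients
#'
#' The combinatorial backbone of the Etienne sampling formula:
#' \deqn{K(D,A)=\sum_{\{a_i\,|\,\sum a_i=A\}} \prod_{i=1}^{S}
#'   \frac{s(n_i,a_i)\, s(a_i,1)}{s(n_i,1)}}
#' summing over allocations of `a_i` immigrant ancestors to species `i`.
#' Each species contributes the vector
#' `c_i(a) = log s(n_i, a) + lgamma(a) - lgamma(n_i)`, and the `S` vectors
#' are convolved sequentially in log space (species in descending abundance
#' order; the order does not change the result). `K` depends only on the
#' abundance multiset, never on `theta` or `m`, so it is computed once per
#' sample and reused across the likelihood surface.
#'
#' @param abund Positive integer abundance vector.
#' @return Object of class `etienne_K`: numeric vector `log K(D, A)` for
#'   `A = S..J` (names are the `A` values), with attributes `J` and `S`.
#' @examples
#' exp(etienne_K(c(2)))  # K = 1, 1 for A = 1, 2
#' @export
etienne_K <- function(abund) {
  abund <- as_abundance(abund)
  J <- sum(abund); S <- length(abund)
  logK <- etienne_logK_cpp(abund)
  structure(setNames(logK, S:J), class = "etienne_K", J = J, S = S)
}

#' Convert between immigration probability m and immigration number I
#'
#' `I = m (J - 1) / (1 - m)` is the equivalent number of immigrants
#' competing for each vacancy in a local community of `J` individuals;
#' `m = I / (I + J - 1)` inverts it. `m = 1` maps to `I = Inf`.
#'
#' @param m Immigration probability in (0, 1].
#' @param I Positive immigration number.
#' @param J Local community size, `J >= 2`.
#' @return The converted parameter.
#' @export
m_to_I <- function(m, J) {
  stopifnot(J >= 2, all(m > 0), all(m <= 1))
  ifelse(m == 1, Inf, m * (J - 1) / (1 - m))
}

#' @rdname m_to_I
#' @export
I_to_m <- function(I, J) {
  stopifnot(J >= 2, all(I > 0))
  ifelse(is.infinite(I), 1, I / (I + J - 1))
}

#' Etienne sampling formula log-likelihood
#'
#' Natural-log probability of an abundance configuration under the
#' dispersal-limited neutral model:
#' \deqn{\Pr(D\mid\theta,m,J)=\frac{J!}{\prod_i n_i \prod_j \phi_j!}
#'   \frac{\theta^S}{(I)_J}\sum_{A=S}^{J} K(D,A)\frac{I^A}{(\theta)_A}}
#' with `I = m (J-1) / (1-m)` and Pochhammer symbols `(x)_A` via log-gamma.
#' The `A` sum is a log-sum-exp over the precomputed [etienne_K()] vector.
#' As `m -> 1` this converges to the Ewens likelihood.
#'
#' @param abund Positive integer abundance vector.
#' @param theta Positive biodiversity number.
#' @param m Immigration probability, strictly inside (0, 1).
#' @param K Optional precomputed [etienne_K()] for `abund`; pass it when
#'   evaluating many `(theta, m)` points on the same sample.
#' @return Log-likelihood (nonpositive real).
#' @examples
#' exp(etienne_loglik(c(2), theta = 1, m = 0.5)) # 3/4 at I = 1
#' @export
etienne_loglik <- function(abund, theta, m, K = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("theta must be a single positive number")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 || m >= 1)
    stop("m must lie strictly inside (0, 1)")
  abund <- as_abundance(abund)
  J <- sum(abund); S <- length(abund)
  if (J == 1L) return(0)
  if (is.null(K)) K <- etienne_K(abund)
  stopifnot(length(K) == J - S + 1L)
  I <- m_to_I(m, J)
  A <- S:J
  phi <- phi_of(abund)
  terms <- as.numeric(K) + A * log(I) - (lgamma(theta + A) - lgamma(theta))
  # ln (I)_J as a direct product sum: the lgamma difference loses ~J digits
  # of absolute precision once I >> 1 (e.g. m = 1 - 1e-9)
  log_poch_I <- sum(log(I + 0:(J - 1)))
  lgamma(J + 1) - sum(log(abund)) - sum(lgamma(phi + 1)) + S * log(theta) -
    log_poch_I + logsumexp(terms)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit the Etienne sampling formula
#'
#' Joint maximum-likelihood estimation of `(theta, m)`. The `K(D, A)`
#' coefficients are computed once; the negative log-likelihood is then
#' minimized over the unconstrained scale `(log theta, logit m)` by
#' Nelder-Mead simplex search from three starts: `theta0` at the Ewens MLE
#' and `m0` in `{0.5, 0.9, 0.999}`. Convergence tolerance is `reltol` on
#' the objective, at most `maxit` evaluations per restart.
#'
#' @param abund Positive integer abundance vector.
#' @param starts_m Numeric vector of starting immigration probabilities.
#' @param reltol,maxit Nelder-Mead control parameters.
#' @return Object of class `etienne_fit`: list with `theta`, `m`,
#'   `I`, `logL`, `J`, `S`, `converged`, `n_restarts_used`, and
#'   `weakly_identified` (`TRUE` for `S = 1` samples, where `m` carries
#'   little information).
#' @examples
#' fit <- fit_etienne(c(20, 5, 3, 1, 1))
#' glance(fit)
#' @export
fit_etienne <- function(abund, starts_m = c(0.5, 0.9, 0.999),
                        reltol = 1e-8, maxit = 2000) {
  abund <- as_abundance(abund)
  J <- sum(abund); S <- length(abund)
  if (J == 1L)
    return(structure(list(theta = NaN, m = NaN, I = NaN, logL = 0, J = J, S = S,
                          converged = FALSE, n_restarts_used = 0L,
                          weakly_identified = TRUE),
                     class = "etienne_fit"))
  K <- etienne_K(abund)
  theta0 <- ewens_theta_mle(S, J)
  if (!is.finite(theta0) || theta0 <= 0) theta0 <- max(S / 2, 1)
  nll <- function(par) {
    th <- exp(par[1]); mm <- stats::plogis(par[2])
    if (!is.finite(th) || th <= 0 || mm <= 0 || mm >= 1) return(1e10)
    v <- -etienne_loglik(abund, th, mm, K = K)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL; used <- 0L; any_conv <- FALSE
  for (m0 in starts_m) {
    used <- used + 1L
    res <- tryCatch(
      optim(c(log(theta0), stats::qlogis(m0)), nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  # the Ewens solution is the m -> 1 boundary of the same family: keep it as
  # a candidate so the fitted optimum always dominates the nested model
  boundary <- c(log(theta0), stats::qlogis(1 - 1e-9))
  boundary_val <- nll(boundary)
  if (!is.null(best) && boundary_val < best$value) {
    best$par <- boundary; best$value <- boundary_val
    any_conv <- TRUE
  }
  if (is.null(best))
    return(structure(list(theta = theta0, m = NA_real_, I = NA_real_,
                          logL = NA_real_, J = J, S = S, converged = FALSE,
                          n_restarts_used = used,
                          weakly_identified = (S == 1L)),
                     class = "etienne_fit"))
  theta <- exp(best$par[1]); m <- stats::plogis(best$par[2])
  structure(list(theta = theta, m = m, I = m_to_I(m, J), logL = -best$value,
                 J = J, S = S, converged = any_conv, n_restarts_used = used,
                 weakly_identified = (S == 1L)),
            class = "etienne_fit")
}

#' @export
print.etienne_fit <- function(x, ...) {
  cat("Etienne sampling formula fit\n")
  cat(sprintf("  J = %d, S = %d\n", x$J, x$S))
  cat(sprintf("  theta = %.3f, m = %.5f (I = %.4g), logL = %.4f\n",
              x$theta, x$m, x$I, x$logL))
  if (!x$converged) cat("  warning: optimizer did not report convergence\n")
  if (x$weakly_identified) cat("  note: m weakly identified (S = 1)\n")
  invisible(x)
}
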