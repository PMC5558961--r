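#' Ewens sampling formula log-likelihood
#'
#' Natural-log probability of an abundance configuration under the Ewens
#' sampling formula, the neutral model without dispersal limitation (m = 1):
#'
#' \deqn{\ln\Pr = \ln J! + S\ln\theta - \sum_i \ln n_i - \sum_a \ln\phi_a!
#'   - \sum_{k=1}^{J}\ln(\theta + k - 1)}
#'
#' where `theta` is the fundamental biodiversity number. Everything is
#' computed via log-gamma, so counts up to 1e4 and beyond are safe.
#'
#' @param abund Positive integer abundance vector (one sample's SAD).
#' @param theta Positive fundamental biodiversity number.
#' @return Log-likelihood (a nonpositive real).
#' @examples
#' exp(ewens_loglik(c(1, 1), theta = 1)) # 1/2
#' @export
ewens_loglik <- function(abund, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("theta must be a single positive number")
  abund <- as_abundance(abund)
  J <- sum(abund); S <- length(abund)
  phi <- phi_of(abund)
  lgamma(J + 1) + S * log(theta) - sum(log(abund)) - sum(lgamma(phi + 1)) -
    (lgamma(theta + J) - lgamma(theta))
}

#' Maximum-likelihood fundamental biodiversity number
#'
#' Under the Ewens formula the species count `S` is sufficient for `theta`:
#' the score equation is \eqn{S = \sum_{k=0}^{J-1} \theta/(\theta+k)}, whose
#' right-hand side is the expected richness of a sample of `J` individuals
#' and is strictly increasing in `theta`. `ewens_theta_mle()` solves it by
#' bracketed root finding on `log(theta)` over `[1e-8, 1e8]`.
#'
#' @param S Observed species count, `1 <= S <= J`.
#' @param J Sample size (number of reads/individuals).
#' @return The root `theta`; `Inf` when `S == J` (every individual its own
#'   species; the likelihood increases without bound), and `NaN` for the
#'   J = 1 sample, where the likelihood is 1 for every `theta`.
#' @examples
#' ewens_theta_mle(S = 37, J = 537) # about 8.856
#' @export
ewens_theta_mle <- function(S, J) {
  stopifnot(S >= 1, J >= 1)
  if (S > J) stop("S cannot exceed J")
  if (J == 1L) return(NaN)
  if (S == J) return(Inf)
  if (S == 1L) {
    # score equation still has a root (expected richness -> 1 as theta -> 0
    # only in the limit); 1 < E[S] for all theta > 0, so the MLE is the
    # boundary theta -> 0: return the lower bracket end
    return(1e-8)
  }
  f <- function(logtheta) expected_richness(exp(logtheta), J) - S
  root <- uniroot(f, lower = log(1e-8), upper = log(1e8), tol = 1e-12)$root
  exp(root)
}

#' Fit the Ewens sampling formula
#'
#' Estimates `theta` by maximum likelihood (see [ewens_theta_mle()]) and
#' evaluates the log-likelihood at the estimate. The fit depends on the
#' configuration only through `(S, J)`.
#'
#' @param abund Positive integer abundance vector.
#' @return An object of class `ewens_fit`: a list with `theta`, `logL`,
#'   `J`, `S`, and `degenerate` (`TRUE` when `S == J`, where the MLE is the
#'   `theta = Inf` boundary and `logL` is reported at that limit, or when
#'   `J == 1`, where every `theta` gives probability 1).
#' @examples
#' fit <- fit_ewens(c(20, 5, 3, 1, 1))
#' tidy(fit)
#' @export
fit_ewens <- function(abund) {
  abund <- as_abundance(abund)
  J <- sum(abund); S <- length(abund)
  theta <- ewens_theta_mle(S, J)
  degenerate <- (S == J)
  logL <- if (J == 1L) {
    0
  } else if (degenerate) {
    # limit theta -> Inf of the Ewens probability of the all-singletons
    # configuration is J! * theta^J / ((prod n_i) phi! (theta)_J) -> 1/phi_1!
    # times J!/J! ... evaluate at a large theta instead of the limit:
    ewens_loglik(abund, 1e12)
  } else {
    ewens_loglik(abund, theta)
  }
  structure(list(theta = theta, logL = logL, J = J, S = S,
                 degenerate = degenerate),
            class = "ewens_fit")
}

#' Expected species richness under the Ewens formula
#'
#' \eqn{E[S \mid \theta, J] = \sum_{k=0}^{J-1} \theta/(\theta+k)}; used both
#' as the score function of [ewens_theta_mle()] and as the oracle for
#' validating the community simulator.
#'
#' @param theta Positive biodiversity number.
#' @param J Sample size.
#' @return Expected number of species (real, in `[1, J]`).
#' @export
expected_richness <- function(theta, J) {
  stopifnot(theta > 0, J >= 1)
  sum(theta / (theta + 0:(J - 1)))
}

#' @export
print.ewens_fit <- function(x, ...) {
  cat("Ewens sampling formula fit\n")
  cat(sprintf("  J = %d, S = %d\n", x$J, x$S))
  cat(sprintf("  theta = %.3f%s, logL = %.4f\n", x$theta,
              if (x$degenerate) " (degenerate)" else "", x$logL))
  invisible(x)
}
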