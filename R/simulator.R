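#' Simulate a neutral local community
#'
#' Sequential-urn construction of a dispersal-limited neutral sample of `J`
#' individuals, consistent with the Etienne sampling formula: individual `j`
#' founds a new immigrant lineage with probability `I / (I + j - 1)` and
#' otherwise copies a uniformly chosen earlier individual; each new lineage
#' draws its species from a Chinese-restaurant process with parameter
#' `theta` over the lineages so far (new species with probability
#' `theta / (theta + a - 1)` for the `a`-th lineage). `I = Inf` (equivalently
#' `m = 1`) collapses to the pure Ewens/CRP sampler in which every
#' individual immigrates.
#'
#' Randomness comes from R's global RNG: call `set.seed()` for
#' reproducibility, or use [simulate_batch()] for per-replicate streams.
#'
#' @param theta Positive biodiversity number.
#' @param J Community size (number of individuals).
#' @param I Positive immigration number (may be `Inf`).
#' @param m Alternatively, immigration probability in (0, 1]; exactly one
#'   of `I` and `m` must be given.
#' @return Integer abundance vector sorted in descending order; sums to `J`.
#' @examples
#' set.seed(1)
#' simulate_community(theta = 5, m = 0.9, J = 100)
#' @export
simulate_community <- function(theta, J, I = NULL, m = NULL) {
  if (is.null(I) == is.null(m)) stop("supply exactly one of I and m")
  if (is.null(I)) I <- m_to_I(m, max(J, 2))
  counts <- simulate_urn_cpp(theta, I, as.integer(J))
  sort(as.integer(counts), decreasing = TRUE)
}

#' Simulate a batch of neutral communities
#'
#' Generates `n_reps` independent communities at fixed `(theta, I, J)`.
#' Replicate `i` uses its own RNG stream seeded with `seed + i`, so the
#' batch is reproducible and independent of evaluation order. The caller's
#' RNG state is restored on exit.
#'
#' @inheritParams simulate_community
#' @param n_reps Number of communities.
#' @param seed Integer base seed.
#' @return Tibble with columns `replicate`, `J`, `S`, `abundances`
#'   (list column of descending integer vectors).
#' @export
simulate_batch <- function(theta, J, n_reps, seed, I = NULL, m = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(I) == is.null(m)) stop("supply exactly one of I and m")
  if (is.null(I)) I <- m_to_I(m, max(J, 2))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  sims <- lapply(seq_len(n_reps), function(i) {
    set.seed((seed + i) %% .Machine$integer.max)
    simulate_community(theta, J, I = I)
  })
  tibble::tibble(replicate = seq_len(n_reps), J = as.integer(J),
                 S = vapply(sims, length, integer(1)), abundances = sims)
}
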