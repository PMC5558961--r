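#' Specification for a study-shaped synthetic fixture
#'
#' Defaults emulate the shape of a subgingival 454 survey stratified into
#' three treatments: 17 healthy samples and 22 each from bleeding-on-probing
#' (BoP) and non-BoP periodontitis sites; per-sample read depths of
#' 500-4000; treatment-specific biodiversity numbers with the periodontitis
#' groups roughly 1.8x the healthy mean; and a mixture of neutral and
#' niche-structured communities with a neutral fraction near one quarter.
#'
#' @param n_per_treatment Named integer vector of sample counts.
#' @param J_range Inclusive range per-sample read depths are drawn from
#'   (uniform integers).
#' @param theta_by_treatment Named list of `c(mean, sd)` for the normal
#'   distribution the true theta of a neutral sample is drawn from
#'   (truncated below at 1).
#' @param m_range Range true immigration probabilities are drawn from.
#' @param neutral_fraction Probability a sample is generated by the neutral
#'   urn sampler rather than the niche generator.
#' @param niche_model `"lognormal"` or `"geometric"`.
#' @param niche_sigma Lognormal sd on the log scale.
#' @param niche_ratio Geometric-series ratio.
#' @param niche_S_range Range of niche species-pool sizes (uniform integers).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_treatment = c(Healthy = 17, BoP = 22, NonBoP = 22),
                         J_range = c(500, 4000),
                         theta_by_treatment = list(Healthy = c(15, 5),
                                                   BoP = c(27, 6),
                                                   NonBoP = c(27, 6)),
                         m_range = c(0.8, 0.9999),
                         neutral_fraction = 0.25,
                         niche_model = c("lognormal", "geometric"),
                         niche_sigma = 0.5, niche_ratio = 0.9,
                         niche_S_range = c(30, 165)) {
  niche_model <- match.arg(niche_model)
  stopifnot(neutral_fraction >= 0, neutral_fraction <= 1,
            J_range[1] >= 1, J_range[1] <= J_range[2],
            m_range[1] > 0, m_range[1] <= m_range[2], m_range[2] < 1)
  structure(list(n_per_treatment = n_per_treatment, J_range = J_range,
                 theta_by_treatment = theta_by_treatment, m_range = m_range,
                 neutral_fraction = neutral_fraction, niche_model = niche_model,
                 niche_sigma = niche_sigma, niche_ratio = niche_ratio,
                 niche_S_range = niche_S_range),
            class = "fixture_spec")
}

#' Niche-structured community generator
#'
#' The alternative-hypothesis generator: species relative abundances come
#' from a deterministic-niche abundance model and `J` reads are drawn
#' multinomially. `"lognormal"` draws `S_pool` relative abundances from a
#' lognormal (`meanlog = 0`, `sdlog = sigma`); `"geometric"` uses the
#' niche-preemption series `r^(i-1)`. Zero-count species are dropped.
#'
#' @param J Number of reads to draw.
#' @param model `"lognormal"` or `"geometric"`.
#' @param S_pool Species-pool size.
#' @param sigma Lognormal sd (0 gives equal expected abundances).
#' @param ratio Geometric ratio in (0, 1]; 1 gives equal expected abundances.
#' @return Integer abundance vector, descending, summing to `J`.
#' @export
niche_community <- function(J, model = c("lognormal", "geometric"),
                            S_pool = 30, sigma = 0.5, ratio = 0.9) {
  model <- match.arg(model)
  stopifnot(J >= 1, S_pool >= 1)
  rel <- switch(model,
    lognormal = if (sigma == 0) rep(1, S_pool) else rlnorm(S_pool, 0, sigma),
    geometric = ratio^(seq_len(S_pool) - 1))
  counts <- as.integer(rmultinom(1, size = J, prob = rel / sum(rel)))
  sort(counts[counts > 0], decreasing = TRUE)
}

#' Generate a study-shaped synthetic dataset
#'
#' Builds an OTU table, treatment map, and ground-truth table for a full
#' synthetic study. Each sample is generated by the neutral urn sampler
#' ([simulate_community()], with its true `theta` drawn from the
#' treatment's distribution and `m` from `m_range`) with probability
#' `neutral_fraction`, otherwise by [niche_community()]. Byte-identical
#' under a fixed seed. Taxon labels are opaque (`Otu0001`, ...) and
#' per-sample: the fixture carries no shared metacommunity structure.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List with `otu` (tibble, samples x taxa, zeros filled),
#'   `treatments` (tibble `sample_id`, `treatment`), and `truth` (tibble
#'   `sample_id`, `treatment`, `generator`, `theta`, `m`, `J`, `S`).
#' @examples
#' fx <- make_fixture(fixture_spec(n_per_treatment = c(Healthy = 2, BoP = 2),
#'                                 J_range = c(100, 200)), seed = 1)
#' fx$truth
#' @export
make_fixture <- function(spec = fixture_spec(), seed = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  prefix <- c(Healthy = "H", BoP = "PB", NonBoP = "PnB", Other = "X")
  rows <- list(); truth <- list()
  for (tr in names(spec$n_per_treatment)) {
    n_tr <- spec$n_per_treatment[[tr]]
    pars <- spec$theta_by_treatment[[tr]]
    if (is.null(pars)) pars <- c(20, 5)
    for (i in seq_len(n_tr)) {
      sid <- sprintf("%s%02d", prefix[[tr]] %||% "X", i)
      J <- sample(spec$J_range[1]:spec$J_range[2], 1)
      neutral <- runif(1) < spec$neutral_fraction
      if (neutral) {
        theta <- max(1, rnorm(1, pars[1], pars[2]))
        m <- runif(1, spec$m_range[1], spec$m_range[2])
        ab <- simulate_community(theta, J, m = m)
        truth[[sid]] <- tibble::tibble(sample_id = sid, treatment = tr,
                                       generator = "neutral", theta = theta,
                                       m = m, J = J, S = length(ab))
      } else {
        S_pool <- sample(spec$niche_S_range[1]:spec$niche_S_range[2], 1)
        ab <- niche_community(J, model = spec$niche_model, S_pool = S_pool,
                              sigma = spec$niche_sigma, ratio = spec$niche_ratio)
        truth[[sid]] <- tibble::tibble(sample_id = sid, treatment = tr,
                                       generator = spec$niche_model,
                                       theta = NA_real_, m = NA_real_,
                                       J = J, S = length(ab))
      }
      rows[[sid]] <- ab
    }
  }

  n_taxa <- max(vapply(rows, length, integer(1)))
  taxa <- sprintf("Otu%04d", seq_len(n_taxa))
  mat <- matrix(0L, nrow = length(rows), ncol = n_taxa,
                dimnames = list(names(rows), taxa))
  for (sid in names(rows)) mat[sid, seq_along(rows[[sid]])] <- rows[[sid]]
  otu <- tibble::tibble(sample_id = names(rows),
                        !!!as.data.frame(mat, optional = TRUE))
  truth <- dplyr::bind_rows(truth)
  list(otu = otu,
       treatments = truth[c("sample_id", "treatment")],
       truth = truth)
}

#' Write a fixture to disk
#'
#' Emits the same formats [read_otu_table()] and [read_treatment_map()]
#' read: a mothur `.shared` OTU table, a treatment map TSV, and the
#' ground-truth table `truth.tsv`.
#'
#' @param fixture Output of [make_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu = file.path(dir, "fixture.shared"),
             treatments = file.path(dir, "treatments.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_otu_table(fixture$otu, paths["otu"], format = "shared")
  write_treatment_map(fixture$treatments, paths["treatments"])
  readr::write_tsv(fixture$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
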