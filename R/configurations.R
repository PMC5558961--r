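#' Species abundance configurations
#'
#' An abundance configuration is one sample's species abundance distribution
#' (SAD): the vector of positive per-species counts `n_1 >= n_2 >= ... >= n_S`,
#' with `J = sum(n_i)` individuals (reads) and `S` species. The frequency of
#' frequencies `phi_a` counts the species with abundance exactly `a`; the
#' identities `sum_a phi_a = S` and `sum_a a * phi_a = J` always hold.
#'
#' `as_configurations()` turns an OTU table (as returned by
#' [read_otu_table()]) into a tibble of configurations, one row per sample.
#' Zero-count taxa are dropped per sample, abundances are sorted in
#' descending order (ties broken by taxon id so output is deterministic),
#' and samples with no positive counts are excluded with a warning.
#'
#' @param otu A tibble with a `sample_id` column followed by one
#'   nonnegative-integer count column per taxon.
#' @param treatments Optional treatment map: a data frame with columns
#'   `sample_id` and `treatment`, or a named character vector. Labels are
#'   matched case-insensitively to Healthy / BoP / NonBoP; anything else
#'   (including unmapped samples) becomes `Other`.
#' @return A tibble with columns `sample_id`, `treatment` (factor), `J`,
#'   `S`, and `abundances` (list column of descending integer vectors,
#'   named by taxon id).
#' @examples
#' otu <- tibble::tibble(sample_id = c("a", "b"),
#'                       t1 = c(5L, 1L), t2 = c(3L, 1L), t3 = c(0L, 1L))
#' as_configurations(otu)
#' @export
as_configurations <- function(otu, treatments = NULL) {
  stopifnot(is.data.frame(otu), "sample_id" %in% names(otu))
  counts <- as.matrix(otu[setdiff(names(otu), "sample_id")])
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts in OTU table")
  taxa <- colnames(counts)

  tmap <- treatment_lookup(treatments)
  rows <- lapply(seq_len(nrow(otu)), function(i) {
    x <- counts[i, ]
    keep <- which(x > 0)
    if (length(keep) == 0L) return(NULL)
    ab <- sort_abundances(x[keep], taxa[keep])
    tibble::tibble(sample_id = otu$sample_id[i],
                   J = sum(ab), S = length(ab), abundances = list(ab))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    warning("excluding ", sum(empty), " sample(s) with no positive counts: ",
            paste(otu$sample_id[empty], collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  out$treatment <- normalize_treatment(tmap[out$sample_id])
  dplyr::select(out, "sample_id", "treatment", "J", "S", "abundances")
}

# descending counts, ties broken by taxon id (lexicographic) for determinism
sort_abundances <- function(x, ids) {
  ord <- order(-x, ids)
  as.integer(setNames(x[ord], ids[ord]))
}

treatment_lookup <- function(treatments) {
  if (is.null(treatments)) return(character(0))
  if (is.data.frame(treatments)) {
    stopifnot(all(c("sample_id", "treatment") %in% names(treatments)))
    return(setNames(as.character(treatments$treatment), treatments$sample_id))
  }
  stopifnot(!is.null(names(treatments)))
  setNames(as.character(treatments), names(treatments))
}

# coerce a bare count vector to a valid configuration (positive, descending)
as_abundance <- function(x) {
  if (is.list(x) && length(x) == 1L) x <- x[[1]]
  x <- as.integer(round(x))
  x <- x[x > 0]
  if (length(x) == 0L) stop("configuration has no positive abundances")
  sort(x, decreasing = TRUE)
}

#' Frequency of frequencies of a configuration
#'
#' @param abund Positive integer abundance vector.
#' @return Named integer vector: `phi["a"]` is the number of species with
#'   abundance `a`; only realized abundance classes appear.
#' @examples
#' phi_of(c(2, 2, 1)) # phi_2 = 2, phi_1 = 1
#' @export
phi_of <- function(abund) {
  abund <- as_abundance(abund)
  tab <- table(abund)
  setNames(as.integer(tab), names(tab))
}

#' Rank-abundance coordinates
#'
#' Returns the rank-abundance curve (Whittaker plot coordinates) for one or
#' many configurations: species rank on the x axis, natural-log abundance on
#' the y axis.
#'
#' @param x Either a configurations tibble from [as_configurations()] or a
#'   single positive integer abundance vector.
#' @return A tibble with columns `sample_id`, `rank`, `abundance`,
#'   `log_abundance` (natural log), nonincreasing in rank within a sample.
#' @examples
#' rank_abundance(c(8, 2, 1))
#' @export
rank_abundance <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample_id", "abundances") %in% names(x)))
    purrr::map2_dfr(x$sample_id, x$abundances, function(id, ab) {
      ab <- as_abundance(ab)
      tibble::tibble(sample_id = id, rank = seq_along(ab),
                     abundance = ab, log_abundance = log(ab))
    })
  } else {
    ab <- as_abundance(x)
    tibble::tibble(sample_id = NA_character_, rank = seq_along(ab),
                   abundance = ab, log_abundance = log(ab))
  }
}
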