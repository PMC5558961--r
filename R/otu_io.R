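#' Read an OTU count table
#'
#' Reads a samples-by-taxa count table either from a mothur `.shared` file
#' (tab-separated with `label`, `Group`, `numOtus` header columns, samples as
#' rows) or from a plain TSV whose header row holds taxon ids. Plain TSV is
#' accepted in either orientation via `samples_in`.
#'
#' @param path Path to the file.
#' @param format `"shared"`, `"tsv"`, or `"auto"` (default: `.shared`
#'   extension or a `label`/`Group` header selects the mothur dialect).
#' @param samples_in For plain TSV only: `"rows"` (default) if each row is a
#'   sample, `"cols"` if each column is a sample.
#' @return A tibble with a `sample_id` column followed by one integer count
#'   column per taxon.
#' @export
read_otu_table <- function(path, format = c("auto", "shared", "tsv"),
                           samples_in = c("rows", "cols")) {
  format <- match.arg(format)
  samples_in <- match.arg(samples_in)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop("malformed header in ", path, ": need >= 2 columns")
  if (format == "auto") {
    format <- if (grepl("\\.shared$", path) ||
                  all(c("label", "Group", "numOtus") %in% names(raw))) "shared" else "tsv"
  }

  if (format == "shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(raw)))
      stop("malformed shared header in ", path, ": missing ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    sample_id <- raw$Group
    counts <- raw[setdiff(names(raw), need)]
  } else {
    sample_id <- raw[[1]]
    counts <- raw[-1]
    if (samples_in == "cols") {
      taxa <- sample_id
      sample_id <- names(counts)
      counts <- as.data.frame(t(as.matrix(counts)))
      names(counts) <- taxa
    }
  }

  counts[] <- lapply(counts, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (any(is.na(v))) stop("non-numeric count in ", path)
    v
  })
  bad <- which(apply(as.matrix(counts) < 0, 1, any))
  if (length(bad) > 0L)
    stop("negative count in ", path, " at data line ", bad[1],
         " (sample ", sample_id[bad[1]], ")")
  dup <- duplicated(sample_id)
  if (any(dup))
    stop("duplicate sample id in ", path, ": ", sample_id[which(dup)[1]],
         " at data line ", which(dup)[1])
  counts[] <- lapply(counts, function(v) as.integer(round(v)))
  tibble::tibble(sample_id = sample_id, !!!counts)
}

#' Write an OTU table
#'
#' Writes the inverse of [read_otu_table()]: a mothur `.shared` file
#' (`label` fixed at `"0.03"`) or a plain samples-in-rows TSV. Reading the
#' written file back reproduces the counts exactly.
#'
#' @param otu Tibble with `sample_id` plus taxon count columns.
#' @param path Output path.
#' @param format `"shared"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu, path, format = c("shared", "tsv")) {
  format <- match.arg(format)
  stopifnot("sample_id" %in% names(otu))
  if (format == "shared") {
    taxa <- setdiff(names(otu), "sample_id")
    out <- tibble::tibble(label = "0.03", Group = otu$sample_id,
                          numOtus = length(taxa), !!!otu[taxa])
  } else {
    out <- otu
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample-to-treatment map
#'
#' The treatment map is a 2-column TSV `sample_id<TAB>treatment` (header
#' optional on read). Labels are kept verbatim here; they are normalized to
#' Healthy / BoP / NonBoP / Other by [as_configurations()].
#'
#' @param path Path to the TSV.
#' @return For the reader, a tibble with columns `sample_id`, `treatment`.
#' @export
read_treatment_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) stop("malformed treatment map: need 2 columns")
  if (!all(c("sample_id", "treatment") %in% names(tab))) {
    # headerless file: first row is data
    tab <- readr::read_tsv(path, col_names = c("sample_id", "treatment"),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  }
  tibble::tibble(sample_id = tab$sample_id, treatment = tab$treatment)
}

#' @rdname read_treatment_map
#' @param treatments Tibble with columns `sample_id`, `treatment`.
#' @export
write_treatment_map <- function(treatments, path) {
  readr::write_tsv(treatments[c("sample_id", "treatment")], path, progress = FALSE)
  invisible(path)
}
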