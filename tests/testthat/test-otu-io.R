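test_that("plain TSV OTU tables parse with correct per-sample totals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttaxA\ttaxB\ttaxC",
               "s1\t5\t3\t0",
               "s2\t1\t1\t1"), path)
  otu <- read_otu_table(path, format = "tsv")
  expect_equal(otu$sample_id, c("s1", "s2"))
  expect_equal(rowSums(as.matrix(otu[-1])), c(8, 3), ignore_attr = TRUE)

  # same table transposed, samples in columns
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2",
               "taxA\t5\t1",
               "taxB\t3\t1",
               "taxC\t0\t1"), path2)
  otu2 <- read_otu_table(path2, format = "tsv", samples_in = "cols")
  expect_equal(otu2$sample_id, c("s1", "s2"))
  expect_equal(as.matrix(otu2[-1]), as.matrix(otu[-1]), ignore_attr = TRUE)
})

test_that("mothur shared files take sample ids from the Group column", {
  path <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\tOtu001\tOtu002",
               "0.03\tmouthA\t2\t4\t2",
               "0.03\tmouthB\t2\t0\t9"), path)
  otu <- read_otu_table(path)
  expect_equal(otu$sample_id, c("mouthA", "mouthB"))
  expect_equal(otu$Otu002, c(2L, 9L))
  expect_false(any(c("label", "numOtus") %in% names(otu)))
})

test_that("malformed inputs raise parse errors naming the problem", {
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ta\tb", "s1\t5\t-2"), neg)
  expect_error(read_otu_table(neg, format = "tsv"), "negative count")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ta", "s1\t5", "s1\t2"), dup)
  expect_error(read_otu_table(dup, format = "tsv"), "duplicate sample id")

  badshared <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tWrong\tnumOtus\tOtu001", "0.03\ts\t1\t5"), badshared)
  expect_error(read_otu_table(badshared, format = "shared"), "Group")

  expect_error(read_otu_table(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("write/read round trip preserves counts in both formats", {
  otu <- tibble::tibble(sample_id = c("x", "y"),
                        Otu1 = c(5L, 0L), Otu2 = c(3L, 7L), Otu3 = c(1L, 2L))
  for (fmt in c("shared", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_otu_table(otu, path, format = fmt)
    back <- read_otu_table(path, format = fmt)
    expect_equal(back, otu)
  }
})

test_that("configurations drop zeros, sort descending, and satisfy the phi identities", {
  otu <- tibble::tibble(sample_id = c("s1", "s2", "empty"),
                        a = c(5L, 2L, 0L), b = c(3L, 2L, 0L), c = c(0L, 1L, 0L))
  expect_warning(cfg <- as_configurations(otu), "empty")
  expect_equal(nrow(cfg), 2L)
  expect_equal(cfg$J, c(8L, 5L))
  expect_equal(cfg$S, c(2L, 3L))
  expect_equal(as.integer(cfg$abundances[[1]]), c(5L, 3L))

  phi <- phi_of(cfg$abundances[[2]])
  expect_equal(phi, c(`1` = 1L, `2` = 2L))
  for (i in seq_len(nrow(cfg))) {
    p <- phi_of(cfg$abundances[[i]])
    a <- as.integer(names(p))
    expect_equal(sum(p), cfg$S[i])
    expect_equal(sum(a * p), cfg$J[i])
  }
})

test_that("treatment labels map case-insensitively and unknowns become Other", {
  otu <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                        a = c(1L, 1L, 1L, 1L))
  tm <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       treatment = c("HEALTHY", "non-bop", "plaque"))
  cfg <- as_configurations(otu, tm)
  expect_equal(as.character(cfg$treatment),
               c("Healthy", "NonBoP", "Other", "Other"))
})

test_that("rank abundance is ranks 1..S with nonincreasing ln abundance", {
  ra <- rank_abundance(c(8, 2, 1))
  expect_equal(ra$rank, 1:3)
  expect_equal(ra$log_abundance, c(log(8), log(2), 0))

  expect_equal(nrow(rank_abundance(c(5))), 1L)
  ties <- rank_abundance(c(3, 3))
  expect_equal(ties$log_abundance, rep(log(3), 2))

  set.seed(42)
  for (i in 1:10) {
    ab <- sort(rpois(20, 5) + 1, decreasing = TRUE)
    expect_true(all(diff(rank_abundance(ab)$log_abundance) <= 0))
  }
})
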