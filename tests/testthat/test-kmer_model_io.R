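test_that("kmer-model tables read in both dialects and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAAAAA\t100.0", "AAAAAT\t95.5"), p)
  m <- read_kmer_model(p)
  expect_identical(nrow(m), 2L)
  expect_equal(model_levels(m, "AAAAAT"), c(AAAAAT = 95.5))
  # header + comments tolerated
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ont model", "kmer\tlevel_mean\tlevel_stdv",
               "AAAAAA\t100.0\t2.0"), p2)
  m2 <- read_kmer_model(p2)
  expect_identical(names(m2), c("kmer", "level_mean", "level_stdv"))
  # nanopolish dialect maps M to 5mC
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAMAAA\t88.2"), p3)
  m3 <- read_kmer_model(p3, dialect = "nanopolish")
  expect_identical(m3$kmer, "AA[5mC]AAA")
  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_model(m, out)
  back <- read_kmer_model(out)
  expect_equal(back$level_mean, m$level_mean)
  expect_identical(back$kmer, m$kmer)
})

test_that("malformed model tables fail with located errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAAAAA\t100.0", "AAAAAA\t95.0"), p)
  expect_error(read_kmer_model(p), "duplicate")
  writeLines(c("AAAAAA\t100.0", "AAAAAT\tbad"), p)
  expect_error(read_kmer_model(p), "line 2")
  writeLines(c("AAAAAA\t100.0", "AAAAAT"), p)
  expect_error(read_kmer_model(p), "ragged")
  writeLines(c("AAAAAA\t100.0", "AAAT\t95.0"), p)
  expect_error(read_kmer_model(p), "mixed kmer lengths")
})

test_that("model writing is deterministic and byte-identical", {
  kk <- enumerate_kmers(alpha_dna(), 6)
  m <- kmer_model(data.frame(kmer = rev(kk), level_mean = seq_along(kk)))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_kmer_model(m, p1)
  write_kmer_model(m, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(length(readLines(p1)), 4097L)  # header + 4096 rows
  # empty model writes a header-only file
  e <- kmer_model(data.frame(kmer = character(0), level_mean = numeric(0)))
  pe <- withr::local_tempfile()
  write_kmer_model(e, pe)
  expect_identical(readLines(pe), "kmer\tlevel_mean")
})

test_that("eventalign parsing skips placeholder rows and permuted columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eventalign_fixture(p, c("AATGC", "ATGCC", "TTTTT"),
                           c(80, 95, 101), n_placeholder = 1)
  ev <- read_eventalign(p)
  expect_identical(nrow(ev), 3L)
  expect_identical(attr(ev, "n_skipped"), 1L)
  # name-based parsing: column order is irrelevant
  p2 <- withr::local_tempfile(fileext = ".tsv")
  set.seed(2)
  write_eventalign_fixture(p2, c("AATGC", "ATGCC"), c(80, 95),
                           shuffle_cols = TRUE)
  ev2 <- read_eventalign(p2)
  expect_identical(sort(ev2$model_kmer), c("AATGC", "ATGCC"))
  # missing mandatory column
  tab <- read.delim(p)
  write.table(tab[, setdiff(names(tab), "event_level_mean")], p2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_eventalign(p2), "event_level_mean")
  # malformed numeric field
  tab$event_level_mean <- as.character(tab$event_level_mean)
  tab$event_level_mean[2] <- "oops"
  write.table(tab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_eventalign(p2), "malformed numeric")
})

test_that("empirical model averages instances and applies min_count", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eventalign_fixture(p, c("AATGC", "AATGC", "AATGC", "GGGGG"),
                           c(80, 90, 100, 77))
  ev <- read_eventalign(p)
  m <- empirical_model_from_events(ev, nucleic_type = "RNA")
  expect_equal(model_levels(m, "AATGC"), c(AATGC = 90))
  expect_equal(model_levels(m, "GGGGG"), c(GGGGG = 77))
  m2 <- empirical_model_from_events(ev, min_count = 2, nucleic_type = "RNA")
  expect_identical(m2$kmer, "AATGC")
  expect_identical(attr(m2, "excluded"), "GGGGG")
  expect_warning(empirical_model_from_events(ev[0, ], nucleic_type = "RNA"),
                 "empty")
})

test_that("chunked accumulation equals batch averaging regardless of order", {
  set.seed(31)
  kk <- sample(enumerate_kmers(alpha_rna(), 3), 400, replace = TRUE)
  means <- rnorm(400, 100, 8)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eventalign_fixture(p, kk, means)
  batch <- empirical_model_from_events(read_eventalign(p),
                                       nucleic_type = "RNA")
  # same rows split across three files, shuffled
  ord <- sample(400)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, paste0("chunk", 1:3, ".tsv"))
  sets <- split(ord, rep(1:3, length.out = 400))
  for (i in 1:3)
    write_eventalign_fixture(paths[i], kk[sets[[i]]], means[sets[[i]]])
  streamed <- empirical_model_from_events(paths, nucleic_type = "RNA")
  expect_identical(streamed$kmer, batch$kmer)
  expect_equal(streamed$level_mean, batch$level_mean, tolerance = 1e-9)
})

test_that("the canonical/6mA RNA union has 2*4^5 - 3^5 = 1805 kmers", {
  canonical <- enumerate_kmers(alpha_rna(), 5)
  modified <- enumerate_kmers(alphabet(c("6mA", "U", "G", "C"), "RNA"), 5)
  expect_identical(length(union(canonical, modified)), 1805L)
  expect_identical(length(union(canonical, modified)),
                   as.integer(2 * 4^5 - 3^5))
})
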