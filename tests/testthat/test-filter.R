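test_that("pair_level removes the whole pair when either mate maps", {
  reads <- paired_reads_df(1)
  v <- verdicts_df(reads$id, c(TRUE, FALSE))  # mate1 mapped, mate2 not
  fr <- filter_reads(reads, v, "pair_level")
  expect_equal(nrow(fr$removed), 2L)
  expect_equal(nrow(fr$retained), 0L)

  # same verdicts, read_level: the unmapped mate survives as a singleton
  fr2 <- filter_reads(reads, v, "read_level")
  expect_equal(fr2$removed$id, reads$id[1])
  expect_equal(fr2$retained$id, reads$id[2])
})

test_that("empty input produces empty outputs and zero tallies", {
  reads <- paired_reads_df(1)[0, ]
  fr <- filter_reads(reads, verdicts_df(character(0), logical(0)),
                     "read_level")
  expect_equal(nrow(fr$retained), 0L)
  expect_equal(nrow(fr$removed), 0L)
  expect_equal(fr$tally$bp, c(0L, 0L, 0L))
})

test_that("a missing verdict is an error naming the read", {
  reads <- paired_reads_df(2)
  v <- verdicts_df(reads$id[-3], rep(FALSE, 3))
  expect_error(filter_reads(reads, v, "pair_level"), reads$id[3])
})

test_that("pair_level rejects unpaired input", {
  reads <- paired_reads_df(2)[1:3, ]  # second pair missing its mate
  v <- verdicts_df(reads$id, rep(FALSE, 3))
  expect_error(filter_reads(reads, v, "pair_level"), "paired input")
  # read_level accepts the same input
  expect_silent(filter_reads(reads, v, "read_level"))
})

test_that("retained and removed always partition the input, and read_level removals are a subset of pair_level removals", {
  set.seed(301)
  for (rep in 1:5) {
    reads <- paired_reads_df(200)
    v <- verdicts_df(reads$id, stats::runif(nrow(reads)) < 0.4)
    fr_pair <- filter_reads(reads, v, "pair_level")
    fr_read <- filter_reads(reads, v, "read_level")
    for (fr in list(fr_pair, fr_read)) {
      expect_setequal(c(fr$retained$id, fr$removed$id), reads$id)
      expect_length(intersect(fr$retained$id, fr$removed$id), 0L)
      # order preservation within each stream
      expect_equal(fr$retained$id,
                   reads$id[reads$id %in% fr$retained$id])
    }
    expect_true(all(fr_read$removed$id %in% fr_pair$removed$id))
  }
})

test_that("background_fraction is removed bp over total bp, two decimals", {
  reads <- data.frame(id = paste0("s", 1:4), seq = strrep("A", 100),
                      qual = strrep("I", 100), mate = 0L,
                      stringsAsFactors = FALSE)
  v <- verdicts_df(reads$id, c(TRUE, TRUE, TRUE, FALSE))
  fr <- filter_reads(reads, v, "read_level")
  expect_equal(background_fraction(fr), 75.00)

  all_removed <- filter_reads(reads, verdicts_df(reads$id, rep(TRUE, 4)),
                              "read_level")
  expect_equal(background_fraction(all_removed), 100.00)
  none_removed <- filter_reads(reads, verdicts_df(reads$id, rep(FALSE, 4)),
                               "read_level")
  expect_equal(background_fraction(none_removed), 0.00)

  empty <- filter_reads(reads[0, ], verdicts_df(character(0), logical(0)),
                        "read_level")
  expect_error(background_fraction(empty), "zero total bp")
})

test_that("FASTQ reading and writing round-trip, paired and gzipped", {
  reads <- paired_reads_df(25)
  p1 <- tempfile(fileext = ".fastq")
  p2 <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads[reads$mate == 1L, ], p1)
  write_fastq(reads[reads$mate == 2L, ], p2)
  back <- read_fastq(p1, p2)
  expect_equal(back$id, reads$id)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  expect_equal(back$mate, reads$mate)

  # interleaved single-file route
  p3 <- tempfile(fileext = ".fastq")
  write_fastq(reads, p3)
  inter <- read_fastq(p3, interleaved = TRUE)
  expect_equal(inter$seq, reads$seq)
  expect_equal(inter$mate, reads$mate)
})

test_that("filter outputs land on disk in the advertised shapes", {
  set.seed(302)
  reads <- paired_reads_df(30)
  v <- verdicts_df(reads$id, stats::runif(60) < 0.5)
  fr <- filter_reads(reads, v, "pair_level")
  out <- tempfile()
  paths <- write_filter_outputs(fr, out)
  expect_true(all(file.exists(paths)))
  r1 <- read_fastq(paths[["retained_r1"]], paths[["retained_r2"]])
  expect_setequal(r1$id, fr$retained$id)
  removed_ids <- readLines(paths[["removed_ids"]])
  expect_setequal(removed_ids, fr$removed$id)
  tally <- utils::read.table(paths[["tally"]], header = TRUE, sep = "\t")
  expect_equal(tally$bp[tally$class == "total"],
               sum(nchar(reads$seq)))
})
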