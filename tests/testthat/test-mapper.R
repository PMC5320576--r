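test_that("the seed index holds exactly the N-free positional k-mers", {
  bg <- bg_from_seqs("ACGTACGT")
  idx <- index_background(bg, k = 4L)
  expect_equal(idx$n_kmers, 5L)  # 8 - 4 + 1

  bg2 <- bg_from_seqs("AANAA")
  idx2 <- index_background(bg2, k = 2L)
  expect_equal(idx2$n_kmers, 2L)  # AA, AA; AN and NA excluded
  expect_null(idx2$env[["AN"]])
  expect_null(idx2$env[["NA"]])

  # a fully masked record contributes nothing
  bg3 <- bg_from_seqs(c(strrep("N", 100), "ACGTACGTACGT"))
  idx3 <- index_background(bg3, k = 6L)
  expect_equal(idx3$n_kmers, 12L - 6L + 1L)

  expect_error(index_background(bg_from_seqs("ACGT"), k = 10L),
               "exceeds every background record")
})

test_that("exact substrings map with identity 1 on either strand", {
  set.seed(101)
  bgseq <- rand_dna(5000)
  bg <- bg_from_seqs(bgseq, "chr")
  idx <- index_background(bg, 15L)
  cfg <- mapper_config()

  read <- substr(bgseq, 1001, 1100)
  v <- map_read(read, idx, cfg)
  expect_true(v$mapped)
  expect_equal(v$identity, 1.0)
  expect_equal(v$aligned_fraction, 1.0)
  expect_equal(v$start, 1001L)
  expect_equal(v$strand, "+")

  vr <- map_read(revcomp(read), idx, cfg)
  expect_true(vr$mapped)
  expect_equal(vr$start, 1001L)
  expect_equal(vr$strand, "-")
})

test_that("reads from masked regions never map", {
  set.seed(102)
  left <- rand_dna(2000)
  right <- rand_dna(2000)
  masked_src <- rand_dna(1000)  # what the masked window used to be
  bg <- bg_from_seqs(paste0(left, strrep("N", 1000), right), "chr")
  idx <- index_background(bg, 15L)
  read <- substr(masked_src, 101, 250)
  v <- map_read(read, idx, mapper_config())
  expect_false(v$mapped)
})

test_that("mismatch tolerance follows the identity threshold", {
  set.seed(103)
  bgseq <- rand_dna(20000)
  bg <- bg_from_seqs(bgseq, "chr")
  idx <- index_background(bg, 15L)
  cfg <- mapper_config()  # min_identity 0.90

  clean <- substr(bgseq, 5001, 5100)  # 100 bp
  r6 <- place_mismatches(clean, 6L)
  v6 <- map_read(r6, idx, cfg)
  expect_true(v6$mapped)
  expect_equal(v6$identity, 0.94)
  expect_true(brute_force_mapped(r6, bg, cfg))

  r12 <- place_mismatches(clean, 12L)
  v12 <- map_read(r12, idx, cfg)
  expect_false(v12$mapped)
  expect_false(brute_force_mapped(r12, bg, cfg))
})

test_that("mapper decisions agree with the brute-force all-offsets scan", {
  set.seed(104)
  bgseq <- rand_dna(8000)
  bg <- bg_from_seqs(paste0(substr(bgseq, 1, 3000), strrep("N", 500),
                            substr(bgseq, 3501, 8000)), "chr")
  idx <- index_background(bg, 15L)
  cfg <- mapper_config()
  n <- 80
  reads <- character(n)
  for (i in seq_len(n)) {
    type <- sample(c("exact", "err1", "err2", "random", "edge"), 1)
    if (type == "random") {
      reads[i] <- rand_dna(150)
    } else if (type == "edge") {
      # hang off the record end: clipped placement
      reads[i] <- paste0(substr(bgseq, 7901, 8000), rand_dna(30))
    } else {
      st <- sample.int(8000 - 150 + 1, 1)
      r <- substr(bgseq, st, st + 149)
      rate <- c(exact = 0, err1 = 0.01, err2 = 0.02)[type]
      r <- add_subs(r, rate)
      if (stats::runif(1) < 0.5) r <- revcomp(r)
      reads[i] <- r
    }
  }
  mine <- map_reads(data.frame(id = sprintf("r%03d", 1:n), seq = reads),
                    idx, cfg)$mapped
  oracle <- vapply(reads, brute_force_mapped, logical(1), bg = bg, cfg = cfg)
  expect_equal(unname(mine), unname(oracle))
})

test_that("relaxing thresholds never shrinks the mapped set", {
  set.seed(105)
  bgseq <- rand_dna(6000)
  bg <- bg_from_seqs(bgseq, "chr")
  idx <- index_background(bg, 15L)
  reads <- data.frame(id = sprintf("r%03d", 1:60),
                      seq = vapply(1:60, function(i) {
                        st <- sample.int(6000 - 150 + 1, 1)
                        add_subs(substr(bgseq, st, st + 149),
                                 sample(c(0, 0.02, 0.05, 0.12), 1))
                      }, character(1)))
  strict <- mapper_config(min_identity = 0.95, min_aligned_fraction = 0.9)
  loose <- mapper_config(min_identity = 0.85, min_aligned_fraction = 0.7)
  m_strict <- map_reads(reads, idx, strict)
  m_loose <- map_reads(reads, idx, loose)
  expect_true(all(reads$id[m_strict$mapped] %in% reads$id[m_loose$mapped]))
})

test_that("placement ties break on target id, then position, then strand", {
  repeat_unit <- "ACGTTGCAATTGGCCAACGGTCAGTCAGGATCCA"
  seq <- paste0(strrep(repeat_unit, 3), rand_dna(50))
  # identical sequence present in two records: lowest id must win
  bg <- bg_from_seqs(c(seq, seq), c("zrec", "arec"))
  idx <- index_background(bg, 15L)
  v <- map_read(repeat_unit, idx, mapper_config(seed_length = 15L))
  expect_true(v$mapped)
  expect_equal(v$target, "arec")
  expect_equal(v$start, 1L)  # first of the tandem copies
  expect_equal(v$strand, "+")
})

test_that("reads shorter than the seed are unmapped with a warning", {
  bg <- bg_from_seqs(rand_dna(1000))
  idx <- index_background(bg, 15L)
  expect_warning(v <- map_read("ACGTACGT", idx, mapper_config()),
                 "shorter than the seed")
  expect_false(v$mapped)
  reads <- data.frame(id = c("a", "b"), seq = c("ACGTACGT", "ACGT"))
  expect_warning(vv <- map_reads(reads, idx, mapper_config()),
                 "2 read")
  expect_equal(vv$mapped, c(FALSE, FALSE))
})

test_that("mapper configuration rejects out-of-range parameters", {
  expect_error(mapper_config(seed_length = 4), ">= 8")
  expect_error(mapper_config(min_identity = 1.5), "min_identity")
  expect_error(mapper_config(min_aligned_fraction = 0), "min_aligned_fraction")
})
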