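make_feature <- function(product, kind = "CDS", start = 1L, end = 10L,
                         seq_id = "s1", id = "f1", note = NULL,
                         fun = NULL, gene = NULL) {
  q <- list(product = product)
  if (!is.null(note)) q$note <- note
  if (!is.null(fun)) q[["function"]] <- fun
  if (!is.null(gene)) q$gene <- gene
  data.frame(seq_id = seq_id, start = start, end = end, strand = "+",
             kind = kind, feature_id = id, qualifiers = I(list(q)),
             stringsAsFactors = FALSE)
}

test_that("viral features are selected by case-insensitive substring", {
  feats <- rbind(
    make_feature("phage tail fiber protein", id = "a"),
    make_feature("hypothetical protein", id = "b"),
    make_feature("Bacteriophage P2 integrase", id = "c"),
    make_feature("capsid", note = "similar to VIRAL coat proteins",
                 id = "d"),
    make_feature("integrase", kind = "tRNA", id = "e"),  # wrong kind
    make_feature("polymerase", gene = "phageX", id = "f"))  # gene not searched

  sel <- select_viral_features(feats, mask_policy())
  expect_equal(sel$feature_id, c("a", "c", "d"))
  expect_equal(sel$matched_keyword, c("phage", "phage", "viral"))
  # order preserved, input untouched
  expect_equal(nrow(feats), 6L)
})

test_that("enlarging the keyword list never shrinks the selection", {
  set.seed(42)
  words <- c("phage", "viral", "integrase", "holin", "polymerase",
             "ribosomal", "hypothetical", "capsid", "transposase")
  for (rep in 1:20) {
    feats <- do.call(rbind, lapply(1:15, function(i) {
      make_feature(paste(sample(words, 3), collapse = " "),
                   id = sprintf("f%02d", i))
    }))
    small <- mask_policy(keywords = c("phage", "viral"))
    big <- mask_policy(keywords = c("phage", "viral", "integrase", "holin"))
    s1 <- select_viral_features(feats, small)$feature_id
    s2 <- select_viral_features(feats, big)$feature_id
    expect_true(all(s1 %in% s2))
  }
})

mask_iv <- function(seq_id, start, end) {
  data.frame(seq_id = seq_id, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("mask_record replaces exactly the interval union with Ns", {
  r <- list(id = "s1", seq = "ACGTACGT")
  out <- mask_record(r, mask_iv("s1", 3L, 5L))
  expect_equal(out$seq, "ACNNNCGT")
  expect_equal(attr(out, "masked_bp"), 3L)

  # empty interval list is the identity
  same <- mask_record(r, mask_iv(character(0), integer(0), integer(0)))
  expect_equal(same$seq, r$seq)

  # overlapping intervals are masked once (union semantics)
  r2 <- list(id = "s1", seq = "AAAAAAAAAA")
  out2 <- mask_record(r2, mask_iv(c("s1", "s1"), c(2L, 4L), c(5L, 8L)))
  expected_pos <- position_set_union(c(2L, 4L), c(5L, 8L))
  chars <- strsplit(out2$seq, "")[[1]]
  expect_equal(which(chars == "N"), expected_pos)
  expect_equal(attr(out2, "masked_bp"), length(expected_pos))

  # length always preserved; idempotent; pre-existing Ns not recounted
  r3 <- list(id = "s1", seq = "ACGTNNGTAC")
  out3 <- mask_record(r3, mask_iv("s1", 4L, 7L))
  expect_equal(nchar(out3$seq), nchar(r3$seq))
  expect_equal(attr(out3, "masked_bp"), 2L)  # positions 5,6 were already N
  again <- mask_record(out3, mask_iv("s1", 4L, 7L))
  expect_equal(again$seq, out3$seq)
  expect_equal(attr(again, "masked_bp"), 0L)

  expect_error(mask_record(r, mask_iv("s1", 5L, 99L)), "out of bounds")
  expect_error(mask_record(r, mask_iv("other", 1L, 2L)), "other")
})

write_genome_with_phage <- function(id, len, phage_start, phage_end,
                                    extra = NULL) {
  set.seed(sum(utf8ToInt(id)))
  records <- data.frame(id = id, description = "synthetic host",
                        seq = rand_dna(len), stringsAsFactors = FALSE)
  features <- make_feature("phage integrase", start = phage_start,
                           end = phage_end, seq_id = id,
                           id = paste0(id, "_P1"))
  if (!is.null(extra)) features <- rbind(features, extra)
  path <- tempfile(fileext = ".gbk")
  write_genbank(records, features, path)
  list(path = path, records = records, features = features)
}

test_that("build_background masks selected features and logs them", {
  g <- write_genome_with_phage("hostA", 5000L, 1001L, 1900L)
  bg <- build_background(g$path)
  expect_s3_class(bg, "BackgroundGenome")
  expect_equal(bg$total_bp, 5000L)
  expect_equal(bg$masked_bp, 900L)
  expect_equal(nchar(bg$records$seq), 5000L)  # length preserved
  chars <- strsplit(bg$records$seq, "")[[1]]
  expect_equal(which(chars == "N"), 1001:1900)  # completeness + exclusivity

  # masking disabled: pass-through
  bg0 <- build_background(g$path, mask_policy(masking_enabled = FALSE))
  expect_equal(bg0$masked_bp, 0L)
  expect_equal(bg0$records$seq, toupper(g$records$seq))
  expect_equal(nrow(bg0$mask_log), 0L)
})

test_that("masked_bp across genomes equals the position-set union", {
  extra <- rbind(
    make_feature("phage holin", start = 1600L, end = 2400L,
                 seq_id = "hostB", id = "hostB_P2"))
  g1 <- write_genome_with_phage("hostB", 4000L, 1001L, 2000L, extra = extra)
  g2 <- write_genome_with_phage("hostC", 3000L, 501L, 700L)
  bg <- build_background(c(g1$path, g2$path))
  oracle <- length(position_set_union(c(1001L, 1600L), c(2000L, 2400L))) +
    length(position_set_union(501L, 700L))
  expect_equal(bg$masked_bp, oracle)
  expect_equal(nrow(bg$records), 2L)
})

test_that("duplicate record ids across genome files are rejected", {
  g1 <- write_genome_with_phage("dupX", 2000L, 101L, 300L)
  expect_error(build_background(c(g1$path, g1$path)), "dupX")
})

test_that("background FASTA round-trips ids and sequences", {
  g <- write_genome_with_phage("hostD", 3000L, 501L, 1400L)
  bg <- build_background(g$path)
  fa <- tempfile(fileext = ".fasta")
  write_background_fasta(bg, fa)
  back <- background_from_fasta(fa)
  expect_equal(back$records$id, bg$records$id)
  expect_equal(back$records$seq, bg$records$seq)
})

test_that("mask log BED output is 0-based half-open", {
  g <- write_genome_with_phage("hostE", 2000L, 251L, 750L)
  bg <- build_background(g$path)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_mask_bed(bg, bed, tsv)
  b <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(b$V1, "hostE")
  expect_equal(b$V2, 250L)   # start - 1
  expect_equal(b$V3, 750L)   # end unchanged
  expect_equal(b$V3 - b$V2, bg$masked_bp)
  side <- utils::read.table(tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(side$matched_keyword, "phage")
})
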