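small_cfg <- function(n_pairs = 400L, ...) {
  sim_config(host_length = 40000L, prophage_length = 8000L,
             free_phage_length = 10000L, prophage_insert_pos = 20001L,
             n_pairs = n_pairs, seed = 9L, ...)
}

test_that("simulation is deterministic in the seed", {
  cfg <- small_cfg()
  g1 <- simulate_genomes(cfg)
  g2 <- simulate_genomes(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_reads(g1, cfg)
  s2 <- simulate_reads(g2, cfg)
  expect_identical(s1, s2)
  # and file outputs are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in c("host.gbk", "phage.fasta", "reads_R1.fastq", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the prophage replaces a host window, preserving host length", {
  cfg <- small_cfg()
  g <- simulate_genomes(cfg)
  expect_equal(nchar(g$host$records$seq), cfg$host_length)
  expect_equal(g$prophage_end - g$prophage_start + 1L, cfg$prophage_length)
  expect_equal(nchar(g$phage$seq), cfg$free_phage_length)
})

test_that("prophage annotations are selected by the default policy and masked_bp matches the position-set union", {
  cfg <- small_cfg()
  g <- simulate_genomes(cfg)
  pro <- g$host$features[g$host$features$start >= g$prophage_start, ]
  sel <- select_viral_features(g$host$features, mask_policy())
  expect_setequal(sel$feature_id, unique(pro$feature_id))

  dir <- tempfile()
  fx <- simulate_fixture(cfg, dir)
  bg <- build_background(fx$paths[["host"]])
  oracle <- length(position_set_union(sel$start, sel$end))
  expect_equal(bg$masked_bp, oracle)
  # inter-feature gaps are short: no unmasked prophage window can hold most
  # of a read
  merged <- sel[order(sel$start), ]
  gaps <- merged$start[-1] - merged$end[-nrow(merged)] - 1L
  expect_true(all(gaps < cfg$read_length * 0.9))
})

test_that("error-free reads are exact substrings of their source", {
  cfg <- small_cfg(error_rate = 0)
  g <- simulate_genomes(cfg)
  s <- simulate_reads(g, cfg)
  pick <- sample(nrow(s$reads), 60)
  host <- g$host$records$seq
  phage <- g$phage$seq
  for (i in pick) {
    tr <- s$truth[i, ]
    src <- if (tr$origin == "free_phage") phage else host
    window <- substr(src, tr$source_start,
                     tr$source_start + cfg$read_length - 1L)
    expected <- if (tr$source_strand == "+") window else revcomp(window)
    expect_equal(s$reads$seq[i], expected)
  }
})

test_that("origin labels respect the configured fractions and regions", {
  cfg <- small_cfg(n_pairs = 2000L)
  g <- simulate_genomes(cfg)
  s <- simulate_reads(g, cfg)
  counts <- table(s$truth$origin[s$truth$read_id %in%
                                   paste0(pair_ids <- sprintf("sim_%06d", 1:2000), "/1")])
  # binomial 99% bounds around 0.2 * 2000 and 0.1 * 2000
  bounds <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
  expect_true(counts[["free_phage"]] >= bounds(2000, 0.2)[1] &&
                counts[["free_phage"]] <= bounds(2000, 0.2)[2])
  expect_true(counts[["prophage"]] >= bounds(2000, 0.1)[1] &&
                counts[["prophage"]] <= bounds(2000, 0.1)[2])

  # host inserts never overlap the prophage window; prophage inserts stay
  # inside it
  host_rows <- s$truth$origin == "host"
  expect_true(all(s$truth$source_start[host_rows] +
                    cfg$read_length - 1L < g$prophage_start |
                    s$truth$source_start[host_rows] > g$prophage_end))
  pro_rows <- s$truth$origin == "prophage"
  expect_true(all(s$truth$source_start[pro_rows] >= g$prophage_start &
                    s$truth$source_start[pro_rows] +
                      cfg$read_length - 1L <= g$prophage_end))
})

test_that("score_run reports rates per origin and validates ids", {
  truth <- data.frame(read_id = sprintf("r%02d/1", 1:9),
                      origin = rep(c("host", "prophage", "free_phage"),
                                   each = 3),
                      source_start = 1L, source_strand = "+",
                      stringsAsFactors = FALSE)
  all_in <- score_run(truth, truth$read_id)
  expect_equal(all_in$host_removal_rate, 0)
  expect_equal(all_in$phage_retention_rate, 1)
  expect_equal(all_in$prophage_retention_rate, 1)
  none <- score_run(truth, character(0))
  expect_equal(none$host_removal_rate, 1)
  expect_equal(none$phage_retention_rate, 0)
  expect_error(score_run(truth, "ghost/1"), "ghost/1")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(phage_read_fraction = 0.8,
                          prophage_read_fraction = 0.3), "sum")
  expect_error(sim_config(host_length = 10000L, prophage_length = 8000L,
                          prophage_insert_pos = 5000L), "out of range")
  expect_warning(sim_config(read_length = 400L), "overlap")
})
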