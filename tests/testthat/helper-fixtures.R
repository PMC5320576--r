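# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing binary ships with the package.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Wrap plain sequences as a BackgroundGenome through the public FASTA route.
bg_from_seqs <- function(seqs, ids = sprintf("bg%02d", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  background_from_fasta(path)
}

# Reads sampled uniformly from a source sequence at a given fold coverage,
# random strand, i.i.d. substitution errors.
sample_reads <- function(src, coverage, read_len = 150L, error_rate = 0) {
  n <- max(1L, as.integer(nchar(src) * coverage / read_len))
  st <- sample.int(nchar(src) - read_len + 1L, n, replace = TRUE)
  rd <- substring(src, st, st + read_len - 1L)
  flip <- stats::runif(n) < 0.5
  rd[flip] <- revcomp(rd[flip])
  add_subs(rd, error_rate)
}

add_subs <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  for (i in which(nerr > 0L)) {
    r <- charToRaw(reads[i])
    for (p in sample.int(lens[i], nerr[i])) {
      alt <- setdiff(c("A", "C", "G", "T"), rawToChar(r[p]))
      r[p] <- charToRaw(sample(alt, 1L))
    }
    reads[i] <- rawToChar(r)
  }
  reads
}

# Place a fixed number of substitutions at distinct positions.
place_mismatches <- function(seq, n_mm) {
  r <- charToRaw(seq)
  pos <- sample.int(nchar(seq), n_mm)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), rawToChar(r[p]))
    r[p] <- charToRaw(sample(alt, 1L))
  }
  rawToChar(r)
}

# Fraction of `src` covered by exact occurrences of the contigs (either
# orientation) — substring-containment coverage.
containment_coverage <- function(contigs, src) {
  if (!nrow(contigs)) return(0)
  cov <- logical(nchar(src))
  for (i in seq_len(nrow(contigs))) {
    for (q in unique(c(contigs$seq[i], revcomp(contigs$seq[i])))) {
      m <- gregexpr(q, src, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        for (s in m) cov[s:(s + nchar(q) - 1L)] <- TRUE
      }
    }
  }
  mean(cov)
}

# A small hand-written GenBank record exercising join(), complement() and
# multi-line qualifiers; sequence length 120.
tiny_genbank_text <- function() {
  seq <- paste0("atgcatgcat", "gggtttcccA", "ACGTACGTAA", "tttggcatgc",
                "atcgatcgat", "cgatcgatta", "ggccggccgg", "ttaattaatt",
                "acgtacgtac", "gtacgtacgt", "aaaaaccccc", "gggggttttt")
  c("LOCUS       tinyrec01        120 bp    DNA     linear   UNA 01-JAN-2026",
    "DEFINITION  tiny synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..39",
    "                     /locus_tag=\"T_001\"",
    "                     /product=\"phage tail fiber",
    "                     protein\"",
    "     CDS             complement(50..79)",
    "                     /locus_tag=\"T_002\"",
    "                     /product=\"hypothetical protein\"",
    "                     /note=\"unremarkable\"",
    "     CDS             join(85..96,101..112)",
    "                     /locus_tag=\"T_003\"",
    "                     /product=\"Bacteriophage P2 integrase\"",
    "ORIGIN",
    sprintf("%9d %s %s %s %s %s %s", 1, substr(seq, 1, 10),
            substr(seq, 11, 20), substr(seq, 21, 30), substr(seq, 31, 40),
            substr(seq, 41, 50), substr(seq, 51, 60)),
    sprintf("%9d %s %s %s %s %s %s", 61, substr(seq, 61, 70),
            substr(seq, 71, 80), substr(seq, 81, 90), substr(seq, 91, 100),
            substr(seq, 101, 110), substr(seq, 111, 120)),
    "//")
}

write_tiny_genbank <- function(path = tempfile(fileext = ".gbk")) {
  writeLines(tiny_genbank_text(), path)
  path
}

# Paired reads data.frame in the shape read_fastq() produces.
paired_reads_df <- function(n_pairs, read_len = 30L) {
  base <- sprintf("p%04d", seq_len(n_pairs))
  ids <- as.vector(rbind(paste0(base, "/1"), paste0(base, "/2")))
  data.frame(id = ids,
             seq = vapply(seq_along(ids), function(i) rand_dna(read_len),
                          character(1)),
             qual = strrep("I", read_len),
             mate = rep(c(1L, 2L), n_pairs),
             stringsAsFactors = FALSE)
}

verdicts_df <- function(ids, mapped) {
  data.frame(read_id = ids, mapped = mapped, target = NA_character_,
             start = NA_integer_, strand = NA_character_,
             identity = NA_real_, aligned_fraction = NA_real_,
             clip_left = NA_integer_, aligned_len = NA_integer_,
             mismatches = NA_integer_, stringsAsFactors = FALSE)
}
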