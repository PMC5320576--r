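# Independent oracles. These deliberately take different routes from the
# implementation they check: the mapping oracle scans every offset of every
# record on both strands via Biostrings::matchPattern (C code, no seeding),
# the N50 oracle walks sorted prefix sums in a plain loop, and the masking
# oracle materialises position sets.

# Brute-force mapped/unmapped decision under the mapper's thresholds:
# all-offsets, both-strands, ungapped, with clipped placements at record
# edges handled explicitly.
brute_force_mapped <- function(seq, bg, cfg) {
  L <- nchar(seq)
  mm_max <- floor(L * (1 - cfg$min_identity) + 1e-9)
  rawN <- charToRaw("N")
  for (ri in seq_len(nrow(bg$records))) {
    subj <- Biostrings::DNAString(bg$records$seq[ri])
    reclen <- length(subj)
    braw <- charToRaw(bg$records$seq[ri])
    strands <- c(seq, revcomp(seq))
    if (!cfg$both_strands) strands <- strands[1]
    for (s in strands) {
      if (L <= reclen &&
          length(Biostrings::matchPattern(s, subj, max.mismatch = mm_max,
                                          with.indels = FALSE))) {
        return(TRUE)
      }
      # clipped placements hanging off either record end
      sraw <- charToRaw(s)
      offs <- unique(c(seq.int(2L - L, 0L),
                       seq.int(reclen - L + 2L, reclen)))
      for (p in offs) {
        astart <- max(1L, p)
        aend <- min(reclen, p + L - 1L)
        alen <- aend - astart + 1L
        if (alen < 1L || alen / L < cfg$min_aligned_fraction) next
        ra <- sraw[(astart - p + 1L):(aend - p + 1L)]
        bb <- braw[astart:aend]
        mm <- sum(ra != bb | ra == rawN | bb == rawN)
        if ((alen - mm) / alen >= cfg$min_identity) return(TRUE)
      }
    }
  }
  FALSE
}

# N50 by definition: shortest contig in the smallest descending-sorted
# prefix whose cumulative length reaches half the total.
brute_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  if (!length(lens)) return(0L)
  total <- sum(as.numeric(lens))
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= total / 2) return(l)
  }
  lens[length(lens)]
}

# Union of 1-based inclusive intervals as an explicit position set.
position_set_union <- function(start, end) {
  if (!length(start)) return(integer(0))
  sort(unique(unlist(mapply(seq.int, start, end, SIMPLIFY = FALSE))))
}
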