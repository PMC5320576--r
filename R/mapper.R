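# Stage 2 mapping: mismatch-tolerant ungapped seed-and-extend against the
# masked background.
#
# The index hashes every k-mer of the background's forward strand (k-mers
# containing N are excluded, which is how masking makes regions invisible).
# A read is mapped when some ungapped placement — found by exact seed hits of
# the read or its reverse complement — reaches both the identity and the
# aligned-fraction thresholds. N counts as a mismatch on either side during
# extension. Placements hanging off a record end are clipped, which lowers
# the aligned fraction. Everything is deterministic: ties between equally
# identical placements break on target id, then start, then forward strand.

#' Mapper configuration
#'
#' Defaults are deliberately tolerant of mismatches — roughly the level of
#' variation expected between the sequenced strain and the reference used as
#' background: 90% identity over at least 80% of the read.
#'
#' @param seed_length Exact-match seed length k (integer, >= 8).
#' @param min_identity Minimum fraction of matching bases over the aligned
#'   region, in (0, 1].
#' @param min_aligned_fraction Minimum fraction of the read covered by the
#'   alignment, in (0, 1]. End clipping reduces it.
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return A `mapper_config` object.
#' @export
mapper_config <- function(seed_length = 15L, min_identity = 0.90,
                          min_aligned_fraction = 0.80, both_strands = TRUE) {
  seed_length <- as.integer(seed_length)
  if (is.na(seed_length) || seed_length < 8L) {
    abort("seed_length must be an integer >= 8")
  }
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 1) {
    abort("min_identity must be in (0, 1]")
  }
  if (!is.numeric(min_aligned_fraction) || min_aligned_fraction <= 0 ||
      min_aligned_fraction > 1) {
    abort("min_aligned_fraction must be in (0, 1]")
  }
  structure(list(seed_length = seed_length,
                 min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 both_strands = isTRUE(both_strands)),
            class = "mapper_config")
}

#' Build the seed index over a background genome
#'
#' Hashes every length-k substring of every background record (forward
#' strand) to its positions. k-mers containing N are excluded, so fully
#' masked regions contribute nothing.
#'
#' @param bg A `BackgroundGenome`.
#' @param k Seed length (defaults to 15).
#' @return A `seed_index` object (hash environment plus record metadata).
#' @export
index_background <- function(bg, k = 15L) {
  stopifnot(inherits(bg, "BackgroundGenome"))
  k <- as.integer(k)
  seqs <- toupper(bg$records$seq)
  lens <- nchar(seqs)
  if (all(lens < k)) {
    abort("seed length ", k, " exceeds every background record length")
  }
  off <- c(0L, cumsum(lens))
  all_km <- character(0)
  all_gp <- integer(0)
  for (i in seq_along(seqs)) {
    km <- kmers_of(seqs[i], k)
    if (!length(km)) next
    ok <- !grepl("N", km, fixed = TRUE)
    if (!any(ok)) next
    all_km <- c(all_km, km[ok])
    all_gp <- c(all_gp, off[i] + which(ok))
  }
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(16L, length(all_km)))
  if (length(all_km)) {
    sp <- split(all_gp, all_km)
    list2env(sp, envir = env)
  }
  structure(list(env = env, k = k, n_kmers = length(all_km),
                 ids = bg$records$id, lens = lens, off = off,
                 raws = lapply(seqs, charToRaw)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("Seed index: k =", x$k, "over", length(x$ids), "record(s);",
      format(x$n_kmers, big.mark = ","), "positional k-mers\n")
  invisible(x)
}

unmapped_verdict <- function(read_id) {
  data.frame(read_id = read_id, mapped = FALSE, target = NA_character_,
             start = NA_integer_, strand = NA_character_,
             identity = NA_real_, aligned_fraction = NA_real_,
             clip_left = NA_integer_, aligned_len = NA_integer_,
             mismatches = NA_integer_, stringsAsFactors = FALSE)
}

# Evaluate one candidate placement of strand-oriented read `sraw` starting at
# local position p of record r; returns NULL if it cannot reach the
# aligned-fraction threshold.
.extend_placement <- function(sraw, L, r, p, index, min_af) {
  reclen <- index$lens[r]
  astart <- max(1L, p)
  aend <- min(reclen, p + L - 1L)
  if (aend < astart) return(NULL)
  alen <- aend - astart + 1L
  af <- alen / L
  if (af < min_af) return(NULL)
  ra <- sraw[(astart - p + 1L):(aend - p + 1L)]
  bb <- index$raws[[r]][astart:aend]
  mm <- sum(ra != bb | ra == RAW_N | bb == RAW_N)
  list(r = r, astart = astart, alen = alen, af = af,
       mm = mm, identity = (alen - mm) / alen,
       clip_left = astart - p)
}

.map_one <- function(read_id, fwd, rev, index, cfg) {
  L <- nchar(fwd)
  k <- index$k
  if (L < k) return(unmapped_verdict(read_id))
  strands <- if (cfg$both_strands) c("+", "-") else "+"
  best <- NULL       # best qualifying placement
  best_any <- NULL   # best placement overall (reported when unmapped)
  for (strand in strands) {
    s <- if (strand == "+") fwd else rev
    n <- L - k + 1L
    seeds <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    hits <- mget(seeds, envir = index$env, ifnotfound = list(NULL))
    hl <- lengths(hits)
    if (!sum(hl)) next
    gpos <- unlist(hits, use.names = FALSE)
    soff <- rep.int(seq_len(n), hl)
    rec <- findInterval(gpos, index$off[-length(index$off)] + 1L)
    ls <- gpos - index$off[rec] - soff + 1L
    key <- rec * 1e9 + ls
    keep <- which(!duplicated(key))
    # deterministic candidate order: record, then start
    keep <- keep[order(rec[keep], ls[keep])]
    sraw <- charToRaw(s)
    for (j in keep) {
      pl <- .extend_placement(sraw, L, rec[j], ls[j], index,
                              cfg$min_aligned_fraction)
      if (is.null(pl)) next
      pl$strand <- strand
      if (is.null(best_any) || pl$identity > best_any$identity) {
        best_any <- pl
      }
      if (pl$identity >= cfg$min_identity) {
        if (is.null(best) || .placement_beats(pl, best, index$ids)) {
          best <- pl
        }
      }
    }
  }
  hit <- if (!is.null(best)) best else best_any
  if (is.null(hit)) return(unmapped_verdict(read_id))
  data.frame(read_id = read_id, mapped = !is.null(best),
             target = index$ids[hit$r], start = hit$astart,
             strand = hit$strand, identity = hit$identity,
             aligned_fraction = hit$af, clip_left = hit$clip_left,
             aligned_len = hit$alen, mismatches = hit$mm,
             stringsAsFactors = FALSE)
}

.placement_beats <- function(a, b, ids) {
  if (a$identity != b$identity) return(a$identity > b$identity)
  if (ids[a$r] != ids[b$r]) return(ids[a$r] < ids[b$r])
  if (a$astart != b$astart) return(a$astart < b$astart)
  a$strand == "+" && b$strand == "-"
}

#' Map one read against the background
#'
#' Finds exact seed hits at every read offset (and in the reverse complement
#' when `both_strands`), extends each candidate placement without gaps
#' across the full read, and reports the best placement by identity. A read
#' shorter than the seed length yields an unmapped verdict with a warning,
#' never an error.
#'
#' @param read Either a nucleotide string or a list/one-row data.frame with
#'   `id` and `seq`.
#' @param index A `seed_index` from [index_background()].
#' @param cfg A [mapper_config()].
#' @return One-row data.frame verdict: `read_id`, `mapped`, `target`,
#'   `start`, `strand`, `identity`, `aligned_fraction`, `clip_left`,
#'   `aligned_len`, `mismatches`.
#' @export
map_read <- function(read, index, cfg = mapper_config()) {
  if (is.character(read) && length(read) == 1L) {
    read <- list(id = "read", seq = read)
  }
  seq <- toupper(read$seq)
  if (nchar(seq) < index$k) {
    warning("read ", read$id, " is shorter than the seed length (",
            index$k, "); reported unmapped", call. = FALSE)
    return(unmapped_verdict(read$id))
  }
  .map_one(read$id, seq, revcomp(seq), index, cfg)
}

#' Map a set of reads against the background
#'
#' Vectorised driver over [map_read()]; reverse complements are computed in
#' one batch. Reads shorter than the seed length produce unmapped verdicts
#' and a single summary warning.
#'
#' @param reads data.frame with columns `id` and `seq`.
#' @param index A `seed_index`.
#' @param cfg A [mapper_config()].
#' @return data.frame of verdicts, one row per read, in input order.
#' @export
map_reads <- function(reads, index, cfg = mapper_config()) {
  n <- nrow(reads)
  seqs <- toupper(reads$seq)
  revs <- revcomp(seqs)
  out <- vector("list", n)
  short <- 0L
  for (i in seq_len(n)) {
    if (nchar(seqs[i]) < index$k) {
      short <- short + 1L
      out[[i]] <- unmapped_verdict(reads$id[i])
    } else {
      out[[i]] <- .map_one(reads$id[i], seqs[i], revs[i], index, cfg)
    }
  }
  if (short > 0L) {
    warning(short, " read(s) shorter than the seed length (", index$k,
            ") reported unmapped", call. = FALSE)
  }
  do.call(rbind, out)
}
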