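# Stage 3: de Bruijn assembly of the retained reads, plus contig statistics.
#
# The graph is built over canonical k-mers (k odd, so no k-mer equals its own
# reverse complement) but materialised in both orientations, which keeps the
# traversal a plain digraph: node u has an edge to v when the (k-1)-suffix of
# u equals the (k-1)-prefix of v. Maximal unbranched paths are emitted as
# contigs; each contig appears once after collapsing reverse-complement
# twins. Two cleaning steps precede the final traversal:
#   * a k-mer coverage cutoff (default: auto from the weighted median
#     multiplicity) that removes the sequencing-error haze — interior read
#     errors create low-coverage bubbles that would otherwise shatter the
#     unitigs;
#   * tip clipping: dead-end paths of singleton k-mers shorter than 2k.

.build_graph <- function(kmers, counts, k) {
  nodes <- c(kmers, revcomp(kmers))
  cnt <- c(counts, counts)
  o <- order(nodes)
  nodes <- nodes[o]
  cnt <- cnt[o]
  pref <- substr(nodes, 1L, k - 1L)
  suf <- substr(nodes, 2L, k)
  U <- unique(c(pref, suf))
  pu <- match(pref, U)
  su <- match(suf, U)
  nP <- tabulate(pu, length(U))
  nS <- tabulate(su, length(U))
  outdeg <- nP[su]
  indeg <- nS[pu]
  firstP <- integer(length(U))
  firstP[pu] <- seq_along(nodes)
  firstS <- integer(length(U))
  firstS[su] <- seq_along(nodes)
  succ <- ifelse(outdeg == 1L, firstP[su], NA_integer_)
  pred <- ifelse(indeg == 1L, firstS[pu], NA_integer_)
  list(nodes = nodes, cnt = cnt, outdeg = outdeg, indeg = indeg,
       succ = succ, pred = pred)
}

# Maximal unbranched paths (lists of node indices), deterministic order.
.unitig_paths <- function(g) {
  n <- length(g$nodes)
  cont <- g$indeg == 1L & !is.na(g$pred)
  cont[cont] <- g$outdeg[g$pred[cont]] == 1L
  is_start <- !cont
  visited <- logical(n)
  buf <- integer(n)
  paths <- vector("list", n)
  np <- 0L
  for (v in seq_len(n)) {
    if (!is_start[v] || visited[v]) next
    i <- 1L
    buf[1L] <- v
    visited[v] <- TRUE
    cur <- v
    repeat {
      nx <- if (g$outdeg[cur] == 1L) g$succ[cur] else NA_integer_
      if (is.na(nx) || is_start[nx] || visited[nx]) break
      i <- i + 1L
      buf[i] <- nx
      visited[nx] <- TRUE
      cur <- nx
    }
    np <- np + 1L
    paths[[np]] <- buf[seq_len(i)]
  }
  # isolated cycles: every node is a continuation, none was a start
  for (v in seq_len(n)) {
    if (visited[v]) next
    i <- 1L
    buf[1L] <- v
    visited[v] <- TRUE
    cur <- v
    repeat {
      nx <- g$succ[cur]
      if (is.na(nx) || visited[nx]) break
      i <- i + 1L
      buf[i] <- nx
      visited[nx] <- TRUE
      cur <- nx
    }
    np <- np + 1L
    paths[[np]] <- buf[seq_len(i)]
  }
  paths[seq_len(np)]
}

.path_seq <- function(idx, nodes, k) {
  if (length(idx) == 1L) return(nodes[idx])
  paste0(nodes[idx[1L]],
         paste(substr(nodes[idx[-1L]], k, k), collapse = ""))
}

# Weighted median of k-mer multiplicities (each distinct k-mer weighted by
# its own count): robust centre of the true-coverage mode.
.coverage_centre <- function(counts) {
  o <- order(counts)
  cs <- cumsum(as.numeric(counts[o]))
  counts[o][which(cs >= cs[length(cs)] / 2)[1]]
}

#' Assemble reads into contigs
#'
#' Builds a de Bruijn graph over canonical read k-mers (both strands),
#' removes low-coverage k-mers below `cov_cutoff`, clips coverage-1 dead-end
#' tips shorter than `2k`, compresses unbranched paths, and emits maximal
#' unbranched paths of length at least `min_contig_len` as contigs, in
#' deterministic order (length descending, then sequence). Each contig is
#' reported in its canonical orientation (the lexicographically smaller of
#' the two strands).
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `seq` column.
#' @param k Odd assembly k-mer size (default 31); reads shorter than `k` are
#'   dropped with a warning.
#' @param min_contig_len Minimum emitted contig length (default 1000; use a
#'   smaller value to keep short unitigs).
#' @param cov_cutoff `"auto"` or a non-negative integer c (k-mers seen
#'   <= c times are discarded before traversal; `0` keeps everything).
#'   In auto mode the cleaning is two-staged and coverage-aware: when the
#'   weighted-median k-mer multiplicity indicates real coverage (>= 4),
#'   singleton k-mers (the sequencing-error haze) are dropped; when it is
#'   high enough to separate signal from noise (>= 8), short unitigs whose
#'   mean k-mer coverage falls below a quarter of the median — the error
#'   bubbles that survive the haze filter — are removed as well, and the
#'   graph is rebuilt so the flanking unitigs merge back together. Judging
#'   coverage on compressed unitigs rather than individual k-mers keeps
#'   Poisson dips in true coverage from breaking contigs.
#' @param prune_tips Clip coverage-1 dead ends shorter than 2k.
#' @return data.frame of contigs: `id`, `seq`, `length`, `read_support`
#'   (estimated number of contributing reads, >= 1).
#' @export
assemble <- function(reads, k = 31L, min_contig_len = 1000L,
                     cov_cutoff = "auto", prune_tips = TRUE) {
  if (is.data.frame(reads)) reads <- reads$seq
  k <- as.integer(k)
  if (k %% 2L == 0L) abort("assembly k-mer size must be odd")
  empty <- data.frame(id = character(0), seq = character(0),
                      length = integer(0), read_support = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  seqs <- toupper(reads)
  long <- nchar(seqs) >= k
  if (!any(long)) {
    warning("all reads are shorter than k = ", k,
            "; nothing to assemble", call. = FALSE)
    return(empty)
  }
  seqs <- seqs[long]
  mean_rl <- mean(nchar(seqs))

  km <- unlist(lapply(seqs, kmers_of, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(empty)
  rc <- revcomp(km)
  canon <- ifelse(km <= rc, km, rc)
  s <- sort(canon)
  r <- rle(s)
  dk <- r$values
  cnt <- r$lengths

  auto <- identical(cov_cutoff, "auto")
  centre <- .coverage_centre(cnt)
  cutoff <- if (auto) {
    if (centre >= 4L) 1L else 0L  # drop the singleton error haze only
  } else {
    as.integer(cov_cutoff)
  }
  keep <- cnt > cutoff
  dk <- dk[keep]
  cnt <- cnt[keep]
  if (!length(dk)) return(empty)

  # iterative cleaning on compressed unitigs: tips, and (in auto mode at
  # informative coverage) short low-mean-coverage paths, i.e. error bubbles
  g <- .build_graph(dk, cnt, k)
  clean_bubbles <- auto && centre >= 8L
  for (round in 1:3) {
    paths <- .unitig_paths(g)
    drop <- vapply(paths, function(idx) {
      first <- idx[1L]
      last <- idx[length(idx)]
      dangle_l <- g$indeg[first] == 0L
      dangle_r <- g$outdeg[last] == 0L
      bp <- k + length(idx) - 1L
      if (prune_tips && xor(dangle_l, dangle_r) && bp < 2L * k &&
          max(g$cnt[idx]) == 1L) {
        return(TRUE)
      }
      clean_bubbles && bp < 4L * k && !(dangle_l && dangle_r) &&
        mean(g$cnt[idx]) <= centre / 4
    }, logical(1))
    if (!any(drop) || all(drop)) break
    drop_nodes <- g$nodes[unlist(paths[drop], use.names = FALSE)]
    drop_rc <- revcomp(drop_nodes)
    drop_canon <- unique(ifelse(drop_nodes <= drop_rc,
                                drop_nodes, drop_rc))
    keep2 <- !(dk %in% drop_canon)
    dk <- dk[keep2]
    cnt <- cnt[keep2]
    if (!length(dk)) return(empty)
    g <- .build_graph(dk, cnt, k)
  }
  paths <- .unitig_paths(g)
  cseq <- vapply(paths, .path_seq, character(1), nodes = g$nodes, k = k)
  csum <- vapply(paths, function(idx) sum(as.numeric(g$cnt[idx])),
                 numeric(1))
  crc <- revcomp(cseq)
  ccan <- ifelse(cseq <= crc, cseq, crc)
  d <- !duplicated(ccan)
  ccan <- ccan[d]
  csum <- csum[d]
  lens <- nchar(ccan)
  ok <- lens >= min_contig_len
  ccan <- ccan[ok]
  csum <- csum[ok]
  lens <- lens[ok]
  o <- order(-lens, ccan)
  ccan <- ccan[o]
  csum <- csum[o]
  lens <- lens[o]
  support <- pmax(1L, as.integer(round(csum / max(1, mean_rl - k + 1))))
  data.frame(id = sprintf("contig_%05d", seq_along(ccan)),
             seq = ccan, length = lens, read_support = support,
             stringsAsFactors = FALSE)
}

#' Import contigs from FASTA
#'
#' Accepts contigs produced by an external assembler. `read_support` is
#' unknown and recorded as 1.
#'
#' @param path Contig FASTA (gzip accepted).
#' @return Contig data.frame as from [assemble()].
#' @export
import_contigs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) abort("no contigs in FASTA file ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort("duplicate contig id in ", path, ": ",
          ids[duplicated(ids)][1])
  }
  data.frame(id = ids, seq = toupper(as.character(ss)),
             length = Biostrings::width(ss),
             read_support = 1L, stringsAsFactors = FALSE)
}

#' Write contigs as FASTA
#'
#' @param contigs Contig data.frame.
#' @param path Output path (80-column wrapped).
#' @return Invisibly, `path`.
#' @export
write_contigs <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$seq)
  names(ss) <- contigs$id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Contig-set summary statistics
#'
#' Restricts to contigs of length at least `min_report_len` and reports
#' their count, maximum length, N50 and total bp. N50 follows the sorted
#' prefix-sum convention: sort lengths descending; N50 is the length of the
#' contig at which the cumulative length first reaches half the total.
#' An empty reported set yields all zeros.
#'
#' @param contigs Contig data.frame, or simply a numeric vector of contig
#'   lengths.
#' @param min_report_len Reporting threshold (default 1000 bp).
#' @return An `AssemblyStats` object: `min_report_len`, `n_contigs`,
#'   `max_length`, `n50`, `total_bp`.
#' @export
compute_stats <- function(contigs, min_report_len = 1000L) {
  lens <- if (is.numeric(contigs)) {
    as.integer(contigs)
  } else if (!is.null(contigs$length)) {
    contigs$length
  } else {
    nchar(contigs$seq)
  }
  lens <- sort(lens[lens >= min_report_len], decreasing = TRUE)
  if (!length(lens)) {
    stats <- list(min_report_len = as.integer(min_report_len),
                  n_contigs = 0L, max_length = 0L, n50 = 0L, total_bp = 0L)
  } else {
    total <- sum(lens)
    n50 <- lens[which(cumsum(as.numeric(lens)) >= total / 2)[1]]
    stats <- list(min_report_len = as.integer(min_report_len),
                  n_contigs = length(lens), max_length = lens[1],
                  n50 = n50, total_bp = total)
  }
  structure(stats, class = "AssemblyStats")
}

#' @export
print.AssemblyStats <- function(x, ...) {
  cat("Contigs >= ", x$min_report_len, " bp: ", x$n_contigs,
      " | max ", x$max_length, " | N50 ", x$n50,
      " | total ", format(x$total_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}
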