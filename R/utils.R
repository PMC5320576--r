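# Small shared helpers. Coordinates throughout the package are 1-based and
# inclusive on both ends (GenBank convention); BED output converts to 0-based
# half-open at the point of writing.

DNA_BASES <- c("A", "C", "G", "T")
RAW_N <- charToRaw("N")
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

abort <- function(...) stop(..., call. = FALSE)

#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of one sequence (character scalar), in order of start position.
kmers_of <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Merge 1-based inclusive intervals into a disjoint sorted set.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (!length(start)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- as.integer(start[o])
  end <- as.integer(end[o])
  ms <- start[1]
  me <- end[1]
  outs <- integer(0)
  oute <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms)
      oute <- c(oute, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

union_size <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start + 1L)
}

# Canonical pair key: strip a trailing /1 or /2 mate suffix.
pair_key <- function(ids) sub("/[12]$", "", ids)

validate_sequence_records <- function(records, where = "input") {
  if (!nrow(records)) abort("no sequence records parsed from ", where)
  if (any(!nzchar(records$id))) abort("empty sequence id in ", where)
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    abort("duplicate record id(s) in ", where, ": ",
          paste(dup, collapse = ", "))
  }
  if (any(!nzchar(records$seq))) {
    abort("empty sequence for record ",
          records$id[!nzchar(records$seq)][1], " in ", where)
  }
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
               toupper(records$seq))
  if (any(bad)) {
    abort("record ", records$id[bad][1], " in ", where,
          " contains non-IUPAC characters")
  }
  invisible(records)
}

# Open a (possibly gzipped) text file for reading; gzfile() reads plain text
# transparently as well.
read_text_lines <- function(path) {
  if (!file.exists(path)) abort("cannot read file: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
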