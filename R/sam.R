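# SAM interchange for the plug-and-play mapping stage: verdicts from the
# built-in mapper can be exported as SAM, and mapping results produced by an
# external mapper can be imported in their place. Import only needs the
# mapped/unmapped partition plus identity and aligned fraction where the
# alignment records allow them to be computed (CIGAR + NM tag), so the text
# format is parsed directly with line-number diagnostics.

#' Export mapping verdicts as SAM
#'
#' Writes a minimal valid SAM file: `@HD`/`@SQ` headers from the background,
#' one alignment line per read (flag 4 for unmapped, 16 for reverse strand),
#' soft-clipped ungapped CIGARs, and an `NM` tag with the mismatch count.
#'
#' @param verdicts Verdict data.frame from [map_reads()].
#' @param reads data.frame with `id`, `seq` and optional `qual`.
#' @param bg The `BackgroundGenome` the verdicts refer to.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(verdicts, reads, bg, path) {
  m <- match(reads$id, verdicts$read_id)
  if (anyNA(m)) abort("no verdict for read ", reads$id[is.na(m)][1])
  v <- verdicts[m, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", bg$records$id,
                      nchar(bg$records$seq)),
              "@PG\tID:phagesift\tPN:phagesift")
  qual <- if (!is.null(reads$qual)) reads$qual else rep("*", nrow(reads))
  lines <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (!isTRUE(v$mapped[i])) {
      lines[i] <- paste(reads$id[i], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                        toupper(reads$seq[i]), qual[i], sep = "\t")
      next
    }
    L <- nchar(reads$seq[i])
    lc <- v$clip_left[i]
    rc <- L - lc - v$aligned_len[i]
    cigar <- paste0(if (lc > 0L) paste0(lc, "S") else "",
                    v$aligned_len[i], "M",
                    if (rc > 0L) paste0(rc, "S") else "")
    minus <- identical(v$strand[i], "-")
    seq_out <- toupper(reads$seq[i])
    qual_out <- qual[i]
    if (minus) {
      seq_out <- revcomp(seq_out)
      if (qual_out != "*") {
        qual_out <- paste(rev(strsplit(qual_out, "", fixed = TRUE)[[1]]),
                          collapse = "")
      }
    }
    lines[i] <- paste(reads$id[i], if (minus) 16L else 0L, v$target[i],
                      v$start[i], 255L, cigar, "*", 0L, 0L,
                      seq_out, qual_out,
                      paste0("NM:i:", v$mismatches[i]), sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

cigar_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    abort("bad CIGAR: ", cigar)
  }
  parts <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", parts)),
             op = sub("^[0-9]+", "", parts), stringsAsFactors = FALSE)
}

#' Import mapping verdicts from a SAM file
#'
#' A read is mapped iff any of its alignment lines lacks the unmapped flag
#' (0x4). Identity and aligned fraction are computed from CIGAR and the `NM`
#' tag where present, otherwise recorded as `NA` (unknown). Reads present in
#' the SAM but absent from `known_ids` are dropped with a warning; malformed
#' lines raise an error naming the line number.
#'
#' @param path SAM path.
#' @param known_ids Optional character vector of expected read ids.
#' @return Verdict data.frame (one row per read).
#' @export
import_sam_verdicts <- function(path, known_ids = NULL) {
  lines <- read_text_lines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      abort("malformed SAM line ", ln, " in ", path,
            ": fewer than 11 fields")
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) {
      abort("malformed SAM line ", ln, " in ", path,
            ": non-integer FLAG or POS")
    }
    mapped <- bitwAnd(flag, 4L) == 0L
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    ident <- NA_real_
    af <- NA_real_
    alen <- NA_integer_
    nm <- NA_integer_
    if (mapped && f[6] != "*") {
      ops <- tryCatch(cigar_ops(f[6]), error = function(e) {
        abort("malformed SAM line ", ln, " in ", path, ": ",
              conditionMessage(e))
      })
      alen <- sum(ops$len[ops$op %in% c("M", "=", "X")])
      read_len <- if (f[10] != "*") {
        nchar(f[10])
      } else {
        sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
      }
      if (read_len > 0L && alen > 0L) af <- alen / read_len
      tags <- f[-(1:11)]
      nm_tag <- tags[startsWith(tags, "NM:i:")]
      if (length(nm_tag)) {
        nm <- as.integer(sub("^NM:i:", "", nm_tag[1]))
        if (!is.na(nm) && alen > 0L) ident <- (alen - nm) / alen
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = f[1], mapped = mapped,
      target = if (mapped) f[3] else NA_character_,
      start = if (mapped) pos else NA_integer_,
      strand = if (mapped) strand else NA_character_,
      identity = ident, aligned_fraction = af,
      clip_left = NA_integer_, aligned_len = alen, mismatches = nm,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) abort("no alignment lines in SAM file ", path)
  all_rows <- do.call(rbind, rows)
  if (!is.null(known_ids)) {
    unknown <- setdiff(unique(all_rows$read_id), known_ids)
    if (length(unknown)) {
      warning(length(unknown), " read(s) in SAM absent from the input set ",
              "(e.g. ", unknown[1], "); their verdicts are ignored",
              call. = FALSE)
      all_rows <- all_rows[all_rows$read_id %in% known_ids, , drop = FALSE]
      if (!nrow(all_rows)) abort("no SAM reads match the input read set")
    }
  }
  # collapse multiple alignment lines per read: mapped if ANY line is
  # mapped; report the best mapped line by identity (NA identities last)
  split_rows <- split(seq_len(nrow(all_rows)), all_rows$read_id)
  keep <- vapply(split_rows, function(idx) {
    sub <- all_rows[idx, , drop = FALSE]
    mapped_idx <- idx[sub$mapped]
    if (!length(mapped_idx)) return(idx[1])
    ids <- all_rows$identity[mapped_idx]
    if (all(is.na(ids))) mapped_idx[1] else mapped_idx[which.max(ids)]
  }, integer(1))
  # preserve first-appearance order
  keep <- keep[order(match(names(split_rows),
                           unique(all_rows$read_id)))]
  out <- all_rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
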