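# Stage 1: build the viral-masked background genome.
#
# Non-target (host/contaminant) genomes are loaded with their annotations;
# coding regions whose free-text qualifiers identify them as phage/viral in
# origin are replaced with Ns, so prophage sequence cannot attract reads
# during subtractive filtering. The masked records, concatenated across all
# input genomes, are the "background genome".

#' Masking policy for viral-annotated features
#'
#' Controls which annotated features are replaced with Ns when the
#' background genome is built. Keyword matching is case-insensitive
#' substring search, so "Bacteriophage", "prophage" and "PHAGE" all match
#' the default keyword "phage". Gene names are deliberately not searched by
#' default (too many spurious hits); add `"gene"` to `searched_qualifiers`
#' to include them.
#'
#' @param keywords Character vector of keywords; a feature is selected when
#'   any keyword occurs in any searched qualifier value.
#' @param searched_qualifiers Qualifier names whose values are searched.
#' @param masking_enabled Set `FALSE` to pass genomes through unmasked.
#' @param feature_kinds Feature kinds subject to masking (default: coding
#'   regions only). Add e.g. `"misc_feature"` to mask annotated prophage
#'   regions that are not CDSs.
#' @param mask_char Fixed to `"N"`: the ambiguity character is what makes
#'   masked positions unmappable.
#' @return A `mask_policy` object.
#' @export
mask_policy <- function(keywords = c("phage", "viral"),
                        searched_qualifiers = c("product", "note", "function"),
                        masking_enabled = TRUE,
                        feature_kinds = "CDS",
                        mask_char = "N") {
  if (!identical(toupper(mask_char), "N")) {
    abort("mask_char is fixed to 'N': masked positions must be unmappable")
  }
  if (masking_enabled && !length(keywords)) {
    abort("mask_policy needs at least one keyword when masking is enabled")
  }
  structure(list(keywords = tolower(as.character(keywords)),
                 searched_qualifiers = as.character(searched_qualifiers),
                 masking_enabled = isTRUE(masking_enabled),
                 feature_kinds = as.character(feature_kinds),
                 mask_char = "N"),
            class = "mask_policy")
}

#' @export
print.mask_policy <- function(x, ...) {
  cat("Masking policy:",
      if (x$masking_enabled) "enabled" else "DISABLED", "\n")
  cat("  keywords:  ", paste(x$keywords, collapse = ", "), "\n")
  cat("  qualifiers:", paste(x$searched_qualifiers, collapse = ", "), "\n")
  cat("  kinds:     ", paste(x$feature_kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Select features annotated as viral in origin
#'
#' Returns the subset of `features` whose kind is maskable under `policy`
#' and whose searched qualifier values contain any policy keyword as a
#' case-insensitive substring. Input order is preserved; two audit columns
#' (`matched_keyword`, `matched_text`) are appended.
#'
#' @param features Feature data.frame (see [load_annotated_genome()]).
#' @param policy A [mask_policy()].
#' @return Subset of `features` with match annotations.
#' @export
select_viral_features <- function(features, policy = mask_policy()) {
  stopifnot(inherits(policy, "mask_policy"))
  n <- nrow(features)
  matched_keyword <- rep(NA_character_, n)
  matched_text <- rep(NA_character_, n)
  if (n) {
    kind_ok <- features$kind %in% policy$feature_kinds
    for (i in which(kind_ok)) {
      quals <- features$qualifiers[[i]]
      for (qn in policy$searched_qualifiers) {
        vals <- quals[[qn]]
        if (is.null(vals)) next
        low <- tolower(vals)
        for (kw in policy$keywords) {
          hit <- grepl(kw, low, fixed = TRUE)
          if (any(hit)) {
            matched_keyword[i] <- kw
            matched_text[i] <- vals[hit][1]
            break
          }
        }
        if (!is.na(matched_keyword[i])) break
      }
    }
  }
  sel <- which(!is.na(matched_keyword))
  out <- features[sel, , drop = FALSE]
  out$matched_keyword <- matched_keyword[sel]
  out$matched_text <- matched_text[sel]
  rownames(out) <- NULL
  out
}

#' Mask intervals of a sequence record with Ns
#'
#' Every position covered by the union of `intervals` becomes `N`; all other
#' positions are untouched, and the sequence length is preserved.
#' Overlapping intervals are masked once. Masking is idempotent.
#'
#' @param record A list or one-row data.frame with `id` and `seq`.
#' @param intervals data.frame with `seq_id`, `start`, `end` (1-based
#'   inclusive), all referring to `record$id`.
#' @return The record with `seq` masked, plus attribute `masked_bp`: the
#'   number of positions newly converted to N (pre-existing Ns excluded).
#' @export
mask_record <- function(record, intervals) {
  seq <- record$seq
  len <- nchar(seq)
  if (!nrow(intervals)) {
    attr(record, "masked_bp") <- 0L
    return(record)
  }
  if (any(intervals$seq_id != record$id)) {
    abort("mask interval references sequence ",
          intervals$seq_id[intervals$seq_id != record$id][1],
          " but record is ", record$id)
  }
  if (any(intervals$start < 1L | intervals$end > len |
          intervals$start > intervals$end)) {
    abort("mask interval out of bounds for record ", record$id)
  }
  cover <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    cover[intervals$start[i]:intervals$end[i]] <- TRUE
  }
  raw <- charToRaw(seq)
  newly <- cover & raw != RAW_N & raw != charToRaw("n")
  raw[cover] <- RAW_N
  record$seq <- rawToChar(raw)
  attr(record, "masked_bp") <- sum(newly)
  record
}

#' Build the background genome
#'
#' Loads every genome, selects viral-annotated features per `policy`, masks
#' them with Ns, and concatenates all records into a single background
#' collection with a mask log. With `policy$masking_enabled = FALSE` the
#' records pass through unmasked and the mask log is empty.
#'
#' @param genome_paths Character vector of GenBank or FASTA paths.
#' @param policy A [mask_policy()].
#' @param annotations Optional character vector of GFF3 paths, parallel to
#'   `genome_paths` (use `NA` for GenBank entries).
#' @return A `BackgroundGenome`: list with `records`, `mask_log`,
#'   `total_bp`, `masked_bp`, `policy`.
#' @export
build_background <- function(genome_paths, policy = mask_policy(),
                             annotations = NULL) {
  if (!length(genome_paths)) abort("at least one genome path is required")
  all_records <- list()
  all_features <- list()
  for (i in seq_along(genome_paths)) {
    ann <- if (!is.null(annotations) && !is.na(annotations[i])) {
      annotations[i]
    } else {
      NULL
    }
    g <- load_annotated_genome(genome_paths[i], annotation = ann)
    all_records[[i]] <- g$records
    all_features[[i]] <- g$features
  }
  records <- do.call(rbind, all_records)
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    abort("duplicate record id(s) across input genomes: ",
          paste(dup, collapse = ", "))
  }
  validate_sequence_records(records, "background input")
  features <- do.call(rbind, all_features)
  records$seq <- toupper(records$seq)

  mask_log <- data.frame(seq_id = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         feature_id = character(0),
                         matched_keyword = character(0),
                         matched_text = character(0),
                         stringsAsFactors = FALSE)
  masked_bp <- 0L
  if (policy$masking_enabled && nrow(features)) {
    sel <- select_viral_features(features, policy)
    if (nrow(sel)) {
      mask_log <- data.frame(seq_id = sel$seq_id, start = sel$start,
                             end = sel$end, strand = sel$strand,
                             feature_id = sel$feature_id,
                             matched_keyword = sel$matched_keyword,
                             matched_text = sel$matched_text,
                             stringsAsFactors = FALSE)
      for (i in seq_len(nrow(records))) {
        iv <- mask_log[mask_log$seq_id == records$id[i], , drop = FALSE]
        if (!nrow(iv)) next
        rec <- mask_record(list(id = records$id[i], seq = records$seq[i]), iv)
        records$seq[i] <- rec$seq
        masked_bp <- masked_bp + attr(rec, "masked_bp")
      }
    }
  }
  structure(list(records = records, mask_log = mask_log,
                 total_bp = sum(nchar(records$seq)),
                 masked_bp = as.integer(masked_bp), policy = policy),
            class = "BackgroundGenome")
}

#' @export
print.BackgroundGenome <- function(x, ...) {
  cat("Background genome:", nrow(x$records), "record(s),",
      format(x$total_bp, big.mark = ","), "bp total;",
      format(x$masked_bp, big.mark = ","), "bp masked in",
      nrow(x$mask_log), "interval(s)\n")
  invisible(x)
}

#' Use a pre-built background FASTA
#'
#' Import counterpart of [build_background()]: wraps an already-masked
#' FASTA (e.g. produced elsewhere) as a `BackgroundGenome` with an empty
#' mask log.
#'
#' @param path FASTA path (gzip accepted).
#' @return A `BackgroundGenome`.
#' @export
background_from_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) abort("no sequences in background FASTA ", path)
  records <- data.frame(id = sub("\\s.*$", "", names(ss)),
                        description = sub("^\\S+\\s*", "", names(ss)),
                        seq = toupper(as.character(ss)),
                        stringsAsFactors = FALSE)
  validate_sequence_records(records, path)
  structure(list(records = records,
                 mask_log = data.frame(seq_id = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0),
                                       feature_id = character(0),
                                       matched_keyword = character(0),
                                       matched_text = character(0),
                                       stringsAsFactors = FALSE),
                 total_bp = sum(nchar(records$seq)),
                 masked_bp = NA_integer_,
                 policy = NULL),
            class = "BackgroundGenome")
}

#' Write the background genome as FASTA
#'
#' @param bg A `BackgroundGenome`.
#' @param path Output FASTA path (80-column wrapped).
#' @return Invisibly, `path`.
#' @export
write_background_fasta <- function(bg, path) {
  nm <- ifelse(nzchar(bg$records$description),
               paste(bg$records$id, bg$records$description),
               bg$records$id)
  ss <- Biostrings::DNAStringSet(bg$records$seq)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write the mask log as BED (plus TSV sidecar)
#'
#' BED uses 0-based half-open coordinates: a mask interval
#' `start..end` (1-based inclusive) becomes `start-1, end`. The TSV sidecar
#' records the matched keyword and the qualifier text that triggered each
#' interval.
#'
#' @param bg A `BackgroundGenome` from [build_background()].
#' @param bed_path Output BED path.
#' @param tsv_path Optional sidecar TSV path.
#' @return Invisibly, `bed_path`.
#' @export
write_mask_bed <- function(bg, bed_path, tsv_path = NULL) {
  ml <- bg$mask_log
  bed <- data.frame(chrom = ml$seq_id,
                    start = ml$start - 1L,
                    end = ml$end,
                    name = ml$feature_id,
                    score = rep(0L, nrow(ml)),
                    strand = ifelse(ml$strand %in% c("+", "-"),
                                    ml$strand, "."))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) write_tsv(ml, tsv_path)
  invisible(bed_path)
}
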