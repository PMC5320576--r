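# Annotated-genome input. Two routes into the same in-memory shape:
#   * GenBank flat files (possibly multi-record, possibly gzipped) via a
#     purpose-built feature-table parser (no installed R package reads the
#     GenBank feature table with qualifiers and join() locations);
#   * FASTA + GFF3 pairs via Biostrings / rtracklayer.
#
# Records are a data.frame with columns id, description, seq.
# Features are a data.frame with one row PER INTERVAL (compound join()
# locations are expanded) and columns seq_id, start, end, strand, kind,
# feature_id plus a list-column `qualifiers` (named list of character
# vectors).

empty_features <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), kind = character(0),
             feature_id = character(0),
             qualifiers = I(list()), stringsAsFactors = FALSE)
}

features_frame <- function(seq_id, start, end, strand, kind, feature_id,
                           qualifiers) {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             feature_id = feature_id, qualifiers = I(qualifiers),
             stringsAsFactors = FALSE)
}

flip_strand <- function(strand) {
  ifelse(strand == "+", "-", ifelse(strand == "-", "+", strand))
}

# Split a location string on commas at parenthesis depth zero.
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(j) {
    paste(chars[starts[j]:ends[j]], collapse = "")
  }, character(1))
}

# Parse a GenBank location into a data.frame(start, end, strand).
# Handles n, n..m, complement(...), join(...), order(...), and partial
# markers (< >), which are stripped.
parse_gb_location <- function(s, strand = "+") {
  s <- gsub("[<>[:space:]]", "", s)
  if (grepl("^complement\\(", s)) {
    inner <- sub("\\)$", "", sub("^complement\\(", "", s))
    return(parse_gb_location(inner, flip_strand(strand)))
  }
  if (grepl("^(join|order)\\(", s)) {
    inner <- sub("\\)$", "", sub("^(join|order)\\(", "", s))
    parts <- lapply(split_top_level(inner), parse_gb_location, strand = strand)
    return(do.call(rbind, parts))
  }
  m <- regmatches(s, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", s))[[1]]
  if (!length(m)) abort("cannot parse feature location: ", s)
  start <- as.integer(m[2])
  end <- if (nzchar(m[4])) as.integer(m[4]) else start
  data.frame(start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

parse_gb_qualifier <- function(raw) {
  m <- regmatches(raw, regexec("^/([A-Za-z0-9_]+)(=(.*))?$", raw))[[1]]
  if (!length(m)) return(NULL)
  name <- m[2]
  value <- if (nzchar(m[3])) m[4] else ""
  value <- sub("^\"", "", sub("\"$", "", value))
  list(name = name, value = value)
}

#' Read a GenBank flat file
#'
#' Parses one or more GenBank records (LOCUS/DEFINITION/FEATURES/ORIGIN)
#' including joined and complemented feature locations and multi-line
#' qualifiers. Gzipped input is accepted.
#'
#' @param path Path to a GenBank flat file (`.gb`, `.gbk`, optionally `.gz`).
#' @return A list with `records` (data.frame: id, description, seq) and
#'   `features` (one row per feature interval; see package overview).
#' @export
read_genbank <- function(path) {
  lines <- read_text_lines(path)
  term <- which(trimws(lines) == "//")
  if (!length(term)) abort("no GenBank record terminator (//) in ", path)
  starts <- c(1L, term[-length(term)] + 1L)
  recs <- list()
  feats <- list()
  for (r in seq_along(term)) {
    block <- lines[starts[r]:(term[r] - 1L)]
    parsed <- parse_one_genbank(block, path)
    recs[[r]] <- parsed$record
    feats[[r]] <- parsed$features
  }
  records <- do.call(rbind, recs)
  features <- do.call(rbind, feats)
  if (is.null(features)) features <- empty_features()
  validate_sequence_records(records, path)
  validate_features(features, records, path)
  list(records = records, features = features)
}

parse_one_genbank <- function(block, path) {
  locus_line <- block[grepl("^LOCUS", block)]
  if (!length(locus_line)) abort("GenBank record without LOCUS line in ", path)
  id <- strsplit(trimws(locus_line[1]), "\\s+")[[1]][2]

  def_i <- grep("^DEFINITION", block)
  description <- ""
  if (length(def_i)) {
    j <- def_i[1]
    parts <- sub("^DEFINITION\\s*", "", block[j])
    j <- j + 1L
    while (j <= length(block) && grepl("^\\s", block[j]) &&
           !grepl("^FEATURES", block[j])) {
      parts <- c(parts, trimws(block[j]))
      j <- j + 1L
    }
    description <- sub("\\.$", "", paste(parts, collapse = " "))
  }

  origin_i <- grep("^ORIGIN", block)
  seq <- ""
  if (length(origin_i)) {
    seq_lines <- block[(origin_i[1] + 1L):length(block)]
    seq <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  }

  feat_i <- grep("^FEATURES", block)
  features <- empty_features()
  if (length(feat_i)) {
    stop_i <- if (length(origin_i)) origin_i[1] - 1L else length(block)
    # other top-level keywords (e.g. CONTIG, BASE COUNT) end the table too
    tail_keys <- grep("^[A-Z]", block)
    tail_keys <- tail_keys[tail_keys > feat_i[1]]
    if (length(tail_keys)) stop_i <- min(stop_i, min(tail_keys) - 1L)
    if (stop_i > feat_i[1]) {
      features <- parse_feature_table(block[(feat_i[1] + 1L):stop_i], id)
    }
  }
  list(record = data.frame(id = id, description = description, seq = seq,
                           stringsAsFactors = FALSE),
       features = features)
}

parse_feature_table <- function(lines, seq_id) {
  # collect (kind, location string, raw qualifier strings) per feature
  raw_feats <- list()
  cur <- NULL
  mode <- "none"  # what the last line belonged to: "loc" or "qual"
  for (line in lines) {
    if (grepl("^ {5}\\S", line)) {
      if (!is.null(cur)) raw_feats[[length(raw_feats) + 1L]] <- cur
      kind <- trimws(substr(line, 6L, 20L))
      loc <- trimws(substring(line, 21L))
      cur <- list(kind = kind, loc = loc, quals = character(0))
      mode <- "loc"
    } else if (!is.null(cur)) {
      txt <- trimws(line)
      if (!nzchar(txt)) next
      if (grepl("^/[A-Za-z0-9_]+($|=)", txt)) {
        cur$quals <- c(cur$quals, txt)
        mode <- "qual"
      } else if (mode == "loc") {
        cur$loc <- paste0(cur$loc, txt)
      } else {
        n <- length(cur$quals)
        sep <- if (grepl("^/translation", cur$quals[n])) "" else " "
        cur$quals[n] <- paste(cur$quals[n], txt, sep = sep)
      }
    }
  }
  if (!is.null(cur)) raw_feats[[length(raw_feats) + 1L]] <- cur

  rows <- list()
  counter <- 0L
  for (f in raw_feats) {
    if (f$kind == "source") next
    counter <- counter + 1L
    loc <- parse_gb_location(f$loc)
    quals <- list()
    for (q in f$quals) {
      pq <- parse_gb_qualifier(q)
      if (is.null(pq)) next
      quals[[pq$name]] <- c(quals[[pq$name]], pq$value)
    }
    fid <- if (!is.null(quals$locus_tag)) {
      quals$locus_tag[1]
    } else if (!is.null(quals$gene)) {
      quals$gene[1]
    } else {
      sprintf("%s_%s_%d", seq_id, f$kind, counter)
    }
    rows[[length(rows) + 1L]] <- features_frame(
      seq_id = rep(seq_id, nrow(loc)), start = loc$start, end = loc$end,
      strand = loc$strand, kind = rep(f$kind, nrow(loc)),
      feature_id = rep(fid, nrow(loc)),
      qualifiers = rep(list(quals), nrow(loc)))
  }
  if (!length(rows)) return(empty_features())
  do.call(rbind, rows)
}

validate_features <- function(features, records, where) {
  if (!nrow(features)) return(invisible(features))
  m <- match(features$seq_id, records$id)
  if (anyNA(m)) {
    abort("feature ", features$feature_id[is.na(m)][1], " in ", where,
          " references unknown sequence ", features$seq_id[is.na(m)][1])
  }
  lens <- nchar(records$seq)[m]
  bad <- features$start < 1L | features$end > lens |
    features$start > features$end
  if (any(bad)) {
    abort("feature ", features$feature_id[bad][1], " in ", where,
          " has coordinates outside its sequence (",
          features$start[bad][1], "..", features$end[bad][1],
          " on a ", lens[bad][1], " bp record)")
  }
  invisible(features)
}

#' Write records and features as a GenBank flat file
#'
#' Emits the dialect `read_genbank()` parses: one LOCUS block per record with
#' a FEATURES table (single-interval locations, `complement()` for minus
#' strand) and a numbered ORIGIN section. Used by the simulator to produce
#' annotated host genomes.
#'
#' @param records data.frame with columns id, description, seq.
#' @param features Feature data.frame (may be empty); `translation`
#'   qualifiers are not written.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(records, features, path) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    seq <- toupper(records$seq[i])
    len <- nchar(seq)
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     linear   UNA 01-JAN-2026",
                          id, len))
    desc <- records$description[i]
    if (nzchar(desc)) out <- c(out, paste0("DEFINITION  ", desc, "."))
    out <- c(out, "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", len))
    fi <- which(features$seq_id == id)
    for (j in fi) {
      loc <- sprintf("%d..%d", features$start[j], features$end[j])
      if (features$strand[j] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-15s %s", features$kind[j], loc))
      quals <- features$qualifiers[[j]]
      for (qn in names(quals)) {
        if (qn == "translation") next
        for (qv in quals[[qn]]) {
          full <- sprintf("/%s=\"%s\"", qn, qv)
          wrapped <- strwrap(full, width = 58)
          out <- c(out, paste0(strrep(" ", 21), wrapped))
        }
      }
    }
    out <- c(out, "ORIGIN")
    pos <- seq(1L, len, by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(len, p + 59L))
      groups <- substring(chunk,
                          seq(1L, nchar(chunk), by = 10L),
                          pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, by = 10L)))
      out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

# FASTA + GFF3 route (Biostrings + rtracklayer).
read_fasta_gff <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) abort("cannot read file: ", fasta_path)
  if (!file.exists(gff_path)) abort("cannot read file: ", gff_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  records <- data.frame(id = ids, description = desc,
                        seq = toupper(as.character(ss)),
                        stringsAsFactors = FALSE)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (!length(gr)) {
    features <- empty_features()
  } else {
    mc <- as.data.frame(gr)
    qual_cols <- intersect(c("product", "note", "Note", "function", "gene",
                             "locus_tag", "ID", "Name"),
                           names(mc))
    quals <- lapply(seq_len(nrow(mc)), function(i) {
      q <- list()
      for (cn in qual_cols) {
        v <- mc[[cn]][[i]]
        v <- as.character(unlist(v))
        v <- v[!is.na(v) & nzchar(v)]
        if (length(v)) q[[tolower(cn)]] <- v
      }
      q
    })
    fid <- vapply(seq_along(quals), function(i) {
      q <- quals[[i]]
      for (key in c("locus_tag", "id", "gene", "name")) {
        if (!is.null(q[[key]])) return(q[[key]][1])
      }
      sprintf("%s_%s_%d", mc$seqnames[i], mc$type[i], i)
    }, character(1))
    strand <- as.character(mc$strand)
    strand[!strand %in% c("+", "-")] <- "*"
    features <- features_frame(seq_id = as.character(mc$seqnames),
                               start = mc$start, end = mc$end,
                               strand = strand,
                               kind = as.character(mc$type),
                               feature_id = fid, qualifiers = quals)
  }
  validate_sequence_records(records, fasta_path)
  validate_features(features, records, gff_path)
  list(records = records, features = features)
}

#' Load an annotated genome
#'
#' Reads sequence records and their features from either a GenBank flat file
#' or a FASTA file with a companion GFF3 annotation. `format = "auto"`
#' decides by file extension, falling back to content sniffing.
#'
#' @param path Genome file (GenBank or FASTA; gzip accepted).
#' @param format `"auto"`, `"genbank"`, or `"fasta"`.
#' @param annotation GFF3 path, required when `path` is FASTA.
#' @return List with `records` and `features` data.frames.
#' @export
load_annotated_genome <- function(path, format = c("auto", "genbank", "fasta"),
                                  annotation = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) {
      "genbank"
    } else if (ext %in% c("fa", "fasta", "fna")) {
      "fasta"
    } else {
      first <- read_text_lines(path)
      first <- first[nzchar(trimws(first))][1]
      if (startsWith(first, ">")) "fasta" else "genbank"
    }
  }
  if (format == "genbank") {
    read_genbank(path)
  } else {
    if (is.null(annotation)) {
      abort("FASTA input ", path,
            " requires a companion GFF3 annotation (argument `annotation`)")
    }
    read_fasta_gff(path, annotation)
  }
}
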