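# End-to-end orchestration: one declarative config, one run, one report.
# Any stage can be replaced by its import counterpart (pre-built background
# FASTA, SAM verdicts from an external mapper, contig FASTA from an external
# assembler) — the plug-and-play contract.

config_schema <- function() {
  list(
    background = list(genomes = "character", annotations = "character",
                      keywords = "character", qualifiers = "character",
                      feature_kinds = "character",
                      masking_enabled = "logical",
                      background_fasta = "character"),
    filter = list(seed_length = "numeric", min_identity = "numeric",
                  min_aligned_fraction = "numeric",
                  both_strands = "logical", policy = "character",
                  sam = "character"),
    assembly = list(k = "numeric", min_contig_len = "numeric",
                    cov_cutoff = "any", contigs_fasta = "character"),
    io = list(reads1 = "character", reads2 = "character",
              interleaved = "logical", out_dir = "character",
              gzip = "logical"),
    seed = "numeric")
}

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default;
#' fill in `background$genomes` and `io$reads1` (plus `io$reads2` for
#' paired input) and pass to [run_pipeline()].
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    background = list(genomes = character(0), annotations = NULL,
                      keywords = c("phage", "viral"),
                      qualifiers = c("product", "note", "function"),
                      feature_kinds = "CDS",
                      masking_enabled = TRUE,
                      background_fasta = NULL),
    filter = list(seed_length = 15L, min_identity = 0.90,
                  min_aligned_fraction = 0.80, both_strands = TRUE,
                  policy = "pair_level", sam = NULL),
    assembly = list(k = 31L, min_contig_len = 1000L, cov_cutoff = "auto",
                    contigs_fasta = NULL),
    io = list(reads1 = NULL, reads2 = NULL, interleaved = FALSE,
              out_dir = "phagesift_out", gzip = FALSE),
    seed = 42L)
}

merge_config <- function(user, defaults, schema, prefix = "") {
  for (key in names(user)) {
    qual <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(schema)) {
      abort("unknown configuration key: '", qual, "'")
    }
    if (is.list(schema[[key]]) && !identical(key, "cov_cutoff")) {
      if (!is.list(user[[key]])) {
        abort("configuration section '", qual, "' must be a mapping")
      }
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]],
                                      schema[[key]], qual)
    } else {
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults, rejects
#' unknown keys by name, range-checks thresholds, and checks that every
#' referenced input path exists.
#'
#' @param config YAML path or configuration list (possibly partial).
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort("cannot read config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a file path or a list")
  cfg <- merge_config(config, default_config(), config_schema())

  f <- cfg$filter
  if (f$min_identity <= 0 || f$min_identity > 1) {
    abort("filter.min_identity must be in (0, 1], got ", f$min_identity)
  }
  if (f$min_aligned_fraction <= 0 || f$min_aligned_fraction > 1) {
    abort("filter.min_aligned_fraction must be in (0, 1], got ",
          f$min_aligned_fraction)
  }
  if (f$seed_length < 8) {
    abort("filter.seed_length must be >= 8, got ", f$seed_length)
  }
  cfg$filter$policy <- normalize_policy(f$policy)
  if (cfg$assembly$k %% 2 == 0) {
    abort("assembly.k must be odd, got ", cfg$assembly$k)
  }
  if (cfg$assembly$min_contig_len < 1) {
    abort("assembly.min_contig_len must be >= 1")
  }

  if (is.null(cfg$io$reads1)) abort("io.reads1 is required")
  if (is.null(cfg$background$background_fasta) &&
      !length(cfg$background$genomes)) {
    abort("either background.genomes or background.background_fasta ",
          "is required")
  }
  for (p in c(cfg$background$genomes, cfg$background$annotations,
              cfg$background$background_fasta, cfg$filter$sam,
              cfg$assembly$contigs_fasta, cfg$io$reads1, cfg$io$reads2)) {
    if (!is.null(p) && !is.na(p) && !file.exists(p)) {
      abort("input path does not exist: ", p)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    abort("stage '", name, "' failed: ", conditionMessage(e))
  })
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full subtractive pipeline
#'
#' Executes background building, subtractive filtering and assembly in
#' order, writing every stage artifact (masked FASTA + BED mask log,
#' retained FASTQ, removed-id list, tally, contig FASTA, stats) plus a
#' one-row report TSV and a human-readable summary into `io$out_dir`.
#' While a run is in progress the directory carries an `INCOMPLETE` marker
#' file, removed on success. Each stage can be swapped for an import: a
#' pre-built background FASTA, SAM verdicts, or a contig FASTA.
#'
#' @param config YAML path, configuration list, or `pipeline_config`.
#' @return A `PipelineReport` (invisible-friendly list with counts,
#'   background percentage, assembly stats, timings and the config echo).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out <- cfg$io$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out, "INCOMPLETE")
  writeLines("pipeline run in progress or aborted", marker)

  message("[phagesift] loading reads")
  reads <- read_fastq(cfg$io$reads1, cfg$io$reads2, cfg$io$interleaved)
  if (!nrow(reads)) abort("no reads in input")
  input_bp <- sum(nchar(reads$seq))
  message("[phagesift] ", nrow(reads), " reads, ",
          format(input_bp, big.mark = ","), " bp")

  s1 <- run_stage("background", {
    if (!is.null(cfg$background$background_fasta)) {
      background_from_fasta(cfg$background$background_fasta)
    } else {
      policy <- mask_policy(keywords = cfg$background$keywords,
                            searched_qualifiers = cfg$background$qualifiers,
                            masking_enabled = cfg$background$masking_enabled,
                            feature_kinds = cfg$background$feature_kinds)
      build_background(cfg$background$genomes, policy,
                       cfg$background$annotations)
    }
  })
  bg <- s1$value
  write_background_fasta(bg, file.path(out, "background.fasta"))
  write_mask_bed(bg, file.path(out, "mask.bed"),
                 file.path(out, "mask_log.tsv"))
  message("[phagesift] background: ", format(bg$total_bp, big.mark = ","),
          " bp, ", format(bg$masked_bp, big.mark = ","), " bp masked")

  s2 <- run_stage("filter", {
    verdicts <- if (!is.null(cfg$filter$sam)) {
      import_sam_verdicts(cfg$filter$sam, known_ids = reads$id)
    } else {
      mcfg <- mapper_config(seed_length = cfg$filter$seed_length,
                            min_identity = cfg$filter$min_identity,
                            min_aligned_fraction =
                              cfg$filter$min_aligned_fraction,
                            both_strands = cfg$filter$both_strands)
      idx <- index_background(bg, mcfg$seed_length)
      map_reads(reads, idx, mcfg)
    }
    filter_reads(reads, verdicts, cfg$filter$policy)
  })
  fr <- s2$value
  write_filter_outputs(fr, out, gzip = cfg$io$gzip)
  bg_percent <- background_fraction(fr)
  message("[phagesift] filter (", fr$policy, "): ",
          nrow(fr$removed), " reads removed (", bg_percent,
          "% of bp), ", nrow(fr$retained), " retained")

  s3 <- run_stage("assembly", {
    if (!is.null(cfg$assembly$contigs_fasta)) {
      import_contigs(cfg$assembly$contigs_fasta)
    } else {
      # emit everything down to 2k; the report filters at min_contig_len,
      # but the full contig set goes to disk for inspection
      assemble(fr$retained$seq, k = cfg$assembly$k,
               min_contig_len = min(cfg$assembly$min_contig_len,
                                    2L * cfg$assembly$k),
               cov_cutoff = cfg$assembly$cov_cutoff)
    }
  })
  contigs <- s3$value
  write_contigs(contigs, file.path(out, "contigs.fasta"))
  stats <- compute_stats(contigs,
                         min_report_len = cfg$assembly$min_contig_len)
  message("[phagesift] assembly: ", nrow(contigs), " contig(s); ",
          stats$n_contigs, " >= ", stats$min_report_len, " bp, N50 ",
          stats$n50)

  report <- structure(list(
    input_reads = nrow(reads),
    input_bp = input_bp,
    removed_reads = nrow(fr$removed),
    retained_reads = nrow(fr$retained),
    background_percent = bg_percent,
    assembly = stats,
    timings = c(background = s1$seconds, filter = s2$seconds,
                assembly = s3$seconds),
    config = cfg), class = "PipelineReport")
  write_report(report, out)
  unlink(marker)
  report
}

write_report <- function(report, out_dir) {
  row <- data.frame(input_bp = report$input_bp,
                    background_percent = report$background_percent,
                    n_contigs_ge_min = report$assembly$n_contigs,
                    max_length = report$assembly$max_length,
                    n50 = report$assembly$n50,
                    total_bp = report$assembly$total_bp)
  write_tsv(row, file.path(out_dir, "report.tsv"))
  summary_lines <- c(
    "phagesift run summary",
    sprintf("  input:      %d reads, %d bp", report$input_reads,
            report$input_bp),
    sprintf("  filter:     %d reads removed, %d retained (%.2f%% of bp background)",
            report$removed_reads, report$retained_reads,
            report$background_percent),
    sprintf("  assembly:   %d contigs >= %d bp | max %d | N50 %d | total %d bp",
            report$assembly$n_contigs, report$assembly$min_report_len,
            report$assembly$max_length, report$assembly$n50,
            report$assembly$total_bp),
    sprintf("  timings(s): background %.1f, filter %.1f, assembly %.1f",
            report$timings[["background"]], report$timings[["filter"]],
            report$timings[["assembly"]]))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(report)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("phagesift pipeline report\n")
  cat("  input:  ", x$input_reads, "reads,",
      format(x$input_bp, big.mark = ","), "bp\n")
  cat("  removed:", x$removed_reads, "reads (",
      x$background_percent, "% of bp background )\n")
  cat("  retained:", x$retained_reads, "reads\n")
  cat("  assembly: ")
  print(x$assembly)
  invisible(x)
}
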